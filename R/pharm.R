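#' Normalize raw viability signal to vehicle wells
#'
#' Divides every raw well value by the mean of the vehicle-treated wells,
#' giving viability as a fraction of control.
#'
#' @param raw Numeric vector or matrix of raw signal (e.g. crystal-violet
#'   absorbance).
#' @param vehicle_values Raw signal of the vehicle wells.
#' @return `raw / mean(vehicle_values)`, same shape as `raw`.
#' @export
normalize_to_vehicle <- function(raw, vehicle_values) {
  vm <- mean(vehicle_values, na.rm = TRUE)
  if (!is.finite(vm) || vm <= 0) abort("Vehicle mean must be positive.")
  raw / vm
}

#' Fraction affected from normalized viability
#'
#' `fa = 1 - viability`, clipped into \[0, 1\] for use in Bliss
#' calculations (a well slightly above the vehicle mean would otherwise
#' give a negative fraction affected). Clipping is reported.
#'
#' @param viability Normalized viability (fraction of vehicle control).
#' @return Fraction affected, same shape; the number of clipped values is
#'   available as `attr(, "n_clipped")`.
#' @export
fraction_affected <- function(viability) {
  fa <- 1 - viability
  clipped <- sum(fa < 0 | fa > 1, na.rm = TRUE)
  if (clipped > 0) {
    inform(sprintf("fraction_affected: %d value(s) clipped into [0, 1].", clipped))
  }
  fa <- pmin(pmax(fa, 0), 1)
  attr(fa, "n_clipped") <- clipped
  fa
}

#' Construct a dose-response object
#'
#' @param data Tibble/data frame with columns `conc_um` (positive
#'   concentrations; the 0-concentration vehicle is handled separately by
#'   [normalize_to_vehicle()]), `viability` (fraction of vehicle control),
#'   and optionally `replicate`.
#' @param drug Drug label.
#' @return A `dose_response` tibble (attribute `drug`).
#' @export
dose_response <- function(data, drug = "drug") {
  data <- as_tibble(data)
  req <- c("conc_um", "viability")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (any(data$conc_um <= 0)) {
    abort("Concentrations must be strictly positive (vehicle is the normalizer, not a dose).")
  }
  structure(data, drug = drug, class = c("dose_response", class(data)))
}

fourpl <- function(x, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Fit a four-parameter logistic (sigmoidal) dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`
#' to the per-concentration mean responses, with constraints
#' `0 <= bottom <= top <= 1.2` and `ic50 > 0`. The optimizer
#' (Levenberg-Marquardt, [minpack.lm::nlsLM()]) is run from a multi-start
#' grid (`ic50` over the observed concentration range, `hill` in
#' `{0.5, 1, 2}`) and the best-residual fit is kept. The reported IC50 is
#' the relative IC50 (the curve's inflection).
#'
#' A response flat to within `flat_tol` carries no dose information: the
#' fit is flagged non-convergent and the parameters are `NA`.
#'
#' @param dr A [dose_response()] object (>= 4 distinct concentrations).
#' @param hill_starts Hill-slope starting values.
#' @param flat_tol Minimal dynamic range of the mean response (default 0.05).
#' @return A `parp_4pl` object: list with `bottom`, `top`, `ic50`, `hill`,
#'   `converged`, `rss`, `data` (per-concentration means), `fitted`,
#'   `residuals`, `drug`. Supports [tidy()], [glance()], `predict()` and
#'   [autoplot()].
#' @export
fit_4pl <- function(dr, hill_starts = c(0.5, 1, 2), flat_tol = 0.05) {
  stopifnot(inherits(dr, "dose_response"))
  means <- dplyr::summarise(
    dplyr::group_by(as_tibble(dr), .data$conc_um),
    response = mean(.data$viability), .groups = "drop"
  )
  means <- dplyr::arrange(means, .data$conc_um)
  if (nrow(means) < 4) abort("At least 4 distinct positive concentrations are required.")
  x <- means$conc_um
  y <- means$response
  drug <- attr(dr, "drug")

  if (diff(range(y)) < flat_tol) {
    return(new_parp_4pl(NA, NA, NA, NA, FALSE, sum((y - mean(y))^2), means,
                        rep(mean(y), length(y)), y - mean(y), drug))
  }

  ic50_starts <- exp(seq(log(min(x)), log(max(x)), length.out = 5))
  b0 <- max(min(y), 0)
  span0 <- max(max(y) - min(y), 0.1)
  best <- NULL
  errs <- character(0)
  for (ic in ic50_starts) {
    for (h in hill_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + span / (1 + (x / ic50)^hill),
          start = list(bottom = b0, span = span0, ic50 = ic, hill = h),
          lower = c(bottom = 0, span = 0, ic50 = min(x) / 1e4, hill = 0.05),
          upper = c(bottom = 1.2, span = 1.2, ic50 = max(x) * 1e4, hill = 20),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        errs <- c(errs, conditionMessage(fit))
        next
      }
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort(paste0(
      "4PL fit failed from every start. Mean responses: ",
      paste(sprintf("%.3f", y), collapse = ", "),
      "; last optimizer error: ", utils::tail(errs, 1)
    ))
  }
  cf <- stats::coef(best$fit)
  fitted <- fourpl(x, cf[["bottom"]], cf[["bottom"]] + cf[["span"]], cf[["ic50"]], cf[["hill"]])
  new_parp_4pl(
    bottom = cf[["bottom"]],
    top = cf[["bottom"]] + cf[["span"]],
    ic50 = cf[["ic50"]],
    hill = cf[["hill"]],
    converged = TRUE,
    rss = best$rss,
    data = means,
    fitted = fitted,
    residuals = y - fitted,
    drug = drug
  )
}

new_parp_4pl <- function(bottom, top, ic50, hill, converged, rss, data,
                         fitted, residuals, drug) {
  structure(
    list(bottom = bottom, top = top, ic50 = ic50, hill = hill,
         converged = converged, rss = rss, data = data, fitted = fitted,
         residuals = residuals, drug = drug),
    class = "parp_4pl"
  )
}

#' @export
print.parp_4pl <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("4PL fit for %s: non-convergent (flat or degenerate response); IC50 undefined\n", x$drug))
  } else {
    cat(sprintf(
      "4PL fit for %s: IC50 = %.4g uM, hill = %.3g, top = %.3g, bottom = %.3g (RSS %.3g)\n",
      x$drug, x$ic50, x$hill, x$top, x$bottom, x$rss
    ))
  }
  invisible(x)
}

#' @export
predict.parp_4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$conc_um else newdata$conc_um %||% newdata
  if (!object$converged) return(rep(NA_real_, length(x)))
  fourpl(x, object$bottom, object$top, object$ic50, object$hill)
}

#' @exportS3Method generics::tidy
tidy.parp_4pl <- function(x, ...) {
  tibble(
    term = c("bottom", "top", "ic50", "hill"),
    estimate = c(x$bottom, x$top, x$ic50, x$hill)
  )
}

#' @exportS3Method generics::glance
glance.parp_4pl <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, n = nrow(x$data), drug = x$drug)
}

#' Bliss excess (delta-Bliss) for one combination measurement
#'
#' Under Bliss independence two non-interacting drugs combine as
#' `fa_expected = fa_a + fa_b - fa_a * fa_b` on the fraction-affected
#' scale. The Bliss excess `fa_ab - fa_expected` is positive for synergy
#' and negative for antagonism, and always lies in \[-1, 1\].
#'
#' @param fa_a,fa_b Single-agent fractions affected, in \[0, 1\].
#' @param fa_ab Observed combination fraction affected, in \[0, 1\].
#' @return `fa_ab - (fa_a + fa_b - fa_a * fa_b)` (vectorized).
#' @examples
#' bliss_delta(0.5, 0.5, 0.9)
#' @export
bliss_delta <- function(fa_a, fa_b, fa_ab) {
  vals <- c(fa_a, fa_b, fa_ab)
  if (any(is.na(vals)) || any(vals < 0 | vals > 1)) {
    abort("All fractions affected must lie in [0, 1].")
  }
  fa_ab - (fa_a + fa_b - fa_a * fa_b)
}

#' Delta-Bliss synergy grid for a drug combination
#'
#' Computes the observed and Bliss-expected fraction affected, and their
#' difference, over a concentration-by-concentration combination grid.
#' Single-agent marginal fractions affected are taken as the mean over
#' replicates at each concentration (observed, not fitted); the observed
#' combination effect is likewise the replicate mean, and delta-Bliss is
#' formed from the means.
#'
#' @param single_a,single_b [dose_response()] objects covering every
#'   concentration used in the combination grid.
#' @param combo Tibble with columns `conc_a_um`, `conc_b_um`, `replicate`,
#'   `viability` (fraction of vehicle control).
#' @return A `parp_synergy` object: `grid` (tibble with `conc_a_um`,
#'   `conc_b_um`, `fa_a`, `fa_b`, `fa_obs`, `fa_expected`, `delta_bliss`,
#'   `n_rep`, `sem`), `summary` (mean delta, the maximal-delta cell),
#'   `drug_a`, `drug_b`. Supports [tidy()], [glance()], [autoplot()].
#' @export
synergy_grid <- function(single_a, single_b, combo) {
  stopifnot(inherits(single_a, "dose_response"), inherits(single_b, "dose_response"))
  combo <- as_tibble(combo)
  req <- c("conc_a_um", "conc_b_um", "viability")
  miss <- setdiff(req, names(combo))
  if (length(miss)) abort(paste0("Combo table missing column(s): ", paste(miss, collapse = ", ")))

  marginal_fa <- function(dr) {
    m <- dplyr::summarise(
      dplyr::group_by(as_tibble(dr), .data$conc_um),
      fa = mean(suppressMessages(fraction_affected(.data$viability))),
      .groups = "drop"
    )
    setNames(m$fa, format(m$conc_um, trim = TRUE))
  }
  fa_a <- marginal_fa(single_a)
  fa_b <- marginal_fa(single_b)

  key_a <- format(combo$conc_a_um, trim = TRUE)
  key_b <- format(combo$conc_b_um, trim = TRUE)
  bad <- which(!(key_a %in% names(fa_a)) | !(key_b %in% names(fa_b)))
  if (length(bad)) {
    abort(sprintf(
      "Combination cell (%g, %g) has no single-agent marginal at that concentration.",
      combo$conc_a_um[bad[1]], combo$conc_b_um[bad[1]]
    ))
  }

  fa_combo <- suppressMessages(fraction_affected(combo$viability))
  grid <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(combo, fa = fa_combo),
      .data$conc_a_um, .data$conc_b_um
    ),
    fa_obs = mean(.data$fa),
    n_rep = dplyr::n(),
    sem = sd(.data$fa) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  grid <- dplyr::mutate(
    grid,
    fa_a = unname(fa_a[format(.data$conc_a_um, trim = TRUE)]),
    fa_b = unname(fa_b[format(.data$conc_b_um, trim = TRUE)]),
    fa_expected = .data$fa_a + .data$fa_b - .data$fa_a * .data$fa_b,
    delta_bliss = .data$fa_obs - .data$fa_expected
  )
  imax <- which.max(grid$delta_bliss)
  structure(
    list(
      grid = grid,
      summary = list(
        mean_delta = mean(grid$delta_bliss),
        max_delta = grid$delta_bliss[imax],
        max_cell = c(conc_a_um = grid$conc_a_um[imax], conc_b_um = grid$conc_b_um[imax])
      ),
      drug_a = attr(single_a, "drug"),
      drug_b = attr(single_b, "drug")
    ),
    class = "parp_synergy"
  )
}

#' @export
print.parp_synergy <- function(x, ...) {
  cat(sprintf(
    "Delta-Bliss grid %s x %s: %d cells, mean delta %.3f, max delta %.3f at (%g, %g) uM\n",
    x$drug_a, x$drug_b, nrow(x$grid), x$summary$mean_delta,
    x$summary$max_delta, x$summary$max_cell[1], x$summary$max_cell[2]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.parp_synergy <- function(x, ...) x$grid

#' @exportS3Method generics::glance
glance.parp_synergy <- function(x, ...) {
  tibble(
    n_cells = nrow(x$grid),
    mean_delta = x$summary$mean_delta,
    max_delta = x$summary$max_delta,
    max_conc_a_um = unname(x$summary$max_cell[1]),
    max_conc_b_um = unname(x$summary$max_cell[2])
  )
}
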