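#' Iterative rank-order (rank-invariant set) normalization
#'
#' Scales every intensity column onto a common reference using only a
#' *rank-invariant* feature set, so that features genuinely changing between
#' samples do not drag the normalization with them. The procedure:
#'
#' 1. If `reference = "auto"`, pick the column whose ranks are closest (in
#'    summed absolute rank displacement) to the pseudo-reference formed by
#'    each feature's median within-column rank (the scale-invariant analogue
#'    of the element-wise median column).
#' 2. Start with all features in the invariant set.
#' 3. Iterate: fit a monotone mapping of each column onto the reference over
#'    the invariant set (quantile mapping between the sorted invariant
#'    values, linearly interpolated; ratio-extrapolated beyond the range),
#'    apply it, measure each invariant feature's residual displacement
#'    (max over columns of |log2(normalized/reference)|), and drop the most
#'    displaced `trim` fraction that still exceeds `stab_tol`.
#' 4. Stop when no invariant feature exceeds `stab_tol` or after `max_iter`
#'    iterations, then re-fit on the final invariant set and center each
#'    column so its median log-ratio to the reference over the invariant set
#'    is exactly zero.
#'
#' @param x Positive numeric matrix (features x samples), >= 2 columns;
#'   impute missing values first.
#' @param reference Column name/index, or `"auto"` (default).
#' @param trim Fraction of the invariant set examined for removal per
#'   iteration (default 0.05).
#' @param max_iter Maximum refinement iterations (default 10).
#' @param stab_tol Residual |log2 ratio| below which an invariant feature is
#'   considered in agreement with the reference (default 0.01).
#' @return An `iron_norm` object: list with `matrix` (normalized
#'   intensities), `scale` (tibble of per-column multiplicative scale
#'   factors, `median(ref/column)` over the final invariant set),
#'   `invariant` (logical vector), `reference`, `iterations`.
#' @export
iron_normalize <- function(x, reference = "auto", trim = 0.05,
                           max_iter = 10, stab_tol = 0.01) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("iron_normalize needs at least 2 columns.")
  if (any(is.na(x)) || any(x <= 0)) {
    abort("All intensities must be present and strictly positive; impute first.")
  }
  cn <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- cn

  ref_idx <- if (identical(reference, "auto")) {
    # per-feature median rank is the scale-invariant analogue of the
    # element-wise median column
    col_ranks <- apply(x, 2, rank)
    pseudo_rank <- apply(col_ranks, 1, median)
    which.min(colSums(abs(col_ranks - pseudo_rank)))
  } else if (is.character(reference)) {
    idx <- match(reference, cn)
    if (is.na(idx)) abort(sprintf("Reference column '%s' not found.", reference))
    idx
  } else {
    as.integer(reference)
  }
  ref <- x[, ref_idx]
  others <- setdiff(seq_len(ncol(x)), ref_idx)

  qmap <- function(col, inv) {
    xs <- sort(col[inv])
    ys <- sort(ref[inv])
    lo <- xs[1]
    hi <- xs[length(xs)]
    out <- approx(xs, ys, xout = pmin(pmax(col, lo), hi), ties = mean)$y
    below <- col < lo
    above <- col > hi
    out[below] <- col[below] * (ys[1] / lo)
    out[above] <- col[above] * (ys[length(ys)] / hi)
    out
  }

  normalize_with <- function(inv) {
    norm <- x
    for (j in others) norm[, j] <- qmap(x[, j], inv)
    norm
  }

  inv <- rep(TRUE, nrow(x))
  it <- 0L
  repeat {
    it <- it + 1L
    norm <- normalize_with(inv)
    disp <- rep(0, nrow(x))
    for (j in others) disp <- pmax(disp, abs(log2(norm[, j] / ref)))
    exceed <- inv & disp > stab_tol
    if (!any(exceed) || it >= max_iter) break
    k <- min(ceiling(trim * sum(inv)), sum(exceed))
    worst <- order(ifelse(inv, disp, -Inf), decreasing = TRUE)[seq_len(k)]
    inv[worst] <- FALSE
  }
  norm <- normalize_with(inv)

  # exact median-log-ratio centering over the final invariant set
  for (j in others) {
    shift <- median(log2(norm[inv, j] / ref[inv]))
    norm[, j] <- norm[, j] / 2^shift
  }
  scale_factor <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref_idx) 1 else median(ref[inv] / x[inv, j])
  }, numeric(1))

  structure(
    list(
      matrix = norm,
      scale = tibble(sample = cn, scale_factor = scale_factor),
      invariant = inv,
      reference = cn[ref_idx],
      iterations = it
    ),
    class = "iron_norm"
  )
}

#' @export
print.iron_norm <- function(x, ...) {
  cat(sprintf(
    "Rank-invariant normalization: reference '%s', %d/%d features in invariant set, %d iteration(s)\n",
    x$reference, sum(x$invariant), length(x$invariant), x$iterations
  ))
  print(x$scale)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.iron_norm <- function(x, ...) x$scale
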