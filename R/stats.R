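#' Impute missing intensities with the column minimum
#'
#' Replaces every missing (`NA`) cell with the smallest present value of its
#' own column. This is the standard left-censoring imputation for
#' intensity-based proteomics, where a value is typically missing because the
#' analyte fell below the detection limit of that run; the lowest observed
#' intensity of the run is then the natural stand-in.
#'
#' @param x Numeric matrix (features in rows, samples in columns). `NA`
#'   marks a missing cell.
#' @return The matrix with every `NA` replaced by its column minimum.
#'   Present values are never altered.
#' @examples
#' m <- cbind(a = c(4, NA, 8), b = c(1, 2, 3))
#' impute_column_min(m)
#' @export
impute_column_min <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("`x` must be a numeric matrix.")
  all_na <- apply(x, 2, function(col) all(is.na(col)))
  if (any(all_na)) {
    bad <- colnames(x)[all_na] %||% which(all_na)
    abort(paste0(
      "Cannot impute: column(s) entirely missing: ",
      paste(if (is.null(colnames(x))) which(all_na) else bad, collapse = ", ")
    ))
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- min(x[!miss, j])
  }
  x
}

#' Log2-transform an intensity matrix
#'
#' Elementwise base-2 logarithm. All values must be strictly positive, i.e.
#' imputation (and, where configured, zero-to-missing conversion) must have
#' run first; a non-positive cell is reported with its coordinates so the
#' skipped step can be found.
#'
#' @param x Numeric matrix or vector of strictly positive intensities.
#' @return `log2(x)`, same shape.
#' @export
log2_transform <- function(x) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    if (is.matrix(x)) {
      i <- ((bad[1] - 1) %% nrow(x)) + 1
      j <- ((bad[1] - 1) %/% nrow(x)) + 1
      abort(sprintf(
        "Non-positive intensity at row %d, column %d; impute before log2-transforming.",
        i, j
      ))
    }
    abort(sprintf("Non-positive intensity at position %d; impute before log2-transforming.", bad[1]))
  }
  log2(x)
}

#' Two-sample t test (Student or Welch)
#'
#' Two-sided comparison of two groups of (typically log2) intensities.
#' The Student variant pools the variance; Welch does not. Degenerate
#' inputs follow fixed conventions: two constant, equal groups give
#' `p = 1` (no evidence of a difference); two constant, unequal groups give
#' `p = 0` with an infinite statistic.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return A list with elements `t` and `p`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 non-missing values.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  res <- stats::t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(res$statistic), p = unname(res$p.value))
}

# Vectorised row-wise pooled-variance two-sample t on two aligned matrices.
# Same degenerate-input conventions as two_sample_t().
row_t_student <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- unname(rowMeans(a))
  mb <- unname(rowMeans(b))
  va <- unname(rowSums((a - ma)^2)) / (na - 1)
  vb <- unname(rowSums((b - mb)^2)) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  df <- na + nb - 2
  p <- 2 * pt(-abs(t), df)
  degen <- se == 0
  if (any(degen)) {
    eq <- degen & (ma == mb)
    t[degen] <- sign(ma[degen] - mb[degen]) * Inf
    p[degen] <- 0
    t[eq] <- 0
    p[eq] <- 1
  }
  list(t = t, p = p, mean_a = ma, mean_b = mb, sd_a = sqrt(va), sd_b = sqrt(vb))
}

# Row-wise one-sample t against 0 (used for paired TMT log2 ratios).
row_t_onesample <- function(r) {
  n <- ncol(r)
  m <- unname(rowMeans(r))
  s <- sqrt(unname(rowSums((r - m)^2)) / (n - 1))
  t <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t), n - 1)
  degen <- s == 0
  if (any(degen)) {
    eq <- degen & (m == 0)
    t[degen] <- sign(m[degen]) * Inf
    p[degen] <- 0
    t[eq] <- 0
    p[eq] <- 1
  }
  list(t = t, p = p, mean = m, sd = s)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement, as
#' implemented by [stats::p.adjust()]. Validates the input range first.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Adaptive fold-change threshold from replicate spread
#'
#' Derives a data-driven cutoff for differential calling: per replicate
#' column, the spread of log2 fold changes across features is estimated;
#' these per-replicate spreads are averaged and multiplied (default 2).
#' Features whose |log2 fold change| exceeds the threshold change more than
#' the bulk of the (predominantly unregulated) measurements do.
#'
#' The default spread estimator is the normal-consistent MAD
#' (`mad()`): with a small fraction of truly regulated features present,
#' the classical standard deviation is inflated by exactly the signal the
#' threshold is meant to detect, whereas the MAD tracks the null spread.
#' `estimator = "sd"` gives the classical standard deviation.
#'
#' @param lfc Numeric matrix of per-replicate log2 fold changes
#'   (features x replicates), >= 2 columns.
#' @param multiplier Positive scale applied to the average spread (default 2).
#' @param estimator `"mad"` (robust, default) or `"sd"`.
#' @param average `"per_replicate"` (default): average the per-column
#'   across-feature spreads; `"per_feature"`: average the per-row
#'   across-replicate spreads.
#' @return An object of class `adaptive_threshold`: a list with
#'   `average_sd`, `multiplier`, `threshold`, and the per-replicate (or
#'   per-feature summary) spreads.
#' @export
adaptive_sd_threshold <- function(lfc, multiplier = 2,
                                  estimator = c("mad", "sd"),
                                  average = c("per_replicate", "per_feature")) {
  estimator <- match.arg(estimator)
  average <- match.arg(average)
  lfc <- as.matrix(lfc)
  if (ncol(lfc) < 2) abort("At least 2 replicate columns are required.")
  if (multiplier <= 0) abort("`multiplier` must be positive.")
  est <- switch(estimator,
    mad = function(v) mad(v, na.rm = TRUE),
    sd = function(v) sd(v, na.rm = TRUE)
  )
  sds <- switch(average,
    per_replicate = apply(lfc, 2, est),
    per_feature = apply(lfc, 1, est)
  )
  avg <- mean(sds)
  structure(
    list(
      average_sd = avg,
      multiplier = multiplier,
      threshold = multiplier * avg,
      per_replicate_sd = if (average == "per_replicate") sds else NULL,
      estimator = estimator,
      average = average
    ),
    class = "adaptive_threshold"
  )
}

#' @export
print.adaptive_threshold <- function(x, ...) {
  cat(sprintf(
    "Adaptive |log2FC| threshold: %.4f (= %g x average %s %.4f, %s)\n",
    x$threshold, x$multiplier, toupper(x$estimator), x$average_sd, x$average
  ))
  invisible(x)
}
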