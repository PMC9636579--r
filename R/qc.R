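#' Quality-control filter for quantification tables
#'
#' Removes decoy (reverse) hits, common contaminants, identifications with a
#' posterior error probability at or above `pep_max`, and features with no
#' intensity in any sample. For reporting, each removed feature is counted
#' once, at the first rule it violates, under the fixed precedence
#' reverse -> contaminant -> PEP -> zero-intensity; the surviving set does
#' not depend on that order.
#'
#' @param x A `quant_tbl` (see [read_quant_table()]).
#' @param pep_max Retain features with `pep < pep_max` (default 0.05).
#'   Features without a PEP value (or tables without a PEP column) are kept.
#' @param drop_reverse,drop_contaminant,drop_all_missing Toggle the
#'   individual rules.
#' @param zero_as_missing Treat zero intensities as missing when deciding
#'   whether a feature has any intensity (default `TRUE`).
#' @return The filtered `quant_tbl`, with the [filter_report()] attached as
#'   an attribute.
#' @examples
#' \dontrun{
#' tab <- read_quant_table("proteinGroups.txt", dialect = "protein_groups")
#' kept <- qc_filter(tab)
#' filter_report(kept)
#' }
#' @export
qc_filter <- function(x, pep_max = 0.05, drop_reverse = TRUE,
                      drop_contaminant = TRUE, drop_all_missing = TRUE,
                      zero_as_missing = TRUE) {
  if (pep_max <= 0 || pep_max > 1) abort("`pep_max` must be in (0, 1].")
  n <- nrow(x)
  rev_viol <- if (drop_reverse && !is.null(qcol(x, "reverse_flag"))) x$reverse_flag else rep(FALSE, n)
  con_viol <- if (drop_contaminant && !is.null(qcol(x, "contaminant_flag"))) x$contaminant_flag else rep(FALSE, n)
  pep_viol <- if (!is.null(qcol(x, "pep"))) !is.na(x$pep) & x$pep >= pep_max else rep(FALSE, n)
  m <- intensity_matrix(x, zero_as_missing = zero_as_missing)
  zero_viol <- if (drop_all_missing) apply(m, 1, function(v) all(is.na(v))) else rep(FALSE, n)

  # precedence: reverse -> contaminant -> PEP -> zero-intensity
  n_rev <- sum(rev_viol)
  n_con <- sum(con_viol & !rev_viol)
  n_pep <- sum(pep_viol & !rev_viol & !con_viol)
  n_zero <- sum(zero_viol & !rev_viol & !con_viol & !pep_viol)
  keep <- !(rev_viol | con_viol | pep_viol | zero_viol)

  report <- structure(
    list(
      n_input = n,
      n_removed_reverse = n_rev,
      n_removed_contaminant = n_con,
      n_removed_pep = n_pep,
      n_removed_zero_intensity = n_zero,
      n_output = sum(keep)
    ),
    class = "filter_report"
  )
  out <- new_quant_tbl(x[keep, , drop = FALSE], sample_ids(x), attr(x, "dialect"))
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the QC filter report
#' @param x A `quant_tbl` returned by [qc_filter()].
#' @return A `filter_report` (list of counts), or `NULL` if `x` was not
#'   filtered.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "QC filter: %d features in, %d out\n",
      "  removed: %d reverse, %d contaminant, %d PEP, %d zero-intensity\n"
    ),
    x$n_input, x$n_output, x$n_removed_reverse, x$n_removed_contaminant,
    x$n_removed_pep, x$n_removed_zero_intensity
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.filter_report <- function(x, ...) {
  tibble(
    rule = c("input", "reverse", "contaminant", "pep", "zero_intensity", "output"),
    n = c(x$n_input, x$n_removed_reverse, x$n_removed_contaminant,
          x$n_removed_pep, x$n_removed_zero_intensity, x$n_output)
  )
}
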