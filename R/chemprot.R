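#' Bundle pulldown and competition-control intensity matrices
#'
#' A competitive chemical-proteomics experiment for one probe in one cell
#' line: iBAQ intensities of the drug-bead pulldown (PD) and of the
#' competition control (CT, lysate preincubated with free drug, which
#' scavenges true targets).
#'
#' @param pd,ct Numeric matrices (features x replicates, iBAQ scale) with
#'   identical row order; `NA` marks missing.
#' @param feature_id Character vector of feature ids (defaults to the
#'   rownames of `pd`).
#' @param probe Probe name, e.g. `"c-olaparib"`.
#' @param cell_line Cell line label, e.g. `"UWB"`.
#' @param gene_symbol Optional gene symbols parallel to `feature_id`.
#' @return A `pulldown_set` object.
#' @export
pulldown_set <- function(pd, ct, feature_id = rownames(pd), probe, cell_line,
                         gene_symbol = NULL) {
  pd <- as.matrix(pd)
  ct <- as.matrix(ct)
  if (is.null(feature_id)) abort("`feature_id` is required (or rownames on `pd`).")
  if (nrow(pd) != nrow(ct) || nrow(pd) != length(feature_id)) {
    abort("`pd`, `ct` and `feature_id` must agree on the number of features.")
  }
  if (!is.null(rownames(ct)) && !identical(rownames(pd), rownames(ct))) {
    abort("`pd` and `ct` feature indices differ.")
  }
  if (ncol(pd) < 2 || ncol(ct) < 2) abort("At least 2 replicates are required in PD and CT.")
  if (any(pd < 0, na.rm = TRUE) || any(ct < 0, na.rm = TRUE)) {
    abort("Intensities must be non-negative.")
  }
  rownames(pd) <- rownames(ct) <- feature_id
  structure(
    list(pd = pd, ct = ct, feature_id = feature_id, probe = probe,
         cell_line = cell_line, gene_symbol = gene_symbol),
    class = "pulldown_set"
  )
}

#' @export
print.pulldown_set <- function(x, ...) {
  cat(sprintf(
    "Pulldown set: probe %s, cell line %s, %d features, %d PD / %d CT replicates\n",
    x$probe, x$cell_line, length(x$feature_id), ncol(x$pd), ncol(x$ct)
  ))
  invisible(x)
}

#' Build a pulldown_set from a quant_tbl and a sample design
#'
#' Selects the columns whose design role is `pulldown` / `competition` for
#' the given cell line (replicate-ordered).
#'
#' @param x A `quant_tbl`.
#' @param design Sample design (see [read_sample_design()]).
#' @param probe Probe label to record.
#' @param cell_line Cell line to extract.
#' @return A `pulldown_set`.
#' @export
as_pulldown_set <- function(x, design, probe, cell_line) {
  pd_d <- design_samples(design, "pulldown", cell_line)
  ct_d <- design_samples(design, "competition", cell_line)
  if (!nrow(pd_d) || !nrow(ct_d)) {
    abort(sprintf("Design has no pulldown/competition samples for cell line '%s'.", cell_line))
  }
  pulldown_set(
    pd = intensity_matrix(x, pd_d$sample_id),
    ct = intensity_matrix(x, ct_d$sample_id),
    feature_id = x$feature_id, probe = probe, cell_line = cell_line,
    gene_symbol = qcol(x, "gene_symbol")
  )
}

#' Relative iBAQ (riBAQ) within one sample
#'
#' Divides each protein's iBAQ by the sample total, giving within-sample
#' relative molar abundance. Missing entries stay missing and are excluded
#' from the total.
#'
#' @param x Non-negative numeric vector (one sample's iBAQ values).
#' @return Vector of the same length summing to 1 over present entries.
#' @examples
#' compute_ribaq(c(3, 1))
#' @export
compute_ribaq <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("iBAQ values must be non-negative.")
  tot <- sum(x, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) abort("Cannot compute riBAQ: no positive iBAQ value in sample.")
  x / tot
}

#' Score specific drug-bead interactors (pulldown vs competition)
#'
#' Calls a protein a *specific* interactor when it is enriched in the
#' pulldown over the competition control beyond `fc_cutoff` on the log2
#' scale with a Student's t p-value below `p_cutoff`. Pipeline:
#' zeros treated as missing, column-minimum imputation, log2 transform,
#' per-feature mean log2(PD) - mean log2(CT) and pooled-variance t test
#' across replicates. Note the cutoff applies to the log2 ratio, i.e. a
#' raw-scale fold change of 2^1.5 (about 2.8) at the default.
#'
#' @param ps A [pulldown_set()].
#' @param fc_cutoff Specificity cutoff on the log2 PD/CT ratio (default 1.5,
#'   strict `>`).
#' @param p_cutoff p-value cutoff (default 0.05, strict `<`).
#' @param zero_as_missing Treat zero iBAQ as missing before imputation.
#' @return A tibble of interactor calls: `feature_id`, `probe`, `cell_line`,
#'   `log2fc_pd_ct`, `p_pd_ct`, `specific`, plus group means/SDs on the log2
#'   scale.
#' @export
score_competition <- function(ps, fc_cutoff = 1.5, p_cutoff = 0.05,
                              zero_as_missing = TRUE) {
  stopifnot(inherits(ps, "pulldown_set"))
  m <- cbind(ps$pd, ps$ct)
  if (zero_as_missing) m[m == 0] <- NA_real_
  m <- log2_transform(impute_column_min(m))
  pd <- m[, seq_len(ncol(ps$pd)), drop = FALSE]
  ct <- m[, ncol(ps$pd) + seq_len(ncol(ps$ct)), drop = FALSE]
  tt <- row_t_student(pd, ct)
  out <- tibble(
    feature_id = ps$feature_id,
    probe = ps$probe,
    cell_line = ps$cell_line,
    log2fc_pd_ct = tt$mean_a - tt$mean_b,
    p_pd_ct = tt$p,
    specific = (tt$mean_a - tt$mean_b) > fc_cutoff & tt$p < p_cutoff,
    mean_pd_log2 = tt$mean_a,
    mean_ct_log2 = tt$mean_b,
    sd_pd_log2 = tt$sd_a,
    sd_ct_log2 = tt$sd_b
  )
  if (!is.null(ps$gene_symbol)) out <- dplyr::mutate(out, gene_symbol = ps$gene_symbol, .after = "feature_id")
  out
}

#' Differential interactors between two cell lines via riBAQ
#'
#' Compares the relative abundance (riBAQ) of each interactor in the
#' pulldowns of two cell lines. riBAQ is computed per pulldown replicate;
#' the per-feature ratio of mean riBAQ (line A / line B) and a Student's t
#' test on the replicate riBAQ values give the call:
#' `A` if ratio > `ratio_cutoff` and p < `p_cutoff`, `B` if
#' ratio < 1/`ratio_cutoff` and p < `p_cutoff`, else `none`. The cutoff is
#' on the raw riBAQ ratio (not log2). Features absent from one line are
#' treated as missing and imputed with the minimum present riBAQ of that
#' sample before ratios are formed.
#'
#' @param line_a,line_b [pulldown_set()]s sharing the same probe.
#' @param ratio_cutoff Raw riBAQ ratio cutoff (default 1.5).
#' @param p_cutoff p-value cutoff (default 0.1).
#' @param log_scale Run the t test on log2 riBAQ instead of raw riBAQ
#'   (default `FALSE`).
#' @param zero_as_missing Treat zero iBAQ as missing.
#' @return Tibble: `feature_id`, `probe`, `ribaq_line_a`, `ribaq_line_b`
#'   (means), `ribaq_ratio`, `p_lines`, `line_enriched` (factor A/B/none),
#'   `cell_line_a`, `cell_line_b`.
#' @export
cross_line_differential <- function(line_a, line_b, ratio_cutoff = 1.5,
                                    p_cutoff = 0.1, log_scale = FALSE,
                                    zero_as_missing = TRUE) {
  stopifnot(inherits(line_a, "pulldown_set"), inherits(line_b, "pulldown_set"))
  if (!identical(line_a$probe, line_b$probe)) {
    abort(sprintf("Probe mismatch: '%s' vs '%s'.", line_a$probe, line_b$probe))
  }
  features <- union(line_a$feature_id, line_b$feature_id)

  align <- function(m, ids) {
    out <- matrix(NA_real_, length(features), ncol(m),
                  dimnames = list(features, colnames(m)))
    out[ids, ] <- m
    out
  }
  ribaq_mat <- function(pd) {
    if (zero_as_missing) pd[pd == 0] <- NA_real_
    apply(pd, 2, compute_ribaq)
  }
  ra <- impute_column_min(align(ribaq_mat(line_a$pd), line_a$feature_id))
  rb <- impute_column_min(align(ribaq_mat(line_b$pd), line_b$feature_id))

  tt <- if (log_scale) row_t_student(log2(ra), log2(rb)) else row_t_student(ra, rb)
  mean_a <- unname(rowMeans(ra))
  mean_b <- unname(rowMeans(rb))
  ratio <- mean_a / mean_b
  enriched <- dplyr::case_when(
    ratio > ratio_cutoff & tt$p < p_cutoff ~ "A",
    ratio < 1 / ratio_cutoff & tt$p < p_cutoff ~ "B",
    .default = "none"
  )
  tibble(
    feature_id = features,
    probe = line_a$probe,
    ribaq_line_a = mean_a,
    ribaq_line_b = mean_b,
    ribaq_ratio = ratio,
    p_lines = tt$p,
    line_enriched = factor(enriched, levels = c("A", "B", "none")),
    cell_line_a = line_a$cell_line,
    cell_line_b = line_b$cell_line
  )
}

#' Merge interactor calls from two probes
#'
#' Outer join of two call tables on `feature_id`, labelling each feature
#' with the probe(s) it was observed with. No call values are altered.
#'
#' @param calls_probe1,calls_probe2 Call tibbles (e.g. from
#'   [score_competition()]) keyed by `feature_id`.
#' @return Tibble with a `probes` column: the probe name for single-probe
#'   features, `"both"` for features in both lists, plus all columns of the
#'   inputs suffixed `_probe1` / `_probe2`.
#' @export
merge_probes <- function(calls_probe1, calls_probe2) {
  p1 <- unique(calls_probe1$probe) %||% "probe1"
  p2 <- unique(calls_probe2$probe) %||% "probe2"
  p1 <- if (length(p1) == 1) p1 else "probe1"
  p2 <- if (length(p2) == 1) p2 else "probe2"
  joined <- dplyr::full_join(
    calls_probe1, calls_probe2,
    by = "feature_id", suffix = c("_probe1", "_probe2")
  )
  in1 <- joined$feature_id %in% calls_probe1$feature_id
  in2 <- joined$feature_id %in% calls_probe2$feature_id
  dplyr::mutate(
    joined,
    probes = dplyr::case_when(in1 & in2 ~ "both", in1 ~ p1, .default = p2),
    .after = "feature_id"
  )
}
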