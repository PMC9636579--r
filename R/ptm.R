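#' Precursor mass-error gate
#'
#' Phosphopeptide identifications are kept only when the signed precursor
#' mass error lies within `tol` ppm (closed interval: exactly +/- `tol`
#' passes). If no mass-error values are available the gate becomes a no-op
#' (all `TRUE`) with a warning.
#'
#' @param mass_error_ppm Signed mass errors (ppm), or `NULL` if absent.
#' @param tol Tolerance in ppm (default 3).
#' @param n Length of the output when `mass_error_ppm` is `NULL`.
#' @return Logical vector.
#' @export
ppm_gate <- function(mass_error_ppm, tol = 3, n = length(mass_error_ppm)) {
  if (is.null(mass_error_ppm) || all(is.na(mass_error_ppm))) {
    warn("No mass-error values available; ppm gate passes all features.")
    return(rep(TRUE, n))
  }
  out <- abs(mass_error_ppm) <= tol
  out[is.na(out)] <- TRUE
  out
}

# Assemble a DifferentialResult tibble and attach metadata.
new_parp_diff <- function(tbl, threshold = NULL, contrast = NULL) {
  structure(
    tbl,
    threshold = threshold,
    contrast = contrast,
    class = c("parp_diff", class(tbl))
  )
}

#' Differential phosphorylation from a TMT experiment
#'
#' Calls rucaparib-regulated phosphosites from reporter-ion intensities.
#' Pipeline: zeros to missing, column-minimum imputation, iterative
#' rank-order normalization across all channels, log2 transform,
#' per-feature replicate-wise log2 ratios (treated - vehicle channel of the
#' same replicate pair), Student's t test of the replicate ratios against
#' zero, and an adaptive fold-change threshold of
#' `sd_multiplier` x the average per-replicate spread of the ratios
#' ([adaptive_sd_threshold()]). A site passes when
#' `|log2fc| > threshold` (strict), `p < p_cutoff`, and its precursor mass
#' error is within `ppm_tol` ppm.
#'
#' @param quant A `quant_tbl` of phosphosite reporter intensities (run
#'   [qc_filter()] first).
#' @param design Sample design with `treated` / `vehicle` roles whose
#'   `replicate` values pair the channels.
#' @param cell_line Optional cell line to restrict the design to.
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param sd_multiplier Multiplier for the adaptive threshold (default 2).
#' @param ppm_tol Mass-error tolerance in ppm (default 3).
#' @param normalize Run [iron_normalize()] (default `TRUE`).
#' @param reference Reference column for normalization (default `"auto"`).
#' @param sd_estimator Spread estimator for the threshold (`"mad"` default;
#'   see [adaptive_sd_threshold()]).
#' @param zero_as_missing Treat zero intensities as missing.
#' @return A `parp_diff` tibble: `feature_id`, `gene_symbol`, `log2fc`,
#'   `p_value`, `q_value`, per-arm means/SDs (log2), `pass_fc`, `pass_p`,
#'   `pass_ppm`, `passes`. The [adaptive_sd_threshold()] object is attached
#'   and reported by [glance()].
#' @export
phospho_differential <- function(quant, design, cell_line = NULL,
                                 p_cutoff = 0.05, sd_multiplier = 2,
                                 ppm_tol = 3, normalize = TRUE,
                                 reference = "auto",
                                 sd_estimator = c("mad", "sd"),
                                 zero_as_missing = TRUE) {
  sd_estimator <- match.arg(sd_estimator)
  trt <- design_samples(design, "treated", cell_line)
  veh <- design_samples(design, "vehicle", cell_line)
  if (nrow(trt) < 2 || nrow(veh) < 2) {
    abort("At least 2 treated and 2 vehicle channels are required.")
  }
  if (!identical(trt$replicate, veh$replicate)) {
    abort("Treated and vehicle channels do not pair up by replicate in the design.")
  }
  m <- intensity_matrix(quant, c(trt$sample_id, veh$sample_id),
                        zero_as_missing = zero_as_missing)
  m <- impute_column_min(m)
  if (normalize) m <- iron_normalize(m, reference = reference)$matrix
  m <- log2_transform(m)
  tm <- m[, trt$sample_id, drop = FALSE]
  vm <- m[, veh$sample_id, drop = FALSE]
  ratios <- tm - vm
  thr <- adaptive_sd_threshold(ratios, multiplier = sd_multiplier,
                               estimator = sd_estimator)
  tt <- row_t_onesample(ratios)
  gate <- ppm_gate(qcol(quant, "mass_error_ppm"), tol = ppm_tol, n = nrow(quant))
  lfc <- tt$mean
  out <- tibble(
    feature_id = quant$feature_id,
    gene_symbol = qcol(quant, "gene_symbol") %||% NA_character_,
    log2fc = lfc,
    p_value = tt$p,
    q_value = bh_adjust(tt$p),
    mean_treated = unname(rowMeans(tm)),
    mean_vehicle = unname(rowMeans(vm)),
    sd_treated = unname(apply(tm, 1, sd)),
    sd_vehicle = unname(apply(vm, 1, sd)),
    pass_fc = abs(lfc) > thr$threshold,
    pass_p = tt$p < p_cutoff,
    pass_ppm = gate,
    passes = abs(lfc) > thr$threshold & tt$p < p_cutoff & gate
  )
  new_parp_diff(out, threshold = thr,
                contrast = "phospho: treated - vehicle (log2, normalized)")
}

#' Differential ADP-ribosylation from label-free intensities
#'
#' Compares rucaparib-treated to vehicle (DMSO) protein intensities after
#' column-minimum imputation and log2 transformation, using a per-protein
#' pooled-variance Student's t test. A protein passes when
#' `|log2fc| >= log2(fc_cutoff_raw)` (inclusive at the stated raw
#' fold-change cutoff of 2) and, when `use_p`, `p < p_cutoff`. Negative
#' `log2fc` means decreased ADP-ribosylation under drug.
#'
#' @param quant A `quant_tbl` of label-free protein intensities (run
#'   [qc_filter()] first).
#' @param design Sample design with `treated` / `vehicle` roles.
#' @param cell_line Optional cell line restriction.
#' @param fc_cutoff_raw Raw-scale fold-change cutoff (default 2).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param use_p Apply the p-value gate (default `TRUE`; the fold-change gate
#'   alone reproduces the bare intensity-ratio criterion).
#' @param zero_as_missing Treat zero intensities as missing.
#' @return A `parp_diff` tibble (same columns as
#'   [phospho_differential()], without the ppm gate).
#' @export
adpr_differential <- function(quant, design, cell_line = NULL,
                              fc_cutoff_raw = 2, p_cutoff = 0.05,
                              use_p = TRUE, zero_as_missing = TRUE) {
  trt <- design_samples(design, "treated", cell_line)
  veh <- design_samples(design, "vehicle", cell_line)
  if (nrow(trt) < 2 || nrow(veh) < 2) {
    abort("At least 2 replicates per arm are required.")
  }
  m <- intensity_matrix(quant, c(trt$sample_id, veh$sample_id),
                        zero_as_missing = zero_as_missing)
  m <- log2_transform(impute_column_min(m))
  tm <- m[, trt$sample_id, drop = FALSE]
  vm <- m[, veh$sample_id, drop = FALSE]
  tt <- row_t_student(tm, vm)
  lfc <- tt$mean_a - tt$mean_b
  lfc_cut <- log2(fc_cutoff_raw)
  pass_p <- if (use_p) tt$p < p_cutoff else rep(TRUE, nrow(quant))
  out <- tibble(
    feature_id = quant$feature_id,
    gene_symbol = qcol(quant, "gene_symbol") %||% NA_character_,
    log2fc = lfc,
    p_value = tt$p,
    q_value = bh_adjust(tt$p),
    mean_treated = tt$mean_a,
    mean_vehicle = tt$mean_b,
    sd_treated = tt$sd_a,
    sd_vehicle = tt$sd_b,
    pass_fc = abs(lfc) >= lfc_cut,
    pass_p = pass_p,
    passes = abs(lfc) >= lfc_cut & pass_p
  )
  new_parp_diff(out, contrast = "ADPr: treated - vehicle (log2)")
}

#' @exportS3Method generics::glance
glance.parp_diff <- function(x, ...) {
  thr <- attr(x, "threshold")
  tibble(
    n = nrow(x),
    n_pass = sum(x$passes),
    threshold = if (!is.null(thr)) thr$threshold else NA_real_,
    average_sd = if (!is.null(thr)) thr$average_sd else NA_real_,
    contrast = attr(x, "contrast") %||% NA_character_
  )
}
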