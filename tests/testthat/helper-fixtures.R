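# In-code fixtures shared across test files.

write_toy_protein_groups <- function(path,
                                     ids = c("P09874", "Q9UGN5", "O95271"),
                                     reverse = c("", "+", ""),
                                     contaminant = c("", "", "+"),
                                     pep = c(0.001, 0.02, 0.001),
                                     ibaq_a = c(100, 200, 300),
                                     ibaq_b = c(10, 20, 30)) {
  lines <- c(
    "Majority protein IDs\tiBAQ A\tiBAQ B\tReverse\tPotential contaminant\tPEP",
    sprintf("%s\t%g\t%g\t%s\t%s\t%g", ids, ibaq_a, ibaq_b, reverse, contaminant, pep)
  )
  writeLines(lines, path)
  path
}

# quant_tbl built directly in memory (generic dialect sample columns s1..s_k)
make_quant <- function(intensities, pep = NULL, reverse = NULL,
                       contaminant = NULL, mass_error = NULL,
                       feature_id = NULL) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  feature_id <- feature_id %||% sprintf("F%03d", seq_len(n))
  sids <- colnames(intensities) %||% paste0("s", seq_len(ncol(intensities)))
  tab <- tibble::tibble(feature_id = feature_id)
  if (!is.null(pep)) tab$pep <- pep
  if (!is.null(reverse)) tab$reverse_flag <- reverse
  if (!is.null(contaminant)) tab$contaminant_flag <- contaminant
  if (!is.null(mass_error)) tab$mass_error_ppm <- mass_error
  for (k in seq_along(sids)) tab[[sids[k]]] <- intensities[, k]
  parpiomics:::new_quant_tbl(tab, sids, "generic")
}

make_design <- function(sample_id, role, replicate = NULL,
                        treatment = NULL, cell_line = "UWB") {
  replicate <- replicate %||% stats::ave(seq_along(role), role, FUN = seq_along)
  treatment <- treatment %||% ifelse(role %in% c("treated", "pulldown"), "drug", "DMSO")
  tibble::tibble(
    sample_id = sample_id, cell_line = cell_line,
    treatment = treatment, role = role, replicate = as.integer(replicate)
  )
}

`%||%` <- rlang::`%||%`
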