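# quiet column accessor: NULL when the column is absent
qcol <- function(x, name) if (name %in% names(x)) x[[name]] else NULL

MQ_DIALECTS <- list(
  protein_groups = list(id_col = "Majority protein IDs", intensity_prefix = "iBAQ "),
  phospho_sites  = list(id_col = "Site ID", intensity_prefix = "Reporter intensity corrected "),
  generic        = list(id_col = "Feature ID", intensity_prefix = "Intensity ")
)

OPTIONAL_COLS <- c(
  pep = "PEP",
  reverse_flag = "Reverse",
  contaminant_flag = "Potential contaminant",
  mass_error_ppm = "Mass error [ppm]",
  localization_prob = "Localization prob"
)

#' Read a MaxQuant-dialect quantification table
#'
#' Parses a tab-separated quantification table (proteinGroups-like,
#' phospho-site-like, or a generic intensity table) into a `quant_tbl`:
#' a tibble with one row per feature, metadata columns, and one numeric
#' intensity column per sample. Intensity columns are discovered by header
#' prefix (configurable; MaxQuant dialects vary across versions) and the
#' prefix is stripped so column names become sample ids. A `'+'` in the
#' `Reverse` / `Potential contaminant` columns is mapped to `TRUE`.
#'
#' Zero intensities are preserved as zeros here; downstream steps decide
#' whether zero means "missing" (the default in the differential pipelines).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect `"protein_groups"` (id `Majority protein IDs`, prefix
#'   `"iBAQ "`), `"phospho_sites"` (id `Site ID`, prefix
#'   `"Reporter intensity corrected "`), or `"generic"` (id `Feature ID`,
#'   prefix `"Intensity "`).
#' @param id_col,intensity_prefix Override the dialect defaults.
#' @param gene_col Column holding gene symbols (default `"Gene names"`).
#' @return A `quant_tbl` tibble with columns `feature_id`, `gene_symbol`
#'   (if present), any of `pep`, `reverse_flag`, `contaminant_flag`,
#'   `mass_error_ppm`, `localization_prob` that the file provides, followed
#'   by one numeric column per sample. Sample ids are stored in
#'   `attr(, "sample_ids")`.
#' @export
read_quant_table <- function(path,
                             dialect = c("generic", "protein_groups", "phospho_sites"),
                             id_col = NULL, intensity_prefix = NULL,
                             gene_col = "Gene names") {
  dialect <- match.arg(dialect)
  id_col <- id_col %||% MQ_DIALECTS[[dialect]]$id_col
  intensity_prefix <- intensity_prefix %||% MQ_DIALECTS[[dialect]]$intensity_prefix

  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (!id_col %in% names(raw)) {
    abort(sprintf("Format error: required column '%s' is absent from '%s'.", id_col, path))
  }
  icols <- setdiff(
    names(raw)[startsWith(names(raw), intensity_prefix)],
    trimws(intensity_prefix)
  )
  if (!length(icols)) {
    abort(sprintf("Format error: no intensity columns with prefix '%s' found.", intensity_prefix))
  }

  ids <- raw[[id_col]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("Duplicate feature IDs: ", paste(dup, collapse = ", ")))
  }

  parse_num <- function(col, name, allow_na = FALSE) {
    blank <- is.na(col) | col == "" | col == "NA" | col == "NaN"
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!blank & is.na(out))
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' in column '%s', row %d.", col[bad[1]], name, bad[1]))
    }
    out
  }

  out <- tibble(feature_id = ids)
  if (gene_col %in% names(raw)) out$gene_symbol <- raw[[gene_col]]
  for (field in names(OPTIONAL_COLS)) {
    src <- OPTIONAL_COLS[[field]]
    if (!src %in% names(raw)) next
    out[[field]] <- if (field %in% c("reverse_flag", "contaminant_flag")) {
      !is.na(raw[[src]]) & raw[[src]] == "+"
    } else {
      parse_num(raw[[src]], src)
    }
  }
  sample_ids <- substring(icols, nchar(intensity_prefix) + 1)
  for (k in seq_along(icols)) {
    out[[sample_ids[k]]] <- parse_num(raw[[icols[k]]], icols[k])
  }
  new_quant_tbl(out, sample_ids, dialect)
}

new_quant_tbl <- function(x, sample_ids, dialect = "generic") {
  stopifnot(all(sample_ids %in% names(x)))
  structure(
    as_tibble(x),
    sample_ids = sample_ids,
    dialect = dialect,
    class = c("quant_tbl", class(as_tibble(x)))
  )
}

#' Sample ids of a quant_tbl
#' @param x A `quant_tbl`.
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(x) attr(x, "sample_ids")

#' Extract the intensity matrix of a quant_tbl
#'
#' @param x A `quant_tbl`.
#' @param samples Optional subset/order of sample ids.
#' @param zero_as_missing Convert zeros to `NA` (the downstream default for
#'   label-free and iBAQ data, where a stored zero means "not detected").
#' @return Numeric matrix, rows named by `feature_id`.
#' @export
intensity_matrix <- function(x, samples = NULL, zero_as_missing = FALSE) {
  samples <- samples %||% sample_ids(x)
  missing_cols <- setdiff(samples, names(x))
  if (length(missing_cols)) {
    abort(paste0("Sample column(s) not in table: ", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(x[samples]))
  rownames(m) <- x$feature_id
  if (zero_as_missing) m[m == 0] <- NA_real_
  m
}

#' Write a quant_tbl in the generic tab-separated dialect
#'
#' Intensity columns are written as `Intensity <sample_id>`, flags as `'+'`
#' marks, and numeric values at full double precision so a
#' read-back with [read_quant_table()] reproduces the table exactly.
#'
#' @param x A `quant_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  sids <- sample_ids(x)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- list("Feature ID" = x$feature_id)
  if (!is.null(qcol(x, "gene_symbol"))) out[["Gene names"]] <- x$gene_symbol
  for (field in names(OPTIONAL_COLS)) {
    if (is.null(x[[field]])) next
    out[[OPTIONAL_COLS[[field]]]] <- if (is.logical(x[[field]])) {
      ifelse(x[[field]], "+", "")
    } else {
      fmt(x[[field]])
    }
  }
  for (s in sids) out[[paste0("Intensity ", s)]] <- fmt(x[[s]])
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Read a sample-design table
#'
#' The design maps each intensity column to its experimental role. Required
#' CSV columns: `sample_id`, `cell_line`, `treatment`, `role` (one of
#' `pulldown`, `competition`, `treated`, `vehicle`), `replicate`; optional
#' `channel` (TMT label).
#'
#' @param path CSV path, or a data frame already in memory.
#' @return A validated tibble.
#' @export
read_sample_design <- function(path) {
  d <- if (is.data.frame(path)) as_tibble(path) else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  req <- c("sample_id", "cell_line", "treatment", "role", "replicate")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    abort(paste0("Sample design is missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_role <- setdiff(unique(d$role), c("pulldown", "competition", "treated", "vehicle"))
  if (length(bad_role)) {
    abort(paste0("Unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  key <- paste(d$cell_line, d$treatment, d$role, d$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (cell_line, treatment, role, replicate) combinations in design.")
  }
  if (anyDuplicated(d$sample_id)) abort("Duplicate sample_id in design.")
  d$replicate <- as.integer(d$replicate)
  d
}

# Columns of `design` restricted to one role, ordered by replicate.
design_samples <- function(design, role, cell_line = NULL) {
  d <- design[design$role == role, , drop = FALSE]
  if (!is.null(cell_line)) d <- d[d$cell_line == cell_line, , drop = FALSE]
  d[order(d$replicate), , drop = FALSE]
}
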