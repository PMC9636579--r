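#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `set name`, `description`
#' (discarded), then gene symbols. Genes are uppercased and deduplicated
#' within each set.
#'
#' @param path Path to a GMT file.
#' @param name Collection name (defaults to the file name).
#' @return A `gene_set_collection`: list with `name`, `sets` (named list of
#'   character vectors) and `universe` (union of all set members).
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("GMT file '%s' is empty.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", short[1]))
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  gene_set_collection(sets, name = name)
}

#' Construct a gene-set collection from a named list
#' @param sets Named list of gene-symbol vectors.
#' @param name Collection name.
#' @param universe Optional explicit gene universe; defaults to the union
#'   of all set members.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, name = "collection", universe = NULL) {
  if (!length(sets) || is.null(names(sets))) abort("`sets` must be a non-empty named list.")
  sets <- lapply(sets, function(g) unique(toupper(g)))
  if (any(lengths(sets) == 0)) abort("Empty gene sets are not allowed.")
  universe <- if (is.null(universe)) {
    sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    sort(unique(toupper(universe)))
  }
  structure(list(name = name, sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets, %d genes in universe\n",
              x$name, length(x$sets), length(x$universe)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_set_collection <- function(x, ...) {
  tibble(
    set_name = rep(names(x$sets), lengths(x$sets)),
    gene = unlist(x$sets, use.names = FALSE)
  )
}

#' Hypergeometric over-representation analysis
#'
#' One-sided (enrichment-only) hypergeometric test of a query gene list
#' against every set of a collection: with universe size `N`, set size `K`
#' (after intersection with the universe), query size `n` and overlap `k`,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. The enrichment factor
#' is `(k/n) / (K/N)`. Benjamini-Hochberg q-values are computed across all
#' sets of the collection.
#'
#' The universe should normally be the genes *detected* in the experiment
#' the query came from (testing against the detected proteome avoids
#' detection bias), not the whole genome.
#'
#' @param query Character vector of gene symbols (uppercased internally).
#'   Genes outside the universe are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param universe Gene universe (default: the collection's universe).
#' @return A tibble with one row per set: `set_name`, `overlap`,
#'   `query_size`, `set_size`, `universe_size`, `enrichment_factor`,
#'   `p_value`, `q_value`, `overlap_genes` (list column).
#' @examples
#' gs <- gene_set_collection(list(S = LETTERS[1:5]), universe = LETTERS[1:10])
#' ora_test(LETTERS[2:5], gs)
#' @export
ora_test <- function(query, collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- if (is.null(universe)) collection$universe else sort(unique(toupper(universe)))
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe were dropped.", length(outside)))
    query <- setdiff(query, outside)
  }
  if (!length(query)) abort("Query is empty after intersection with the universe.")
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map(names(collection$sets), function(sn) {
    set <- intersect(collection$sets[[sn]], universe)
    K <- length(set)
    hits <- intersect(query, set)
    k <- length(hits)
    tibble(
      set_name = sn,
      overlap = k,
      query_size = n,
      set_size = K,
      universe_size = N,
      enrichment_factor = if (K > 0) (k / n) / (K / N) else NA_real_,
      p_value = if (K > 0) phyper(k - 1, K, N - K, n, lower.tail = FALSE) else 1,
      overlap_genes = list(sort(hits))
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, q_value = bh_adjust(.data$p_value), .after = "p_value")
}

#' Filter over-representation results
#'
#' Keeps terms with `overlap >= min_overlap`, `p_value < p_cutoff` and
#' `enrichment_factor >= min_enrichment`, sorted by p-value.
#'
#' @param results Tibble from [ora_test()].
#' @param min_overlap Minimum overlap count (default 3).
#' @param p_cutoff p-value cutoff (default 0.01).
#' @param min_enrichment Minimum enrichment factor (default 1.5).
#' @return The passing rows of `results`, sorted by `p_value`, with a
#'   `passes` column (all `TRUE`).
#' @export
filter_terms <- function(results, min_overlap = 3, p_cutoff = 0.01,
                         min_enrichment = 1.5) {
  out <- dplyr::mutate(
    results,
    passes = .data$overlap >= min_overlap &
      .data$p_value < p_cutoff &
      !is.na(.data$enrichment_factor) &
      .data$enrichment_factor >= min_enrichment
  )
  dplyr::arrange(dplyr::filter(out, .data$passes), .data$p_value)
}

#' Combine phosphoproteomics and ADP-ribosylome hit lists
#'
#' Unions the two gene lists with a source flag, producing the joint query
#' used for integrated pathway over-representation analysis.
#'
#' @param phospho_hits,adpr_hits Character vectors of gene symbols.
#' @return Tibble with columns `gene` and `source`
#'   (`"phospho"`, `"adpr"`, or `"both"`), sorted by gene.
#' @examples
#' integrate_omics_lists(c("PRKDC", "MAPK3"), c("AKT2", "MAPK3"))
#' @export
integrate_omics_lists <- function(phospho_hits, adpr_hits) {
  ph <- unique(toupper(phospho_hits))
  ad <- unique(toupper(adpr_hits))
  genes <- sort(union(ph, ad))
  tibble(
    gene = genes,
    source = dplyr::case_when(
      genes %in% ph & genes %in% ad ~ "both",
      genes %in% ph ~ "phospho",
      .default = "adpr"
    )
  )
}
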