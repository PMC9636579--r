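# Seeded synthetic-data generators with planted ground truth. These emulate
# the table shapes the pipeline consumes (iBAQ pulldown tables, TMT reporter
# intensities, label-free intensities, viability grids) so every stage can be
# exercised and validated at desk scale.

# Intensity-dependent (left-censored) missingness: the probability that a
# cell is missing decays logistically with its log2 intensity, calibrated so
# the expected missing fraction of each column equals `rate`. This mirrors
# how MS dropout actually arises (analytes near the detection limit), and it
# is the regime in which column-minimum imputation is meaningful.
censor_low <- function(log2_mat, rate, steepness = 0.3) {
  if (rate <= 0) return(log2_mat)
  for (j in seq_len(ncol(log2_mat))) {
    x <- log2_mat[, j]
    f <- function(L) mean(stats::plogis((L - x) / steepness)) - rate
    L <- stats::uniroot(f, range(x) + c(-10, 10))$root
    miss <- runif(length(x)) < stats::plogis((L - x) / steepness)
    if (all(miss)) miss[which.max(x)] <- FALSE
    log2_mat[miss, j] <- NA_real_
  }
  log2_mat
}

mat_with_names <- function(m, features, samples) {
  dimnames(m) <- list(features, samples)
  m
}

#' Simulate a two-line competitive chemical-proteomics experiment
#'
#' Generates iBAQ pulldown (PD) and competition-control (CT) matrices for
#' two isogenic cell lines with planted ground truth. Baseline log2 iBAQs
#' are drawn from N(`baseline_mean`, `baseline_sd`); the CT signal of every
#' planted binder (specific and line-enriched alike) is attenuated by
#' `2^log2_effect`; line-enriched binders are additionally reduced
#' `line_ratio`-fold in line B's pulldown; multiplicative log-normal noise
#' of SD `noise_sd_log2` (log2 units) is added per cell; and about
#' `miss_rate` of cells are set missing by intensity-dependent
#' left-censoring to exercise the column-minimum imputation.
#'
#' @param n_features Number of protein groups (default 2000).
#' @param n_specific Planted specific binders, equal in both lines
#'   (default 20).
#' @param n_line_diff Planted binders enriched in line A over line B
#'   (default 20).
#' @param log2_effect PD/CT log2 enrichment of planted binders (default 3).
#' @param line_ratio Raw riBAQ-scale enrichment of line-diff binders in
#'   line A (default 4).
#' @param noise_sd_log2 Cell-level noise SD in log2 units (default 0.25).
#' @param n_reps Replicates per arm (default 3).
#' @param miss_rate Expected missing fraction per column (default 0.05).
#' @param baseline_mean,baseline_sd Baseline log2 iBAQ distribution
#'   (defaults 20 and 3).
#' @param probe Probe label (default `"c-rucaparib"`).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return List with `line_a`, `line_b` ([pulldown_set()]s), `quant`
#'   (combined `quant_tbl`), `design` (sample design tibble), and `truth`
#'   (`specific_binders`, `line_enriched` named by line, `all_binders`).
#' @export
sim_chemprot <- function(n_features = 2000, n_specific = 20, n_line_diff = 20,
                         log2_effect = 3, line_ratio = 4, noise_sd_log2 = 0.25,
                         n_reps = 3, miss_rate = 0.05, baseline_mean = 20,
                         baseline_sd = 3, probe = "c-rucaparib", seed = 1) {
  if (n_specific + n_line_diff > n_features) {
    abort("n_specific + n_line_diff must not exceed n_features.")
  }
  withr::with_seed(seed, {
    features <- sprintf("PG%05d", seq_len(n_features))
    specific <- features[seq_len(n_specific)]
    line_diff <- features[n_specific + seq_len(n_line_diff)]
    binders <- c(specific, line_diff)
    base <- rnorm(n_features, baseline_mean, baseline_sd)
    is_binder <- features %in% binders
    is_ldiff <- features %in% line_diff
    # True targets are concentrated by the affinity pulldown, so their eluate
    # abundance sits in the upper half of the background distribution.
    n_bind <- sum(is_binder)
    base[is_binder] <- baseline_mean + abs(rnorm(n_bind, 0, baseline_sd))

    build_line <- function(line) {
      shift_line <- if (line == "B") is_ldiff * log2(line_ratio) else 0
      pd_mu <- base - shift_line
      ct_mu <- pd_mu - is_binder * log2_effect
      noise <- function() matrix(rnorm(n_features * n_reps, 0, noise_sd_log2),
                                 n_features, n_reps)
      pd <- censor_low(pd_mu + noise(), miss_rate)
      ct <- censor_low(ct_mu + noise(), miss_rate)
      list(pd = 2^pd, ct = 2^ct)
    }
    la <- build_line("A")
    lb <- build_line("B")

    sids <- c(paste0("UWB_PD_", seq_len(n_reps)), paste0("UWB_CT_", seq_len(n_reps)),
              paste0("UWBB_PD_", seq_len(n_reps)), paste0("UWBB_CT_", seq_len(n_reps)))

    line_a <- pulldown_set(
      mat_with_names(la$pd, features, sids[seq_len(n_reps)]),
      mat_with_names(la$ct, features, sids[n_reps + seq_len(n_reps)]),
      probe = probe, cell_line = "UWB"
    )
    line_b <- pulldown_set(
      mat_with_names(lb$pd, features, sids[2 * n_reps + seq_len(n_reps)]),
      mat_with_names(lb$ct, features, sids[3 * n_reps + seq_len(n_reps)]),
      probe = probe, cell_line = "UWB+B"
    )

    tab <- tibble(feature_id = features, pep = runif(n_features, 0, 0.04))
    all_int <- cbind(line_a$pd, line_a$ct, line_b$pd, line_b$ct)
    all_int[is.na(all_int)] <- 0  # MaxQuant writes 0 for not-detected
    for (k in seq_along(sids)) tab[[sids[k]]] <- all_int[, k]
    quant <- new_quant_tbl(tab, sids, "protein_groups")

    design <- tibble(
      sample_id = sids,
      cell_line = rep(c("UWB", "UWB+B"), each = 2 * n_reps),
      treatment = probe,
      role = rep(rep(c("pulldown", "competition"), each = n_reps), 2),
      replicate = rep(seq_len(n_reps), 4)
    )

    list(
      line_a = line_a, line_b = line_b, quant = quant, design = design,
      truth = list(
        specific_binders = specific,
        line_enriched = setNames(rep("A", n_line_diff), line_diff),
        all_binders = binders
      )
    )
  })
}

#' Simulate a TMT 6-plex phosphoproteomics experiment
#'
#' Emits reporter-ion intensities for 3 treated / 3 vehicle channel pairs
#' with planted regulated sites, per-channel loading differences (removed
#' by normalization), and precursor mass errors with a small fraction of
#' planted out-of-tolerance outliers to exercise the ppm gate.
#' `noise_sd` is the SD of the replicate-wise treated-vehicle log2 ratio
#' (each channel receives log2 noise of SD `noise_sd / sqrt(2)`).
#'
#' @param n_sites Number of phosphosites (default 5000).
#' @param n_up,n_down Planted up-/down-regulated sites (defaults 50).
#' @param log2_effect Planted |log2 fold change| (default 1.5).
#' @param noise_sd SD of the replicate log2 ratio (default 0.25).
#' @param n_rep_pairs Treated/vehicle channel pairs (default 3; 6-plex).
#' @param ppm_outlier_rate Fraction of sites with mass error beyond
#'   +/- 3 ppm (default 0.02); the rest are uniform on +/- 2 ppm.
#' @param channel_scale_sd SD (log2) of per-channel loading shifts
#'   (default 0.3).
#' @param baseline_mean,baseline_sd Baseline log2 reporter intensity
#'   distribution (defaults 16 and 2).
#' @param seed Integer seed.
#' @return List with `quant` (`quant_tbl`, phospho dialect columns),
#'   `design`, and `truth` (`regulated`: named signed log2 effects;
#'   `ppm_outliers`: feature ids beyond tolerance).
#' @export
sim_phospho_tmt <- function(n_sites = 5000, n_up = 50, n_down = 50,
                            log2_effect = 1.5, noise_sd = 0.25,
                            n_rep_pairs = 3, ppm_outlier_rate = 0.02,
                            channel_scale_sd = 0.3, baseline_mean = 16,
                            baseline_sd = 2, seed = 1) {
  if (n_up + n_down > n_sites) abort("n_up + n_down must not exceed n_sites.")
  withr::with_seed(seed, {
    features <- sprintf("pS%05d", seq_len(n_sites))
    genes <- sprintf("GENE%05d", seq_len(n_sites))
    effect <- c(rep(log2_effect, n_up), rep(-log2_effect, n_down),
                rep(0, n_sites - n_up - n_down))
    base <- rnorm(n_sites, baseline_mean, baseline_sd)

    sid_t <- paste0("T", seq_len(n_rep_pairs))
    sid_v <- paste0("V", seq_len(n_rep_pairs))
    ch_shift <- rnorm(2 * n_rep_pairs, 0, channel_scale_sd)
    cell_sd <- noise_sd / sqrt(2)
    m <- matrix(0, n_sites, 2 * n_rep_pairs,
                dimnames = list(features, c(sid_t, sid_v)))
    for (r in seq_len(n_rep_pairs)) {
      m[, r] <- base + effect + ch_shift[r] + rnorm(n_sites, 0, cell_sd)
      m[, n_rep_pairs + r] <- base + ch_shift[n_rep_pairs + r] + rnorm(n_sites, 0, cell_sd)
    }
    intens <- 2^m

    n_out <- round(ppm_outlier_rate * n_sites)
    out_idx <- sample.int(n_sites, n_out)
    ppm <- runif(n_sites, -2, 2)
    ppm[out_idx] <- sample(c(-1, 1), n_out, replace = TRUE) * runif(n_out, 3.2, 6)

    tab <- tibble(
      feature_id = features,
      gene_symbol = genes,
      pep = runif(n_sites, 0, 0.04),
      mass_error_ppm = ppm,
      localization_prob = runif(n_sites, 0.75, 1)
    )
    for (k in seq_len(ncol(intens))) tab[[colnames(intens)[k]]] <- intens[, k]
    quant <- new_quant_tbl(tab, colnames(intens), "phospho_sites")

    design <- tibble(
      sample_id = c(sid_t, sid_v),
      cell_line = "UWB",
      treatment = rep(c("rucaparib", "DMSO"), each = n_rep_pairs),
      role = rep(c("treated", "vehicle"), each = n_rep_pairs),
      replicate = rep(seq_len(n_rep_pairs), 2),
      channel = paste0("TMT", seq_len(2 * n_rep_pairs))
    )

    reg <- setNames(effect[effect != 0], features[effect != 0])
    list(
      quant = quant, design = design,
      truth = list(regulated = reg, ppm_outliers = features[out_idx])
    )
  })
}

#' Simulate a label-free ADP-ribosylome experiment
#'
#' Label-free protein intensities for a drug vs vehicle contrast with
#' planted hits at a known raw fold change, log-normal noise, and
#' intensity-dependent missingness (see [sim_chemprot()]).
#'
#' @param n_proteins Number of proteins (default 3000).
#' @param n_hits Planted differential proteins (default 60).
#' @param raw_fc Raw-scale fold change of planted hits (default 4).
#' @param direction `"down"` (decreased under drug, default) or `"up"`.
#' @param noise_sd Cell-level log2 noise SD (default 0.3).
#' @param n_reps Replicates per arm (default 3).
#' @param miss_rate Expected missing fraction per column (default 0.05).
#' @param baseline_mean,baseline_sd Baseline log2 intensity distribution.
#' @param seed Integer seed.
#' @return List with `quant`, `design`, `truth` (`hits`: named signed log2
#'   effects).
#' @export
sim_adpr <- function(n_proteins = 3000, n_hits = 60, raw_fc = 4,
                     direction = c("down", "up"), noise_sd = 0.3,
                     n_reps = 3, miss_rate = 0.05, baseline_mean = 20,
                     baseline_sd = 3, seed = 1) {
  direction <- match.arg(direction)
  if (n_hits > n_proteins) abort("n_hits must not exceed n_proteins.")
  withr::with_seed(seed, {
    features <- sprintf("ADPR%05d", seq_len(n_proteins))
    genes <- sprintf("GENE%05d", seq_len(n_proteins))
    sgn <- if (direction == "down") -1 else 1
    effect <- c(rep(sgn * log2(raw_fc), n_hits), rep(0, n_proteins - n_hits))
    base <- rnorm(n_proteins, baseline_mean, baseline_sd)

    sid <- c(paste0("RUCA_", seq_len(n_reps)), paste0("DMSO_", seq_len(n_reps)))
    m <- matrix(0, n_proteins, 2 * n_reps, dimnames = list(features, sid))
    for (r in seq_len(n_reps)) {
      m[, r] <- base + effect + rnorm(n_proteins, 0, noise_sd)
      m[, n_reps + r] <- base + rnorm(n_proteins, 0, noise_sd)
    }
    m <- censor_low(m, miss_rate)
    intens <- 2^m
    intens[is.na(intens)] <- 0

    tab <- tibble(feature_id = features, gene_symbol = genes,
                  pep = runif(n_proteins, 0, 0.04))
    for (k in seq_len(ncol(intens))) tab[[sid[k]]] <- intens[, k]
    quant <- new_quant_tbl(tab, sid, "generic")

    design <- tibble(
      sample_id = sid,
      cell_line = "UWB",
      treatment = rep(c("rucaparib", "DMSO"), each = n_reps),
      role = rep(c("treated", "vehicle"), each = n_reps),
      replicate = rep(seq_len(n_reps), 2)
    )

    list(
      quant = quant, design = design,
      truth = list(hits = setNames(effect[seq_len(n_hits)], features[seq_len(n_hits)]))
    )
  })
}

#' Simulate single-agent and combination viability data
#'
#' Single-agent viability follows a four-parameter logistic curve
#' (bottom 0, top 1) at the given IC50s and Hill slopes; combination
#' fraction affected is the Bliss-independent expectation from the true
#' marginals plus a planted `bliss_offset` (clipped into \[0, 1\]); all
#' wells receive Gaussian noise of SD `noise_sd` on the viability scale.
#'
#' @param ic50_a,ic50_b True IC50s in uM (defaults 0.4 and 1).
#' @param hill_a,hill_b True Hill slopes (defaults 1).
#' @param bliss_offset Planted Bliss excess added to every combination cell
#'   (default 0).
#' @param noise_sd Well-level noise SD on the viability scale (default 0.05).
#' @param concentrations Dose grid in uM (default
#'   `c(0.016, 0.08, 0.4, 2, 10)`; vehicle is the normalizer, not a dose).
#' @param n_reps Biological replicates (default 4).
#' @param drug_a,drug_b Drug labels.
#' @param seed Integer seed.
#' @return List with `single_a`, `single_b` ([dose_response()]s), `combo`
#'   (long tibble `conc_a_um`, `conc_b_um`, `replicate`, `viability`) and
#'   `truth` (`ic50`, `hill`, `bliss_offset`, `offset_cells`: tibble
#'   marking the cells where the planted offset was applied unclipped).
#' @export
sim_viability <- function(ic50_a = 0.4, ic50_b = 1, hill_a = 1, hill_b = 1,
                          bliss_offset = 0, noise_sd = 0.05,
                          concentrations = c(0.016, 0.08, 0.4, 2, 10),
                          n_reps = 4, drug_a = "rucaparib", drug_b = "AZD5363",
                          seed = 1) {
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    abort("`concentrations` must be positive and strictly increasing.")
  }
  withr::with_seed(seed, {
    via_true <- function(c_um, ic50, hill) 1 / (1 + (c_um / ic50)^hill)
    single_tbl <- function(ic50, hill, drug) {
      tidyr::expand_grid(conc_um = concentrations, replicate = seq_len(n_reps)) |>
        dplyr::mutate(
          viability = via_true(.data$conc_um, ic50, hill) +
            rnorm(dplyr::n(), 0, noise_sd)
        ) |>
        dose_response(drug = drug)
    }
    single_a <- single_tbl(ic50_a, hill_a, drug_a)
    single_b <- single_tbl(ic50_b, hill_b, drug_b)

    grid <- tidyr::expand_grid(conc_a_um = concentrations, conc_b_um = concentrations)
    fa_a <- 1 - via_true(grid$conc_a_um, ic50_a, hill_a)
    fa_b <- 1 - via_true(grid$conc_b_um, ic50_b, hill_b)
    fa_exp <- fa_a + fa_b - fa_a * fa_b
    fa_target <- fa_exp + bliss_offset
    unclipped <- fa_target >= 0 & fa_target <= 1
    if (bliss_offset != 0 && !any(unclipped)) {
      abort("`bliss_offset` pushes the fraction affected outside [0, 1] in every cell.")
    }
    fa_c <- pmin(pmax(fa_target, 0), 1)

    combo <- tidyr::expand_grid(
      cell = seq_len(nrow(grid)), replicate = seq_len(n_reps)
    ) |>
      dplyr::mutate(
        conc_a_um = grid$conc_a_um[.data$cell],
        conc_b_um = grid$conc_b_um[.data$cell],
        viability = 1 - fa_c[.data$cell] + rnorm(dplyr::n(), 0, noise_sd)
      ) |>
      dplyr::select(!"cell")

    list(
      single_a = single_a, single_b = single_b, combo = combo,
      truth = list(
        ic50 = c(a = ic50_a, b = ic50_b),
        hill = c(a = hill_a, b = hill_b),
        bliss_offset = bliss_offset,
        offset_cells = dplyr::mutate(grid, unclipped = unclipped)
      )
    )
  })
}
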