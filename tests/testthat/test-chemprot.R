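toy_set <- function(pd, ct, probe = "c-olaparib", cell_line = "UWB") {
  pulldown_set(as.matrix(pd), as.matrix(ct),
               feature_id = sprintf("F%02d", seq_len(nrow(as.matrix(pd)))),
               probe = probe, cell_line = cell_line)
}

test_that("riBAQ normalizes within sample and keeps rank order", {
  expect_equal(compute_ribaq(5), 1)
  expect_equal(compute_ribaq(c(3, 1)), c(0.75, 0.25))
  x <- withr::with_seed(2, runif(100, 1, 1000))
  r <- compute_ribaq(x)
  expect_lt(abs(sum(r) - 1), 1e-9)
  expect_equal(order(r), order(x))
  # scale invariance
  expect_equal(compute_ribaq(17.3 * x), r)
  expect_error(compute_ribaq(c(0, 0)), "positive")
  expect_error(compute_ribaq(c(-1, 2)), "non-negative")
})

test_that("planted specific binders are recovered and each call re-verifies", {
  s <- sim_chemprot(n_features = 200, n_specific = 10, n_line_diff = 0,
                    log2_effect = 3, noise_sd_log2 = 0.2, seed = 21)
  calls <- score_competition(s$line_a)
  planted <- s$truth$specific_binders
  expect_gte(sum(calls$specific & calls$feature_id %in% planted), 10)
  expect_lte(sum(calls$specific & !calls$feature_id %in% planted), 1)

  # brute-force confirmation of each call with plain t.test on the same
  # imputed log2 matrix
  m <- cbind(s$line_a$pd, s$line_a$ct)
  m[m == 0] <- NA
  m <- log2(impute_column_min(m))
  for (i in which(calls$specific)[1:5]) {
    pd_i <- m[i, 1:3]
    ct_i <- m[i, 4:6]
    expect_gt(mean(pd_i) - mean(ct_i), 1.5)
    expect_lt(t.test(pd_i, ct_i, var.equal = TRUE)$p.value, 0.05)
  }
})

test_that("PD identical to CT yields no specific calls", {
  m <- withr::with_seed(3, matrix(runif(30, 100, 1000), 10))
  calls <- score_competition(toy_set(m, m))
  expect_equal(sum(calls$specific), 0)
})

test_that("a 2-fold binder with tiny variance fails the log2 cutoff", {
  pd <- matrix(c(800, 800.1, 799.9), 1)
  ct <- pd / 2
  call <- score_competition(toy_set(pd, ct))
  expect_equal(call$log2fc_pd_ct, 1, tolerance = 1e-3)
  expect_lt(call$p_pd_ct, 0.05)   # highly significant ...
  expect_false(call$specific)     # ... but below the fold-change gate
})

test_that("extreme cutoffs bracket the call set", {
  s <- sim_chemprot(n_features = 100, n_specific = 5, n_line_diff = 0, seed = 5)
  none <- score_competition(s$line_a, fc_cutoff = Inf)
  expect_equal(sum(none$specific), 0)
  all_ <- score_competition(s$line_a, fc_cutoff = -Inf, p_cutoff = 1)
  expect_equal(sum(all_$specific), 100)
})

test_that("cross-line riBAQ ratio gates calls in both directions", {
  # one interactor at mean riBAQ ~0.03 in line A vs ~0.01 in line B
  jitter <- function(base) cbind(base, base * c(1.03, rep(1, 4)),
                                 base * c(0.97, rep(1, 4)))
  pd_a <- jitter(c(30, 300, 300, 170, 170))
  pd_b <- jitter(c(10, 300, 300, 170, 170))
  sa <- toy_set(pd_a, pd_a * 0.1)
  sb <- toy_set(pd_b, pd_b * 0.1, cell_line = "UWB+B")
  res <- cross_line_differential(sa, sb)
  expect_equal(res$ribaq_line_a[1], 0.031, tolerance = 0.05)
  expect_gt(res$ribaq_ratio[1], 1.5)
  expect_equal(as.character(res$line_enriched[1]), "A")

  # identical lines: nothing called
  same <- cross_line_differential(sa, toy_set(pd_a, pd_a * 0.1, cell_line = "X"))
  expect_true(all(same$line_enriched == "none"))

  # mirrored labels when the lines swap
  swapped <- cross_line_differential(sb, sa)
  expect_equal(as.character(swapped$line_enriched[1]), "B")
  expect_equal(swapped$ribaq_ratio, 1 / res$ribaq_ratio, tolerance = 1e-12)
})

test_that("planted line-enriched partners are recovered with mirrored labels", {
  s <- sim_chemprot(n_features = 400, n_specific = 5, n_line_diff = 8,
                    line_ratio = 4, seed = 31)
  planted <- names(s$truth$line_enriched)
  ab <- cross_line_differential(s$line_a, s$line_b)
  expect_gte(sum(ab$line_enriched == "A" & ab$feature_id %in% planted), 7)
  ba <- cross_line_differential(s$line_b, s$line_a)
  expect_equal(
    ab$feature_id[ab$line_enriched == "A"],
    ba$feature_id[ba$line_enriched == "B"]
  )
})

test_that("cross-line requires a shared probe", {
  m <- matrix(runif(12, 10, 20), 4)
  expect_error(
    cross_line_differential(toy_set(m, m, probe = "c-olaparib"),
                            toy_set(m, m, probe = "c-rucaparib")),
    "Probe mismatch"
  )
})

test_that("merge_probes labels per-probe provenance by set arithmetic", {
  mk <- function(ids, probe) tibble::tibble(feature_id = ids, probe = probe,
                                            specific = TRUE)
  disj <- merge_probes(mk(c("a", "b", "c"), "c-olaparib"), mk(c("d", "e"), "c-rucaparib"))
  expect_equal(nrow(disj), 5)
  expect_false(any(disj$probes == "both"))

  ident <- merge_probes(mk(c("a", "b"), "c-olaparib"), mk(c("a", "b"), "c-rucaparib"))
  expect_true(all(ident$probes == "both"))

  one <- merge_probes(mk(c("a", "b"), "c-olaparib"), mk(c("b", "z"), "c-rucaparib"))
  expect_equal(sort(one$feature_id), union(c("a", "b"), c("b", "z")))
  expect_equal(one$probes[one$feature_id == "b"], "both")
  expect_equal(one$probes[one$feature_id == "a"], "c-olaparib")
  expect_equal(one$probes[one$feature_id == "z"], "c-rucaparib")
})
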