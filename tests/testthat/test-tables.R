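test_that("protein-groups dialect parses ids, intensities and '+' flags", {
  path <- write_toy_protein_groups(withr::local_tempfile(fileext = ".tsv"))
  tab <- read_quant_table(path, dialect = "protein_groups")

  expect_s3_class(tab, "quant_tbl")
  expect_equal(tab$feature_id, c("P09874", "Q9UGN5", "O95271"))
  expect_equal(sample_ids(tab), c("A", "B"))
  expect_equal(tab$A, c(100, 200, 300))
  expect_equal(tab$B, c(10, 20, 30))
  expect_equal(tab$reverse_flag, c(FALSE, TRUE, FALSE))
  expect_equal(tab$contaminant_flag, c(FALSE, FALSE, TRUE))
  expect_equal(tab$pep, c(0.001, 0.02, 0.001))

  m <- intensity_matrix(tab)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(rownames(m), tab$feature_id)
})

test_that("an entirely empty Reverse column yields all-FALSE flags", {
  path <- write_toy_protein_groups(withr::local_tempfile(fileext = ".tsv"),
                                   reverse = c("", "", ""))
  tab <- read_quant_table(path, dialect = "protein_groups")
  expect_equal(tab$reverse_flag, rep(FALSE, 3))
})

test_that("parser errors name duplicate ids, missing columns and bad cells", {
  dup <- write_toy_protein_groups(withr::local_tempfile(fileext = ".tsv"),
                                  ids = c("P09874", "P09874", "O95271"))
  expect_error(read_quant_table(dup, dialect = "protein_groups"), "P09874")

  nohdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Wrong column\tiBAQ A", "x\t1"), nohdr)
  expect_error(read_quant_table(nohdr, dialect = "protein_groups"),
               "Majority protein IDs")

  badcell <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Majority protein IDs\tiBAQ A", "P1\t12", "P2\toops"), badcell)
  expect_error(read_quant_table(badcell, dialect = "protein_groups"),
               "oops.*iBAQ A.*row 2")
})

test_that("generic write/read round-trip preserves every field exactly", {
  q <- make_quant(
    cbind(s1 = c(1.25, 0, 1e7 + 1 / 3), s2 = c(NA, 2^-20, 42)),
    pep = c(0.001, NA, 0.049),
    reverse = c(FALSE, TRUE, FALSE),
    contaminant = c(FALSE, FALSE, TRUE),
    mass_error = c(-2.5, 0.1, NA)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(q, path)
  back <- read_quant_table(path, dialect = "generic")
  for (col in c("feature_id", "pep", "reverse_flag", "contaminant_flag",
                "mass_error_ppm", "s1", "s2")) {
    expect_identical(back[[col]], q[[col]], label = col)
  }
})

test_that("sample design is validated", {
  d <- make_design(c("a1", "a2", "b1", "b2"),
                   c("treated", "treated", "vehicle", "vehicle"))
  expect_silent(read_sample_design(d))
  expect_error(read_sample_design(d[, -3]), "treatment")
  d2 <- d
  d2$role[1] <- "mystery"
  expect_error(read_sample_design(d2), "mystery")
  d3 <- d
  d3$replicate <- c(1L, 1L, 1L, 2L)
  expect_error(read_sample_design(d3), "Duplicate")
})

test_that("qc_filter applies the precedence reverse > contaminant > PEP > zero", {
  q <- make_quant(
    cbind(s1 = c(5, 5, 5, 0, 5, 5), s2 = c(5, 5, 5, 0, 5, 5)),
    pep = c(0.001, 0.001, 0.2, 0.001, 0.001, 0.001),
    reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    contaminant = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  out <- qc_filter(q)
  rep <- filter_report(out)
  expect_equal(rep$n_input, 6)
  expect_equal(rep$n_removed_pep, 1)
  expect_equal(rep$n_removed_reverse, 1)
  expect_equal(rep$n_removed_contaminant, 1)
  expect_equal(rep$n_removed_zero_intensity, 1)
  expect_equal(rep$n_output, 2)
  expect_equal(nrow(out), 2)

  # a feature violating several rules is counted once, at the first rule
  q2 <- make_quant(cbind(s1 = c(0, 1)), pep = c(0.9, 0.001),
                   reverse = c(TRUE, FALSE))
  rep2 <- filter_report(qc_filter(q2))
  expect_equal(rep2$n_removed_reverse, 1)
  expect_equal(rep2$n_removed_pep, 0)
  expect_equal(rep2$n_removed_zero_intensity, 0)
})

test_that("qc_filter is the identity on clean tables and without a PEP column", {
  clean <- make_quant(matrix(1:12, 4), pep = rep(0.001, 4))
  out <- qc_filter(clean)
  rep <- filter_report(out)
  expect_equal(rep$n_output, 4)
  expect_equal(rep$n_input - rep$n_output, 0)
  expect_equal(out$feature_id, clean$feature_id)

  nopep <- make_quant(matrix(1:12, 4))
  expect_equal(nrow(qc_filter(nopep, pep_max = 1.0)), 4)
})

test_that("qc_filter is idempotent and its report always balances", {
  for (seed in 1:8) {
    q <- withr::with_seed(seed, {
      n <- 50
      make_quant(
        matrix(sample(c(0, 2, 7), n * 3, replace = TRUE, prob = c(0.3, 0.4, 0.3)), n),
        pep = runif(n, 0, 0.1),
        reverse = runif(n) < 0.1,
        contaminant = runif(n) < 0.1
      )
    })
    once <- qc_filter(q)
    rep <- filter_report(once)
    expect_equal(
      rep$n_output + rep$n_removed_reverse + rep$n_removed_contaminant +
        rep$n_removed_pep + rep$n_removed_zero_intensity,
      rep$n_input
    )
    twice <- qc_filter(once)
    expect_equal(twice$feature_id, once$feature_id)
    expect_equal(filter_report(twice)$n_input, filter_report(twice)$n_output)
  }
})
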