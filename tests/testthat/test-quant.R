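test_that("quantification tables read with schema validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    accession = c("P1", "P1", "P2"), site = c(10, 20, 5),
    peptide = c("LNGTK", "ANCSR", "TNFTK"),
    glycan_composition = c("N2H5F0S0", "N4H5F0S2", "N3H4F1S0"),
    s1 = c(100, 200, 300), s2 = c(110, 190, NA)
  ), path)
  tab <- read_quant_table(path, "glycopeptide")
  expect_equal(nrow(tab), 3)
  expect_true(all(c("feature_id", "glycan") %in% names(tab)))
  expect_equal(tab$feature_id[1], "P1|10|LNGTK|N2H5F0S0")

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(accession = "P1", site = 1, peptide = "X"),
                   bad)
  expect_error(read_quant_table(bad, "glycopeptide"), "glycan_composition")
})

test_that("duplicate feature rows are summed channel-wise", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    accession = c("P1", "P1"), site = c(10, 10),
    peptide = c("LNGTK", "LNGTK"),
    glycan_composition = c("N2H5F0S0", "N2H5F0S0"),
    s1 = c(100, 50), s2 = c(NA, 40), s3 = c(NA_real_, NA_real_)
  ), path)
  expect_warning(tab <- read_quant_table(path, "glycopeptide"), "duplicate")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$s1, 150)   # sum
  expect_equal(tab$s2, 40)    # NA + value sums to the value
  expect_true(is.na(tab$s3))  # all-missing stays missing
})

test_that("channel totals scale to the batch median total", {
  df <- toy_quant("f1", s1 = c(40, 60), s2 = c(100, 200))
  df <- tibble::tibble(feature_id = c("f1", "f2"), s1 = c(40, 60),
                       s2 = c(100, 200))
  out <- normalize_batch(df)
  # totals 100 and 300; median 200; scale factors 2 and 2/3
  expect_equal(out$s1, c(80, 120))
  expect_equal(out$s2, c(100, 200) * 2 / 3)
  expect_equal(sum(out$s1), sum(out$s2))

  same <- tibble::tibble(feature_id = c("f1", "f2"), s1 = c(1, 2), s2 = c(1, 2))
  expect_equal(normalize_batch(same), same)
  one <- tibble::tibble(feature_id = "f1", s1 = 5)
  expect_equal(normalize_batch(one), one)
  allna <- tibble::tibble(feature_id = "f1", s1 = 5, s2 = NA_real_)
  expect_error(normalize_batch(allna), "s2")
})

test_that("reference ratioing gives log2 ratios and drops the reference", {
  design <- toy_design(1, with_ref = TRUE)
  df <- tibble::tibble(feature_id = c("f1", "f2", "f3"),
                       A1 = c(200, 100, 50), B1 = c(100, 100, NA),
                       REF_B1 = c(100, NA, 100))
  expect_warning(out <- ratio_to_reference(df, design), "missing")
  expect_false("REF_B1" %in% names(out))
  expect_equal(out$A1, c(1, NA, log2(0.5)))
  expect_equal(out$B1, c(0, NA, NA))  # missing reference kills the feature
  expect_equal(attr(out, "n_reference_missing"), 1)
})

test_that("batch integration takes the union of features", {
  b1 <- tibble::tibble(feature_id = c("a", "b"), s1 = c(1, 2))
  b2 <- tibble::tibble(feature_id = c("b", "c"), s2 = c(3, 4))
  out <- integrate_batches(list(b1, b2))
  expect_setequal(out$feature_id, c("a", "b", "c"))
  expect_equal(out$s1[out$feature_id == "a"], 1)
  expect_true(is.na(out$s2[out$feature_id == "a"]))
  expect_true(is.na(out$s1[out$feature_id == "c"]))

  expect_identical(integrate_batches(list(b1)), b1)
  dup <- tibble::tibble(feature_id = "a", s1 = 1)
  expect_error(integrate_batches(list(dup, dup)), "more than one batch")
})

test_that("single-batch normalization log2-transforms scaled intensities", {
  df <- tibble::tibble(feature_id = c("f1", "f2"), s1 = c(4, 4), s2 = c(4, 4))
  out <- normalize_single_batch(df)
  expect_equal(unlist(out[c("s1", "s2")], use.names = FALSE), rep(2, 4))

  df2 <- tibble::tibble(feature_id = c("f1", "f2"), s1 = c(10, 30),
                        s2 = c(60, 20))
  out2 <- normalize_single_batch(df2)
  # totals 40 and 80, median 60: s1 scaled by 1.5, s2 by 0.75
  expect_equal(out2$s1, log2(c(15, 45)))
  expect_equal(out2$s2, log2(c(45, 15)))

  zero <- tibble::tibble(feature_id = c("f1", "f2"), s1 = c(0, 8), s2 = c(4, 4))
  expect_true(is.na(normalize_single_batch(zero)$s1[1]))
})

test_that("missingness filter is inclusive at the threshold and idempotent", {
  mk <- function(n_obs) c(rnorm(n_obs), rep(NA_real_, 10 - n_obs))
  set.seed(1)
  df <- tibble::tibble(feature_id = c("half", "under"))
  m <- rbind(mk(5), mk(4))
  colnames(m) <- paste0("s", 1:10)
  df <- dplyr::bind_cols(df, tibble::as_tibble(m))
  out <- apply_quant_filter(df, min_fraction = 0.5)
  expect_equal(out$feature_id, "half")     # 5/10 retained, 4/10 dropped
  rep1 <- filter_report(out)
  expect_equal(rep1$n_dropped_missingness, 1)
  out2 <- apply_quant_filter(out, min_fraction = 0.5)
  expect_equal(out2$feature_id, out$feature_id)  # idempotent
})

test_that("protein filter applies the unique-peptide floor", {
  df <- tibble::tibble(feature_id = c("P1", "P2"), unique_peptides = c(1L, 2L),
                       s1 = c(1, 1), s2 = c(1, 1))
  out <- apply_quant_filter(df)
  expect_equal(out$feature_id, "P2")
  expect_equal(filter_report(out)$n_dropped_peptides, 1)
})

test_that("reference channels are excluded from the filter denominator", {
  design <- toy_design(1, with_ref = TRUE)
  df <- tibble::tibble(feature_id = "f", A1 = 1, B1 = NA_real_,
                       REF_B1 = 1)
  # 1 of 2 non-reference samples quantified: exactly 50%, retained
  out <- apply_quant_filter(df, design, min_fraction = 0.5)
  expect_equal(nrow(out), 1)
  out2 <- apply_quant_filter(df, design, min_fraction = 0.6)
  expect_equal(nrow(out2), 0)
})

test_that("PCA uses complete cases and reports variance fractions", {
  # rank-1 data: all features proportional to one sample-space direction
  v <- c(1, 2, 3, 4)
  df <- tibble::tibble(feature_id = paste0("f", 1:3))
  df <- dplyr::bind_cols(df, tibble::as_tibble(
    t(outer(v, c(1, -2, 0.5))), .name_repair = ~paste0("s", 1:4)))
  p <- pca_summary(df)
  expect_equal(p$variance$variance_explained[1], 1)
  expect_true(all(diff(p$variance$variance_explained) <= 1e-12))

  # duplicated sample columns get identical scores
  set.seed(2)
  df2 <- tibble::tibble(feature_id = paste0("f", 1:20))
  m <- matrix(rnorm(20 * 3), 20, 3)
  df2 <- dplyr::bind_cols(df2, tibble::as_tibble(
    cbind(m, m[, 3]), .name_repair = ~paste0("s", 1:4)))
  p2 <- pca_summary(df2)
  expect_equal(unlist(p2$scores[3, -1]), unlist(p2$scores[4, -1]))

  # features with missing values are excluded; too few complete -> error
  df3 <- tibble::tibble(feature_id = c("a", "b"), s1 = c(1, NA),
                        s2 = c(2, 1), s3 = c(3, 2))
  expect_error(pca_summary(df3), "stricter")
})

test_that("isotropic data spreads variance near 1/(n-1) per component", {
  set.seed(99)
  n_feat <- 2000; n_samp <- 20
  df <- tibble::tibble(feature_id = paste0("f", seq_len(n_feat)))
  df <- dplyr::bind_cols(df, tibble::as_tibble(
    matrix(rnorm(n_feat * n_samp), n_feat, n_samp),
    .name_repair = ~paste0("s", seq_len(n_samp))))
  p <- pca_summary(df)
  expect_lt(abs(p$variance$variance_explained[1] - 1 / 19), 0.02)
})

test_that("global per-batch scaling leaves the final matrix unchanged", {
  design <- toy_design(2, with_ref = TRUE)
  set.seed(3)
  vals <- matrix(2^rnorm(5 * 5, 10), 5, 5)
  df <- dplyr::bind_cols(tibble::tibble(feature_id = paste0("f", 1:5)),
                         tibble::as_tibble(vals, .name_repair = ~design$sample_id))
  run <- function(d) {
    suppressWarnings(ratio_to_reference(normalize_batch(d, design), design))
  }
  scaled <- df
  for (s in design$sample_id) scaled[[s]] <- scaled[[s]] * 37.5
  expect_equal(run(df), run(scaled), ignore_attr = TRUE)
})
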