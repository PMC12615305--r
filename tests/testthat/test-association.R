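expr_fixture <- function(n_genes = 10, n_samples = 2, seed = 31) {
  set.seed(seed)
  df <- tibble::tibble(feature_id = paste0("g", seq_len(n_genes)))
  dplyr::bind_cols(df, tibble::as_tibble(
    matrix(rnorm(n_genes * n_samples), n_genes, n_samples),
    .name_repair = ~paste0("s", seq_len(n_samples))))
}

test_that("gene sets round-trip through GMT", {
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g9", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, path)
  expect_equal(read_gene_sets(path), sets)
})

test_that("ssGSEA scores concentrate sign at the extremes of the ranking", {
  expr <- expr_fixture(50, 3)
  ranked <- expr$feature_id[order(expr$s1, decreasing = TRUE)]
  top <- list(top = utils::head(ranked, 5))
  bottom <- list(bottom = utils::tail(ranked, 5))
  expect_gt(ssgsea_scores(expr, top)$s1, 0)
  expect_lt(ssgsea_scores(expr, bottom)$s1, 0)
})

test_that("rank-only mode is invariant to monotone transforms", {
  expr <- expr_fixture(40, 2)
  sets <- list(s = expr$feature_id[c(3, 11, 25, 38)])
  base <- ssgsea_scores(expr, sets, alpha_weight = 0)
  mono <- expr
  mono$s1 <- exp(mono$s1) + 5   # strictly monotone
  mono$s2 <- 3 * mono$s2 - 1
  expect_equal(ssgsea_scores(mono, sets, alpha_weight = 0), base)
})

test_that("missing expression values are dropped per sample, not imputed", {
  expr <- expr_fixture(30, 2)
  sets <- list(s = expr$feature_id[1:5])
  with_na <- expr
  with_na$s1[10:15] <- NA
  # equivalent to scoring the reduced gene list for that sample
  reduced <- expr[-(10:15), ]
  expect_equal(ssgsea_scores(with_na, sets)$s1,
               ssgsea_scores(reduced, sets)$s1)
  # the untouched sample is unchanged
  expect_equal(ssgsea_scores(with_na, sets)$s2, ssgsea_scores(expr, sets)$s2)
})

test_that("sets without overlap are dropped, all-miss errors", {
  expr <- expr_fixture(10, 2)
  expect_warning(out <- ssgsea_scores(expr, list(
    ok = expr$feature_id[1:3], gone = c("x1", "x2"))), "no overlap")
  expect_equal(out$signature, "ok")
  expect_error(ssgsea_scores(expr, list(gone = c("x1", "x2"))),
               "No gene set overlaps")
})

test_that("composite scores are means of their member signatures", {
  sm <- tibble::tibble(signature = c("Fibroblasts", "Endothelial_cells",
                                     "NK_cells"),
                       s1 = c(1, 3, 5), s2 = c(2, 4, 6))
  out <- composite_scores(sm)
  expect_equal(out$s1[out$signature == "StromaScore"], 2)
  expect_equal(out$s2[out$signature == "MicroenvironmentScore"], 4)
  one <- composite_scores(sm, stromal_signatures = "NK_cells",
                          all_signatures = "NK_cells")
  expect_equal(one$s1[one$signature == "StromaScore"],
               sm$s1[sm$signature == "NK_cells"])
})

test_that("immune differential needs both significance and a fold gate", {
  design <- toy_design(5)
  set.seed(41)
  base <- rnorm(10, 0, 0.01)
  sm <- tibble::tibble(signature = c("flat", "shifted", "subtle"))
  sm <- dplyr::bind_cols(sm, tibble::as_tibble(rbind(
    rep(1, 10),
    c(rep(4, 5), rep(2, 5)) + base,          # 2-fold, clearly significant
    c(rep(1.1, 5), rep(1, 5)) + base / 10    # significant but under 1.25-fold
  ), .name_repair = ~design$sample_id))
  out <- immune_differential(sm, design, "Tumor", "NAT")
  expect_equal(out$call[out$signature == "flat"], "ns")
  expect_equal(out$call[out$signature == "shifted"], "enriched_in_a")
  expect_equal(out$call[out$signature == "subtle"], "ns")
  expect_lt(out$p_value[out$signature == "subtle"], 0.05)  # fold gate did it
})

test_that("immune calls are invariant to per-signature score offsets", {
  design <- toy_design(4)
  set.seed(42)
  sm <- tibble::tibble(signature = "sig")
  sm <- dplyr::bind_cols(sm, tibble::as_tibble(
    matrix(c(rnorm(4, 2, 0.1), rnorm(4, 0.5, 0.1)), 1),
    .name_repair = ~design$sample_id))
  shifted <- sm
  shifted[design$sample_id] <- sm[design$sample_id] - 100
  a <- immune_differential(sm, design)
  b <- immune_differential(shifted, design)
  expect_equal(a$call, b$call)
  expect_equal(a$fold, b$fold)
})

test_that("glycosyltransferase selection intersects with the proteome", {
  st <- call_protein_de(tibble::tibble(
    feature_id = c("DPM1", "MGAT5", "ALB"),
    fold_change = c(3, 1.1, 0.4), log2_fc = log2(c(3, 1.1, 0.4)),
    p_value = c(0.001, 0.8, 0.01)))
  gts <- select_glycosyltransferases(st, c("DPM1", "MGAT5", "ALG6"))
  expect_setequal(gts$feature_id, c("DPM1", "MGAT5"))
  expect_equal(gts$protein_status[gts$feature_id == "DPM1"], "sig_up")
  expect_equal(nrow(select_glycosyltransferases(st, character(0))), 0)
  expect_equal(nrow(select_glycosyltransferases(st, c("B4GALT1"))), 0)
})

test_that("spearman screen matches cor.test and handles direction", {
  x <- tibble::tibble(feature_id = "x", !!!as.list(setNames(
    c(1, 4, 2, 8, 5, 7, 3, 6), paste0("s", 1:8))))
  y_same <- tibble::tibble(feature_id = "y", !!!as.list(setNames(
    c(2, 8, 4, 16, 10, 14, 6, 12), paste0("s", 1:8))))
  out <- spearman_screen(x, y_same, keep_all = TRUE)
  expect_equal(out$rho, 1)
  expect_true(out$retained)

  y_anti <- y_same
  y_anti[paste0("s", 1:8)] <- -y_same[paste0("s", 1:8)]
  anti <- spearman_screen(x, y_anti, keep_all = TRUE)
  expect_equal(anti$rho, -1)
  expect_false(anti$retained)
  expect_true(spearman_screen(x, y_anti, use_abs = TRUE,
                              keep_all = TRUE)$retained)

  # tie-handling cross-check against cor.test mid-rank rho
  set.seed(51)
  xv <- round(rnorm(8), 1); yv <- round(xv + rnorm(8, 0, 0.5), 1)
  xt <- tibble::tibble(feature_id = "x",
                       !!!as.list(setNames(xv, paste0("s", 1:8))))
  yt <- tibble::tibble(feature_id = "y",
                       !!!as.list(setNames(yv, paste0("s", 1:8))))
  got <- spearman_screen(xt, yt, keep_all = TRUE)
  expect_equal(got$rho,
               suppressWarnings(cor.test(xv, yv, method = "spearman"))$estimate,
               ignore_attr = TRUE)
})

test_that("pairwise-complete counts gate the screen", {
  vals <- c(1, 2, 3, 4, NA, NA, NA, NA)
  x <- tibble::tibble(feature_id = "x",
                      !!!as.list(setNames(vals, paste0("s", 1:8))))
  y <- tibble::tibble(feature_id = "y",
                      !!!as.list(setNames(rev(vals), paste0("s", 1:8))))
  # zero overlapping observations after NA alignment in this construction
  out <- spearman_screen(x, y, min_n = 5, keep_all = TRUE)
  expect_equal(nrow(out), 0)
})

test_that("correlated/up intersection carries provenance", {
  corr <- tibble::tibble(x_id = "DPM1", y_id = c("f1", "f2", "f3"),
                         rho = c(0.9, 0.8, 0.7),
                         p_value = c(0.001, 0.002, 0.003), n = 10)
  calls <- tibble::tibble(feature_id = c("f1", "f3", "f4"),
                          fold_change = c(2, 3, 4), p_value = 0.01,
                          label = c("up", "down", "up"),
                          branch = c("A_direct_up", "C_direct_down",
                                     "A_direct_up"))
  out <- intersect_with_de(corr, calls, labels = "up")
  expect_equal(out$y_id, "f1")
  expect_equal(out$rho, 0.9)
  expect_equal(out$de_fold_change, 2)
  both <- intersect_with_de(corr, calls, labels = c("up", "down"))
  expect_setequal(both$y_id, c("f1", "f3"))
  none <- intersect_with_de(corr[0, ], calls)
  expect_equal(nrow(none), 0)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- paste0("g", 1:12)
  term <- paste0("g", 1:4)
  query <- paste0("g", c(1, 2, 5, 6, 7))
  out <- ora_enrichment(query, list(t = term), universe)
  # brute force: P(overlap >= 2) enumerating all 5-subsets of the universe
  combos <- utils::combn(12, 5)
  hits <- colSums(combos <= 4)
  expect_equal(out$p_value, mean(hits >= 2), tolerance = 1e-12)
  expect_equal(out$overlap, 2)

  disjoint <- ora_enrichment(paste0("g", 9:12), list(t = paste0("g", 1:4)),
                             universe)
  expect_equal(disjoint$p_value, 1)

  all_in <- ora_enrichment(universe, list(t = universe), universe)
  expect_equal(all_in$overlap, 12)
  expect_equal(all_in$p_value, 1)
})

test_that("BH correction is monotone in sorted raw p", {
  set.seed(61)
  ann <- lapply(1:8, function(i) sample(paste0("g", 1:30), 6))
  names(ann) <- paste0("t", 1:8)
  out <- ora_enrichment(paste0("g", 1:10), ann, paste0("g", 1:30))
  expect_true(all(diff(out$bh_fdr[order(out$p_value)]) >= -1e-12))
  expect_true(all(out$bh_fdr >= out$p_value - 1e-12))
})
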