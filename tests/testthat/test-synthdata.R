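test_that("configuration validation rejects infeasible designs", {
  expect_error(sim_config(glycan_class_mixture = c(
    mannose = 0.5, sialylated = 0.5, fucosylated = 0,
    complex_hybrid = 0.2, fucosylated_sialylated = -0.2)), "sum to 1")
  expect_error(sim_config(glycan_class_mixture = c(
    mannose = 0.6, sialylated = 0.2, fucosylated = 0.2,
    complex_hybrid = 0.2, fucosylated_sialylated = 0.2)), "sum to 1")
  expect_error(sim_config(n_pairs = 20, n_batches = 2,
                          channels_per_batch = 10), "infeasible")
  expect_error(sim_config(protein_effect_size = 0.5, effect_size = 1),
               "exceed")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_proteins = 40, seed = 77)
  a <- simulate_glyco_study(cfg)
  b <- simulate_glyco_study(cfg)
  expect_identical(a$glycopeptides, b$glycopeptides)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth, b$truth)

  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  pa <- write_sim_dataset(a, dir_a)
  pb <- write_sim_dataset(b, dir_b)
  expect_identical(unname(tools::md5sum(pa)), unname(tools::md5sum(pb)))

  c2 <- simulate_glyco_study(sim_config(n_proteins = 40, seed = 78))
  expect_false(identical(a$glycopeptides, c2$glycopeptides))
})

test_that("written datasets re-read through the standard readers", {
  sim <- simulate_glyco_study(sim_config(n_proteins = 30, seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_sim_dataset(sim, dir)
  gp <- read_quant_table(paths[["glycopeptides"]], "glycopeptide")
  expect_equal(nrow(gp), nrow(sim$glycopeptides))
  pr <- read_quant_table(paths[["proteins"]], "protein")
  expect_equal(pr$accession, sim$proteins$accession)
  d <- read_study_design(paths[["design"]])
  expect_equal(d$sample_id, sim$design$sample_id)
  gs <- read_gene_sets(paths[["gene_sets"]])
  expect_equal(gs, sim$gene_sets)
})

test_that("sampled compositions round-trip through classification", {
  sim <- simulate_glyco_study(sim_config(n_proteins = 60, seed = 13))
  tr <- sim$truth$glycopeptides
  # every emitted composition classifies into one of the five classes and
  # parses canonically
  expect_identical(canonical_glycan(tr$glycan), tr$glycan)
  expect_false(anyNA(classify_glycan(tr$glycan)))
})

test_that("generator marginals match the configured design", {
  cfg <- sim_config(n_proteins = 2000, seed = 17)
  sim <- simulate_glyco_study(cfg)
  des <- landscape_design(cfg)
  rec <- sim$glycopeptides[c("accession", "site", "peptide",
                             "glycan_composition")]
  lc <- landscape_counts(rec)
  expect_equal(lc$n_glycoproteins, des$n_glycoproteins)
  # glycopeptide count within 3 SD of its closed-form expectation (allowing
  # a small deficit from within-site composition collisions)
  expect_lt(lc$n_glycopeptides,
            des$expected_glycopeptides + 3 * des$sd_glycopeptides)
  expect_gt(lc$n_glycopeptides,
            des$expected_glycopeptides - 3 * des$sd_glycopeptides -
              0.01 * des$expected_glycopeptides)

  # single-site proportion matches the geometric parameter
  spp <- sites_per_protein_distribution(rec)
  p1 <- spp$proportion[spp$n_sites == 1]
  se <- sqrt(cfg$sites_prob * (1 - cfg$sites_prob) / cfg$n_proteins)
  expect_lt(abs(p1 - cfg$sites_prob), 4 * se)

  # class mixture recovery over emitted glycoforms
  tp <- type_proportions(sim$truth$glycopeptides$glycan, "site_specific")
  mix <- cfg$glycan_class_mixture[tp$glycan_type]
  se_mix <- sqrt(mix * (1 - mix) / lc$n_glycopeptides)
  expect_true(all(abs(tp$proportion - mix) < 4 * se_mix + 0.01))

  # sequon mixture recovery
  sq <- sequon_proportions(sim$glycopeptides)
  expect_true(all(abs(sq$proportion - cfg$sequon_probs[as.character(sq$motif)])
                  < 0.03))
})

test_that("a noiseless null gives fold changes of exactly 1", {
  cfg <- sim_config(n_proteins = 30, sigma_noise = 0, patient_sd = 0,
                    batch_effect_sd = 0, ref_noise_sd = 0, mnar_scale = 0,
                    effect_size = 1e-9, protein_effect_size = 1,
                    frac_direct_up = 0, frac_direct_down = 0,
                    frac_protein_up = 0, frac_protein_down = 0,
                    signature_shifts = 0, seed = 3)
  sim <- simulate_glyco_study(cfg)
  res <- run_pipeline(sim$glycopeptides, sim$design, sim$proteins)
  expect_equal(res$differential$calls$fold_change,
               rep(1, nrow(res$differential$calls)))
  expect_equal(sum(res$differential$calls$label != "unchanged"), 0)
})

test_that("an injected glycopeptide effect with a flat protein is called A", {
  cfg <- sim_config(n_proteins = 40, sigma_noise = 0.05, patient_sd = 0,
                    batch_effect_sd = 0, mnar_scale = 0, effect_size = 2,
                    protein_effect_size = 3,
                    frac_direct_up = 0.02, frac_direct_down = 0,
                    frac_protein_up = 0, frac_protein_down = 0,
                    frac_protein_quantified = 1, signature_shifts = 0,
                    seed = 9)
  sim <- simulate_glyco_study(cfg)
  truth <- sim$truth$glycopeptides
  expect_true(any(truth$true_branch == "A_direct_up"))
  res <- run_pipeline(sim$glycopeptides, sim$design, sim$proteins)
  calls <- tibble::as_tibble(res$differential$calls)
  hit <- calls[calls$feature_id %in%
                 truth$feature_id[truth$true_branch == "A_direct_up"], ]
  expect_true(all(hit$branch == "A_direct_up"))
  expect_true(all(hit$label == "up"))
})

test_that("pooled-reference ratioing is unbiased for null contrasts", {
  cfg <- sim_config(n_proteins = 400, frac_direct_up = 0,
                    frac_direct_down = 0, frac_protein_up = 0,
                    frac_protein_down = 0, signature_shifts = 0,
                    mnar_scale = 0, seed = 23)
  sim <- simulate_glyco_study(cfg)
  res <- run_pipeline(sim$glycopeptides, sim$design, sim$proteins)
  st <- res$differential$calls
  # tumor/NAT log2 fold changes of null features center on zero
  se <- stats::sd(st$log2_fc) / sqrt(nrow(st))
  expect_lt(abs(mean(st$log2_fc)), 4 * se + 0.01)
  # pooling shifts all samples of a batch equally, so the mean log2 ratio
  # sits near (not mechanically at) zero
  mat <- as.matrix(res$quant$glycopeptides[design_samples(sim$design)])
  expect_lt(abs(mean(mat, na.rm = TRUE)), 0.15)
})

test_that("ground-truth labels agree with the stated decision semantics", {
  sim <- simulate_glyco_study(sim_config(n_proteins = 150, seed = 29))
  tr <- sim$truth$glycopeptides
  # spot-check with the independent scalar oracle
  set.seed(1)
  idx <- sample(nrow(tr), 60)
  for (i in idx) {
    prot <- NULL
    if (tr$protein_quantified[i]) {
      pe <- tr$protein_effect[i]
      prot <- list(fc = 2^pe,
                   status = protein_status_of(2^pe,
                                              ifelse(pe != 0, 0, 1)))
    }
    expect_equal(
      oracle_classify(2^tr$gp_effect[i],
                      ifelse(tr$gp_effect[i] != 0, 0, 1), prot),
      ifelse(tr$true_branch[i] == "none", "none", tr$true_branch[i])
    )
  }
})
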