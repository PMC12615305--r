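# Composition grids per glycan class. Each class samples from a realistic
# composition range so that classification round-trips exactly.
.class_grids <- local({
  grid <- function(n, h, f, s) {
    g <- expand.grid(hexnac = n, hex = h, fuc = f, neuac = s)
    sprintf("N%dH%dF%dS%d", g$hexnac, g$hex, g$fuc, g$neuac)
  }
  list(
    mannose = grid(2, 5:12, 0, 0),
    sialylated = grid(3:6, 4:7, 0, 1:4),
    fucosylated = grid(3:6, 3:7, 1:3, 0),
    complex_hybrid = c(grid(3:5, 3:6, 0, 0), grid(2, 3:4, 0, 0)),
    fucosylated_sialylated = grid(4:6, 5:7, 1:2, 1:3)
  )
})

#' Simulation configuration
#'
#' Describes a paired tumor/NAT TMT glycoproteomics study for the synthetic
#' generator. The defaults emulate the tissue study design this package
#' targets: 10 patient pairs split over 3 TMT-10plex batches, each batch
#' carrying a pooled reference channel built from equal parts of all batch
#' members; log2-scale measurement noise of 0.4; intensity-dependent (MNAR)
#' missingness; and a five-class glycan mixture dominated by high-mannose
#' and fucosylated compositions.
#'
#' Differential structure: a fraction of glycopeptides on
#' protein-level-flat proteins receive a direct glycopeptide effect
#' (`frac_direct_up` / `frac_direct_down`, magnitude `effect_size` in log2
#' units), while dedicated proteins receive a protein-level effect of
#' magnitude `protein_effect_size` whose glycopeptides move only by
#' `effect_size`, creating relative occupancy changes (the protein rises or
#' falls more than the glycopeptide).
#'
#' @param n_proteins Number of glycoproteins.
#' @param sites_prob Geometric parameter for sites per protein
#'   (`P(single site)`; default 0.78).
#' @param max_sites Cap on sites per protein.
#' @param glycoforms_prob Geometric parameter for glycoforms per site.
#' @param max_glycoforms Cap on glycoforms per site.
#' @param glycan_class_mixture Named 5-vector of class probabilities
#'   (must sum to 1).
#' @param sequon_probs Named probabilities for NXT/NXS/NXC motifs.
#' @param n_pairs Patient pairs (each contributes one Tumor + one NAT).
#' @param n_batches TMT batches; pairs are dealt round-robin.
#' @param channels_per_batch Plex capacity (default 10).
#' @param base_mean,base_sd Log2 baseline abundance distribution.
#' @param sigma_noise Log2 measurement noise SD.
#' @param batch_effect_sd Per-feature, per-batch log2 shift SD.
#' @param patient_sd Per-feature, per-pair biological SD (shared by the
#'   pair's tumor and NAT, making paired tests meaningful).
#' @param ref_noise_sd Noise on the pooled reference channel.
#' @param effect_size Glycopeptide log2 effect magnitude.
#' @param protein_effect_size Protein log2 effect magnitude for occupancy
#'   proteins (must exceed `effect_size`).
#' @param frac_direct_up,frac_direct_down Fractions of glycopeptides given
#'   direct up/down effects.
#' @param frac_protein_up,frac_protein_down Fractions of proteins given
#'   protein-level effects (driving the occupancy branches).
#' @param frac_protein_quantified Fraction of the remaining glycoproteins
#'   present in the protein table (emulating partial proteome overlap).
#' @param mnar_quantile Quantile of the log2 intensity distribution at which
#'   the missingness logistic reaches 50%.
#' @param mnar_scale Logistic scale of the missingness curve (log2 units);
#'   `mnar_scale = 0` disables missingness.
#' @param n_signatures,genes_per_signature Immune signature layout; genes
#'   are drawn from effect-free quantified proteins.
#' @param signature_shifts Log2 tumor shifts applied to each signature's
#'   genes (recycled to `n_signatures`).
#' @param seed Integer seed; all randomness in [simulate_glyco_study()]
#'   flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 450,
                       sites_prob = 0.78,
                       max_sites = 8,
                       glycoforms_prob = 0.22,
                       max_glycoforms = 12,
                       glycan_class_mixture = c(
                         mannose = 0.34, sialylated = 0.17,
                         fucosylated = 0.23, complex_hybrid = 0.11,
                         fucosylated_sialylated = 0.15),
                       sequon_probs = c(NXT = 0.531, NXS = 0.418, NXC = 0.051),
                       n_pairs = 10,
                       n_batches = 3,
                       channels_per_batch = 10,
                       base_mean = 20, base_sd = 2,
                       sigma_noise = 0.4,
                       batch_effect_sd = 0.2,
                       patient_sd = 0.3,
                       ref_noise_sd = 0.05,
                       effect_size = 1,
                       protein_effect_size = 2,
                       frac_direct_up = 0.03,
                       frac_direct_down = 0.03,
                       frac_protein_up = 0.02,
                       frac_protein_down = 0.02,
                       frac_protein_quantified = 0.6,
                       mnar_quantile = 0.03,
                       mnar_scale = 0.5,
                       n_signatures = 4,
                       genes_per_signature = 15,
                       signature_shifts = c(-1, -1, -1, 1),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (any(cfg$glycan_class_mixture < 0) ||
      abs(sum(cfg$glycan_class_mixture) - 1) > 1e-8) {
    stop("glycan_class_mixture must be non-negative and sum to 1.",
         call. = FALSE)
  }
  if (!setequal(names(cfg$glycan_class_mixture), glycan_type_levels)) {
    stop("glycan_class_mixture must be named by the five glycan types.",
         call. = FALSE)
  }
  if (abs(sum(cfg$sequon_probs) - 1) > 1e-8) {
    stop("sequon_probs must sum to 1.", call. = FALSE)
  }
  # every batch must fit its pairs plus the reference channel
  pairs_per_batch <- tabulate(((seq_len(cfg$n_pairs) - 1) %% cfg$n_batches) + 1,
                              nbins = cfg$n_batches)
  if (any(2 * pairs_per_batch + (cfg$n_batches > 1) > cfg$channels_per_batch)) {
    stop("Design infeasible: a batch needs more channels than ",
         cfg$channels_per_batch, ".", call. = FALSE)
  }
  if (cfg$protein_effect_size <= cfg$effect_size) {
    stop("protein_effect_size must exceed effect_size for occupancy ",
         "branches to exist.", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# truncated geometric on 1..max with P(1) = prob
.rtrunc_geom <- function(n, prob, max) {
  pmin(1L + stats::rgeom(n, prob), max)
}

.trunc_geom_pmf <- function(prob, max) {
  k <- seq_len(max)
  p <- prob * (1 - prob)^(k - 1)
  p[max] <- (1 - prob)^(max - 1)
  p
}

#' Expected landscape of a simulation configuration
#'
#' Closed-form expectations used to validate the generator: expected counts
#' of glycoproteins, glycosites and glycopeptides, the standard deviation of
#' the glycopeptide count, and the configured class mixture. Expectations
#' ignore the rare event that one site draws more compositions of a class
#' than its grid holds (a sub-percent deficit at the defaults).
#'
#' @param cfg A [sim_config()].
#' @return List: `n_glycoproteins`, `expected_glycosites`,
#'   `expected_glycopeptides`, `sd_glycopeptides`, `class_mixture`.
#' @export
landscape_design <- function(cfg) {
  ps <- .trunc_geom_pmf(cfg$sites_prob, cfg$max_sites)
  pg <- .trunc_geom_pmf(cfg$glycoforms_prob, cfg$max_glycoforms)
  ks <- seq_len(cfg$max_sites)
  kg <- seq_len(cfg$max_glycoforms)
  e_s <- sum(ks * ps); v_s <- sum(ks^2 * ps) - e_s^2
  e_g <- sum(kg * pg); v_g <- sum(kg^2 * pg) - e_g^2
  # per-protein glycopeptide total = sum over S sites of G_i
  e_tot <- e_s * e_g
  v_tot <- e_s * v_g + v_s * e_g^2
  list(
    n_glycoproteins = cfg$n_proteins,
    expected_glycosites = cfg$n_proteins * e_s,
    expected_glycopeptides = cfg$n_proteins * e_tot,
    sd_glycopeptides = sqrt(cfg$n_proteins * v_tot),
    class_mixture = cfg$glycan_class_mixture
  )
}

# random tryptic-like peptide with an N at a known sequon position
.make_peptides <- function(n_sites, sequon_probs) {
  aa_pool <- strsplit("ACDEFGHILMQSTVWY", "")[[1]]  # no K/R/N/P to keep motifs clean
  len <- sample(9:18, n_sites, replace = TRUE)
  pos <- vapply(len, function(l) sample.int(l - 3L, 1), integer(1))
  motif <- sample(names(sequon_probs), n_sites, replace = TRUE,
                  prob = sequon_probs)
  third <- c(NXT = "T", NXS = "S", NXC = "C")[motif]
  pep <- vapply(seq_len(n_sites), function(i) {
    p <- sample(aa_pool, len[i], replace = TRUE)
    p[pos[i]] <- "N"
    p[pos[i] + 2L] <- third[i]
    p[len[i]] <- sample(c("K", "R"), 1)
    paste(p, collapse = "")
  }, character(1))
  tibble::tibble(peptide = pep, site_in_peptide = pos, motif = motif)
}

# truth labels from the same verbal rules the classifier implements,
# evaluated on the noise-free effects
.true_calls <- function(gp_eff, prot_eff, prot_quant, th = glyco_thresholds()) {
  gp_fc <- 2^gp_eff
  pr_fc <- 2^prot_eff
  prot_sig_up <- prot_quant & pr_fc > th$fc_up
  prot_sig_dn <- prot_quant & pr_fc < th$fc_down
  no_change <- !prot_quant | (!prot_sig_up & !prot_sig_dn)
  up_gate <- gp_fc > th$fc_up
  dn_gate <- gp_fc < th$fc_down
  branch <- dplyr::case_when(
    up_gate & (no_change | (prot_quant & gp_fc > pr_fc)) ~ "A_direct_up",
    up_gate & prot_sig_up & pr_fc > gp_fc ~ "D_occupancy_down",
    dn_gate & (no_change | (prot_quant & gp_fc < pr_fc)) ~ "C_direct_down",
    dn_gate & prot_sig_dn & pr_fc < gp_fc ~ "B_occupancy_up",
    TRUE ~ "none"
  )
  label <- dplyr::case_when(
    branch %in% c("A_direct_up", "B_occupancy_up") ~ "up",
    branch %in% c("C_direct_down", "D_occupancy_down") ~ "down",
    TRUE ~ "unchanged"
  )
  list(branch = branch, label = label)
}

#' Simulate a paired tumor/NAT TMT glycoproteomics study
#'
#' Generates a glycopeptide intensity table, a protein intensity table, a
#' study design, immune gene sets and the ground truth, all consistent with
#' the schemas the quantification functions read. Intensities follow
#' `2^(baseline + pair effect + batch effect + condition effect + noise)`;
#' each batch's pooled reference channel is the linear mean of that batch's
#' member intensities (equal-parts pooling) plus a small labeling noise;
#' low intensities are censored by a logistic missing-not-at-random rule.
#' The output is deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `glyco_simulation`: `glycopeptides` and `proteins`
#'   (wide intensity tibbles), `design`, `gene_sets`, `truth` (list with
#'   `glycopeptides`, `proteins`, `signatures` tibbles), and `config`.
#' @export
simulate_glyco_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  ## --- identification structure -------------------------------------------
  acc <- sprintf("P%04d", seq_len(cfg$n_proteins))
  n_sites <- .rtrunc_geom(cfg$n_proteins, cfg$sites_prob, cfg$max_sites)
  sites <- tibble::tibble(
    accession = rep(acc, n_sites),
    site = unlist(lapply(n_sites, function(k) sort(sample(30:900, k))))
  )
  sites <- dplyr::bind_cols(sites,
                            .make_peptides(nrow(sites), cfg$sequon_probs))
  n_forms <- .rtrunc_geom(nrow(sites), cfg$glycoforms_prob, cfg$max_glycoforms)
  draw_site_glycans <- function(k) {
    cls <- sample(glycan_type_levels, k, replace = TRUE,
                  prob = cfg$glycan_class_mixture[glycan_type_levels])
    unlist(lapply(unique(cls), function(cl) {
      pool <- .class_grids[[cl]]
      m <- min(sum(cls == cl), length(pool))
      sample(pool, m)
    }))
  }
  glycans_per_site <- lapply(n_forms, draw_site_glycans)
  gp <- sites[rep(seq_len(nrow(sites)), lengths(glycans_per_site)), ]
  gp$glycan <- unlist(glycans_per_site)
  gp$feature_id <- paste(gp$accession, gp$site, gp$peptide, gp$glycan,
                         sep = "|")

  ## --- effect assignment ---------------------------------------------------
  n_up_prot <- round(cfg$frac_protein_up * cfg$n_proteins)
  n_dn_prot <- round(cfg$frac_protein_down * cfg$n_proteins)
  occ <- sample(acc, n_up_prot + n_dn_prot)
  prot_eff <- stats::setNames(rep(0, cfg$n_proteins), acc)
  prot_eff[occ[seq_len(n_up_prot)]] <- cfg$protein_effect_size
  prot_eff[occ[n_up_prot + seq_len(n_dn_prot)]] <- -cfg$protein_effect_size

  gp$gp_effect <- 0
  on_occ <- gp$accession %in% occ
  gp$gp_effect[on_occ] <- sign(prot_eff[gp$accession[on_occ]]) * cfg$effect_size
  free <- which(!on_occ)
  n_dup <- min(round(cfg$frac_direct_up * nrow(gp)), length(free))
  n_ddn <- min(round(cfg$frac_direct_down * nrow(gp)), length(free) - n_dup)
  pick <- sample(free, n_dup + n_ddn)
  gp$gp_effect[pick[seq_len(n_dup)]] <- cfg$effect_size
  gp$gp_effect[pick[n_dup + seq_len(n_ddn)]] <- -cfg$effect_size

  ## --- immune signatures ---------------------------------------------------
  null_acc <- setdiff(acc, c(occ, unique(gp$accession[gp$gp_effect != 0])))
  shifts <- rep_len(cfg$signature_shifts, cfg$n_signatures)
  # immune/stromal cell-type names mirroring the populations the scoring
  # stage summarizes; extra signatures get generic names
  name_pool <- c("Fibroblasts", "Endothelial_cells", "NK_cells",
                 "Epithelial_cells", "NKT_cells", "Memory_B_cells",
                 "Mast_cells", "CD4_Tem")
  sig_names <- c(utils::head(name_pool, cfg$n_signatures),
                 paste0("Signature_",
                        seq_len(max(0, cfg$n_signatures - length(name_pool)))))
  sig_names <- sig_names[seq_len(cfg$n_signatures)]
  need <- cfg$n_signatures * cfg$genes_per_signature
  sig_genes <- sample(null_acc, min(need, length(null_acc)))
  gene_sets <- split(sig_genes,
                     rep(sig_names,
                         each = cfg$genes_per_signature)[seq_along(sig_genes)])
  gene_sets <- gene_sets[intersect(sig_names, names(gene_sets))]
  for (k in seq_along(gene_sets)) {
    prot_eff[gene_sets[[k]]] <- shifts[match(names(gene_sets)[k], sig_names)]
  }

  ## --- which proteins are in the protein table ----------------------------
  must_quant <- unique(c(occ, sig_genes))
  rest <- setdiff(acc, must_quant)
  quantified <- c(must_quant,
                  sample(rest, round(cfg$frac_protein_quantified * length(rest))))
  prot_quant <- acc %in% quantified

  ## --- design --------------------------------------------------------------
  pair_batch <- ((seq_len(cfg$n_pairs) - 1) %% cfg$n_batches) + 1
  pair_id <- sprintf("pair%02d", seq_len(cfg$n_pairs))
  design <- tibble::tibble(
    sample_id = c(sprintf("T%02d", seq_len(cfg$n_pairs)),
                  sprintf("N%02d", seq_len(cfg$n_pairs))),
    batch = as.character(rep(pair_batch, 2)),
    condition = rep(c("Tumor", "NAT"), each = cfg$n_pairs),
    pair_id = rep(pair_id, 2),
    is_reference = FALSE
  )
  if (cfg$n_batches > 1) {
    design <- dplyr::bind_rows(design, tibble::tibble(
      sample_id = sprintf("REF_B%d", seq_len(cfg$n_batches)),
      batch = as.character(seq_len(cfg$n_batches)),
      condition = "Reference",
      pair_id = NA_character_,
      is_reference = TRUE
    ))
  }
  design <- design |>
    dplyr::arrange(.data$batch, .data$is_reference, .data$sample_id) |>
    dplyr::group_by(.data$batch) |>
    dplyr::mutate(channel = paste0("ch", sprintf("%02d", dplyr::row_number()))) |>
    dplyr::ungroup()
  design <- validate_study_design(
    design[c("sample_id", "batch", "channel", "condition", "pair_id",
             "is_reference")])

  ## --- intensity generation ------------------------------------------------
  members <- design[!design$is_reference, ]
  gen_matrix <- function(n_feat, base, effect, extra_sd = 0) {
    log2m <- matrix(base, nrow = n_feat, ncol = nrow(members))
    pair_idx <- match(members$pair_id, pair_id)
    pair_re <- matrix(stats::rnorm(n_feat * cfg$n_pairs, 0, cfg$patient_sd),
                      nrow = n_feat)
    batch_idx <- match(members$batch, as.character(seq_len(cfg$n_batches)))
    batch_re <- matrix(stats::rnorm(n_feat * cfg$n_batches, 0,
                                    cfg$batch_effect_sd), nrow = n_feat)
    log2m <- log2m + pair_re[, pair_idx, drop = FALSE] +
      batch_re[, batch_idx, drop = FALSE] +
      outer(effect, as.numeric(members$condition == "Tumor")) +
      matrix(stats::rnorm(n_feat * nrow(members), 0, cfg$sigma_noise),
             nrow = n_feat)
    colnames(log2m) <- members$sample_id
    log2m
  }
  finish_table <- function(log2m) {
    lin <- 2^log2m
    out <- lin
    if (cfg$mnar_scale > 0) {
      mid <- stats::quantile(log2m, cfg$mnar_quantile, na.rm = TRUE)
      pmiss <- stats::plogis((mid - log2m) / cfg$mnar_scale)
      out[matrix(stats::runif(length(out)), nrow = nrow(out)) < pmiss] <- NA
    }
    if (cfg$n_batches > 1) {
      for (b in as.character(seq_len(cfg$n_batches))) {
        bcols <- members$sample_id[members$batch == b]
        ref <- rowMeans(lin[, bcols, drop = FALSE]) *
          2^stats::rnorm(nrow(lin), 0, cfg$ref_noise_sd)
        out <- cbind(out, ref)
        colnames(out)[ncol(out)] <- paste0("REF_B", b)
      }
    }
    tibble::as_tibble(out)[design$sample_id]
  }

  gp_base <- stats::rnorm(nrow(gp), cfg$base_mean, cfg$base_sd)
  gp_tab <- dplyr::bind_cols(
    gp[c("accession", "site", "peptide", "site_in_peptide")],
    tibble::tibble(glycan_composition = gp$glycan),
    finish_table(gen_matrix(nrow(gp), gp_base, gp$gp_effect))
  )

  pr_acc <- acc[prot_quant]
  pr_base <- stats::rnorm(length(pr_acc), cfg$base_mean + 2, cfg$base_sd)
  pr_tab <- dplyr::bind_cols(
    tibble::tibble(
      accession = pr_acc,
      unique_peptides = 2L + stats::rpois(length(pr_acc), 3)
    ),
    finish_table(gen_matrix(length(pr_acc), pr_base, prot_eff[pr_acc]))
  )

  ## --- ground truth ---------------------------------------------------------
  tc <- .true_calls(gp$gp_effect, prot_eff[gp$accession],
                    gp$accession %in% pr_acc)
  truth_gp <- tibble::tibble(
    feature_id = gp$feature_id,
    accession = gp$accession,
    glycan = gp$glycan,
    gp_effect = gp$gp_effect,
    protein_effect = unname(prot_eff[gp$accession]),
    protein_quantified = gp$accession %in% pr_acc,
    true_label = tc$label,
    true_branch = tc$branch
  )
  truth_pr <- tibble::tibble(
    accession = acc,
    protein_effect = unname(prot_eff),
    quantified = prot_quant,
    true_status = dplyr::case_when(
      !prot_quant ~ "not_quantified",
      2^prot_eff > 1.5 ~ "sig_up",
      2^prot_eff < 0.67 ~ "sig_down",
      TRUE ~ "not_sig"
    )
  )
  truth_sig <- tibble::tibble(
    signature = names(gene_sets),
    shift = shifts[match(names(gene_sets), sig_names)]
  )

  structure(
    list(glycopeptides = gp_tab, proteins = pr_tab, design = design,
         gene_sets = gene_sets,
         truth = list(glycopeptides = truth_gp, proteins = truth_pr,
                      signatures = truth_sig),
         config = cfg),
    class = "glyco_simulation"
  )
}

#' @export
print.glyco_simulation <- function(x, ...) {
  cat("Synthetic glycoproteomics study:",
      nrow(x$glycopeptides), "glycopeptides,",
      nrow(x$proteins), "proteins,",
      sum(!x$design$is_reference), "samples in",
      length(unique(x$design$batch)), "batch(es)\n")
  cat("Ground-truth calls:",
      sum(x$truth$glycopeptides$true_label == "up"), "up,",
      sum(x$truth$glycopeptides$true_label == "down"), "down\n")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the generator output in exactly the formats the readers accept:
#' TSV quantification tables, a TSV design, a GMT gene-set file, and TSV
#' ground-truth tables.
#'
#' @param sim A `glyco_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "glyco_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    glycopeptides = file.path(dir, "glycopeptides.tsv"),
    proteins = file.path(dir, "proteins.tsv"),
    design = file.path(dir, "design.tsv"),
    gene_sets = file.path(dir, "signatures.gmt"),
    truth_glycopeptides = file.path(dir, "truth_glycopeptides.tsv")
  )
  readr::write_tsv(sim$glycopeptides, paths["glycopeptides"])
  readr::write_tsv(sim$proteins, paths["proteins"])
  readr::write_tsv(sim$design, paths["design"])
  write_gene_sets(sim$gene_sets, paths["gene_sets"])
  readr::write_tsv(sim$truth$glycopeptides, paths["truth_glycopeptides"])
  invisible(paths)
}
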