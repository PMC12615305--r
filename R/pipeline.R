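#' Run the full comparative glycoproteomics pipeline
#'
#' Orchestrates the stages end to end: batch normalization, reference
#' ratioing and integration (or single-batch normalization when the design
#' has no reference channels), missingness filtering, identification
#' landscape statistics, protein differential expression, protein-corrected
#' glycopeptide classification with the glycan-type breakdown, PCA, and —
#' when gene sets / an enzyme list are supplied — ssGSEA immune scoring,
#' immune differential enrichment, glycosyltransferase selection and the
#' enzyme-glycopeptide correlation screen.
#'
#' @param glycopeptides Glycopeptide intensity tibble (schema of
#'   [read_quant_table()]) or a path to one.
#' @param design Design tibble or path ([read_study_design()]).
#' @param proteins Optional protein intensity tibble or path.
#' @param gene_sets Optional named list of gene sets or a GMT path.
#' @param gt_list Optional character vector of glycosyltransferase ids (or a
#'   path to a one-id-per-line file).
#' @param group_a,group_b Conditions compared (fold changes are a/b).
#' @param thresholds [glyco_thresholds()].
#' @param assoc [assoc_thresholds()].
#' @param min_fraction Missingness filter threshold (default 0.5).
#' @param paired Use paired t-tests.
#' @param use_fc_down_alt Use the relaxed cell-line down cutoff.
#' @param out_dir Optional directory; when given, TSV tables and a
#'   `summary.json` are written there.
#' @return List of class `glyco_pipeline` with elements `quant`
#'   (filtered matrices + filter reports), `landscape`, `differential`
#'   (calls, type breakdown, protein stats), `pca`, `association` (or
#'   `NULL`), and `summary` (the headline statistics).
#' @export
run_pipeline <- function(glycopeptides, design, proteins = NULL,
                         gene_sets = NULL, gt_list = NULL,
                         group_a = "Tumor", group_b = "NAT",
                         thresholds = glyco_thresholds(),
                         assoc = assoc_thresholds(),
                         min_fraction = 0.5, paired = FALSE,
                         use_fc_down_alt = FALSE, out_dir = NULL) {
  if (is.character(design)) design <- read_study_design(design)
  design <- validate_study_design(design)
  if (is.character(glycopeptides)) {
    glycopeptides <- read_quant_table(glycopeptides, "glycopeptide")
  } else {
    glycopeptides <- build_feature_ids(glycopeptides, "glycopeptide")
  }
  if (nrow(glycopeptides) == 0) {
    stop("Glycopeptide table is empty.", call. = FALSE)
  }
  if (is.character(proteins)) proteins <- read_quant_table(proteins, "protein")
  if (!is.null(proteins)) proteins <- build_feature_ids(proteins, "protein")
  if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
  if (is.character(gt_list) && length(gt_list) == 1 && file.exists(gt_list)) {
    gt_list <- readr::read_lines(gt_list)
  }

  multi_batch <- any(design$is_reference)
  gp_mat <- process_quant(glycopeptides, design, multi_batch)
  gp_filt <- apply_quant_filter(gp_mat, design, min_fraction = min_fraction)
  pr_filt <- NULL
  if (!is.null(proteins)) {
    pr_mat <- process_quant(proteins, design, multi_batch)
    pr_filt <- apply_quant_filter(pr_mat, design, min_fraction = min_fraction)
  }

  records <- glycopeptides[intersect(
    c("accession", "site", "peptide", "glycan", "site_in_peptide"),
    names(glycopeptides))]
  landscape <- list(
    counts = landscape_counts(records),
    sites_per_protein = sites_per_protein_distribution(records),
    glycans_per_site = glycans_per_site_distribution(records),
    type_proportions_site_specific = type_proportions(records, "site_specific"),
    type_proportions_unique = type_proportions(records, "unique_composition"),
    type_cooccurrence = type_cooccurrence_at_sites(records)
  )
  if ("site_in_peptide" %in% names(records)) {
    landscape$sequon <- sequon_proportions(records)
  }

  gp_stats <- feature_stats(gp_filt, design, group_a, group_b, paired = paired)
  pr_stats <- NULL
  if (!is.null(pr_filt)) {
    pr_stats <- call_protein_de(
      feature_stats(pr_filt, design, group_a, group_b, paired = paired),
      thresholds)
  }
  calls <- classify_glycopeptides(
    attach_feature_meta(gp_stats, glycopeptides),
    pr_stats, thresholds, use_fc_down_alt = use_fc_down_alt)
  type_breakdown <- de_by_glycan_type(calls)
  pca <- tryCatch(pca_summary(gp_filt, design), error = function(e) NULL)

  association <- NULL
  if (!is.null(pr_filt) && (!is.null(gene_sets) || !is.null(gt_list))) {
    association <- list()
    if (!is.null(gene_sets)) {
      scores <- ssgsea_scores(pr_filt, gene_sets, design)
      stromal <- intersect(c("Fibroblasts", "Endothelial_cells"),
                           scores$signature)
      if (length(stromal) > 0) {
        scores <- composite_scores(scores, stromal_signatures = stromal)
      }
      association$scores <- scores
      association$immune <- immune_differential(scores, design, group_a,
                                                group_b, assoc)
    }
    if (!is.null(gt_list)) {
      gts <- select_glycosyltransferases(pr_stats, gt_list, thresholds)
      association$glycosyltransferases <- gts
      sig_up_gts <- gts[gts$protein_status == "sig_up", , drop = FALSE]
      if (nrow(sig_up_gts) > 0) {
        corr <- spearman_screen(
          pr_filt[pr_filt$feature_id %in% sig_up_gts$feature_id, ],
          gp_filt, assoc)
        association$enzyme_glycopeptide <- corr
        association$enzyme_up_intersection <- intersect_with_de(corr, calls)
      }
    }
  }

  summary <- build_pipeline_summary(landscape, gp_filt, pr_filt, calls,
                                    type_breakdown, pca, association)
  res <- structure(
    list(quant = list(glycopeptides = gp_filt, proteins = pr_filt,
                      filter_report_glycopeptides = filter_report(gp_filt),
                      filter_report_proteins =
                        if (!is.null(pr_filt)) filter_report(pr_filt)),
         landscape = landscape,
         differential = list(calls = calls, by_glycan_type = type_breakdown,
                             protein_stats = pr_stats),
         pca = pca, association = association, summary = summary,
         design = design),
    class = "glyco_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# internal: normalize/ratio/integrate one table kind
process_quant <- function(df, design, multi_batch) {
  if (!multi_batch) {
    return(normalize_single_batch(df, design))
  }
  batches <- lapply(split(design, design$batch), function(sub) {
    cols <- intersect(sub$sample_id, names(df))
    if (length(cols) == 0) return(NULL)
    meta <- setdiff(names(df), design$sample_id)
    suppressWarnings(
      ratio_to_reference(normalize_batch(df[c(meta, cols)], sub), sub))
  })
  integrate_batches(Filter(Negate(is.null), batches), design)
}

build_pipeline_summary <- function(landscape, gp_filt, pr_filt, calls,
                                   type_breakdown, pca, association) {
  s <- list(
    n_glycopeptides = landscape$counts$n_glycopeptides,
    n_glycosites = landscape$counts$n_glycosites,
    n_glycoproteins = landscape$counts$n_glycoproteins,
    n_glycopeptides_quantified = nrow(gp_filt),
    n_proteins_quantified = if (!is.null(pr_filt)) nrow(pr_filt),
    n_up = sum(calls$label == "up"),
    n_down = sum(calls$label == "down"),
    branch_counts = as.list(table(calls$branch)),
    de_by_glycan_type = stats::setNames(
      purrr::map2(type_breakdown$n_up, type_breakdown$n_down,
                  ~list(up = .x, down = .y)),
      type_breakdown$glycan_type),
    type_proportions_site_specific = stats::setNames(
      as.list(landscape$type_proportions_site_specific$proportion),
      landscape$type_proportions_site_specific$glycan_type)
  )
  if (!is.null(landscape$sequon)) {
    s$sequon_proportions <- stats::setNames(
      as.list(landscape$sequon$proportion), as.character(landscape$sequon$motif))
  }
  if (!is.null(pca)) {
    s$pc1_pc2_variance <- sum(pca$variance$variance_explained[1:2])
  }
  if (!is.null(association$immune)) {
    s$immune_calls <- as.list(table(association$immune$call))
  }
  if (!is.null(association$glycosyltransferases)) {
    g <- association$glycosyltransferases
    s$n_glycosyltransferases <- nrow(g)
    s$n_glycosyltransferases_changed <- sum(g$protein_status != "not_sig")
  }
  if (!is.null(association$enzyme_up_intersection)) {
    s$n_correlated_and_up <-
      dplyr::n_distinct(association$enzyme_up_intersection$y_id)
  }
  s
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$quant$glycopeptides,
                   file.path(out_dir, "glycopeptides_normalized.tsv"))
  if (!is.null(res$quant$proteins)) {
    readr::write_tsv(res$quant$proteins,
                     file.path(out_dir, "proteins_normalized.tsv"))
  }
  readr::write_tsv(differential_table(res$differential$calls),
                   file.path(out_dir, "differential_glycopeptides.tsv"))
  readr::write_tsv(res$differential$by_glycan_type,
                   file.path(out_dir, "de_by_glycan_type.tsv"))
  readr::write_tsv(res$landscape$type_cooccurrence,
                   file.path(out_dir, "type_cooccurrence.tsv"))
  if (!is.null(res$association$scores)) {
    readr::write_tsv(res$association$scores,
                     file.path(out_dir, "ssgsea_scores.tsv"))
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.glyco_pipeline <- function(x, ...) {
  s <- x$summary
  cat("glycodelta pipeline result\n")
  cat(sprintf("  identified: %d glycopeptides / %d glycosites / %d glycoproteins\n",
              s$n_glycopeptides, s$n_glycosites, s$n_glycoproteins))
  cat(sprintf("  quantified after filter: %d glycopeptides\n",
              s$n_glycopeptides_quantified))
  cat(sprintf("  differential: %d up, %d down\n", s$n_up, s$n_down))
  if (!is.null(s$pc1_pc2_variance)) {
    cat(sprintf("  PC1+PC2 variance explained: %.1f%%\n",
                100 * s$pc1_pc2_variance))
  }
  invisible(x)
}

#' Compare two cohorts' identification runs
#'
#' Produces the subtype-comparison report for two identification record
#' sets: set algebra at the site-specific and unique-composition levels,
#' per-cohort glycan-type mixtures at both levels, and each cohort's top
#' glycans by site count.
#'
#' @param records_a,records_b Identification tibbles (e.g. the
#'   `glycopeptides` table of two studies).
#' @param n_top Rows for the top-glycan tables.
#' @return List: `comparison` (both levels), `type_proportions`
#'   (per cohort x level), `top_glycans` (per cohort).
#' @export
compare_cohort_runs <- function(records_a, records_b, n_top = 10) {
  list(
    comparison = dplyr::bind_rows(
      compare_cohorts(records_a, records_b, "site_specific"),
      compare_cohorts(records_a, records_b, "unique_composition")
    ),
    type_proportions = list(
      a = list(site_specific = type_proportions(records_a, "site_specific"),
               unique_composition = type_proportions(records_a, "unique_composition")),
      b = list(site_specific = type_proportions(records_b, "site_specific"),
               unique_composition = type_proportions(records_b, "unique_composition"))
    ),
    top_glycans = list(a = top_glycans_by_site_count(records_a, n_top),
                       b = top_glycans_by_site_count(records_b, n_top))
  )
}
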