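#' Differential thresholds
#'
#' Bundles the fold-change and significance cutoffs used for tissue
#' differential analysis. Defaults: up if fold change strictly greater than
#' 1.5, down if strictly less than 0.67, at p < 0.05. `fc_down_alt = 0.8` is
#' the relaxed down cutoff used for single-batch cell-line knockdown
#' screens.
#'
#' @param fc_up Upper fold-change cutoff (linear scale).
#' @param fc_down Lower fold-change cutoff.
#' @param alpha Two-sided p-value cutoff.
#' @param fc_down_alt Alternative lower cutoff for cell-line mode.
#' @return A list of class `glyco_thresholds`.
#' @export
glyco_thresholds <- function(fc_up = 1.5, fc_down = 0.67, alpha = 0.05,
                             fc_down_alt = 0.8) {
  stopifnot(fc_down > 0, fc_down < 1, fc_up > 1, alpha > 0, alpha < 1)
  structure(list(fc_up = fc_up, fc_down = fc_down, alpha = alpha,
                 fc_down_alt = fc_down_alt),
            class = "glyco_thresholds")
}

#' Per-feature two-group statistics
#'
#' Computes, for every feature of a log2 quant matrix, the geometric fold
#' change between two conditions (`2^(mean_a - mean_b)` of log2 values) and a
#' two-sided Student's t-test p-value. By default the test is unpaired with
#' pooled variance; `paired = TRUE` uses the design's `pair_id` to form
#' within-pair differences. Features with fewer than 2 non-missing values in
#' either group are excluded and reported with a reason code.
#'
#' @param df Quant tibble of log2 values (from [integrate_batches()] or
#'   [normalize_single_batch()]).
#' @param design Design tibble.
#' @param group_a,group_b Condition labels; the fold change is a/b
#'   (e.g. Tumor/NAT).
#' @param paired Logical; paired t-test on complete pairs.
#' @return A tibble: `feature_id`, `log2_fc`, `fold_change`, `p_value`,
#'   `n_a`, `n_b`. Excluded features are kept in attribute `excluded`
#'   (tibble: `feature_id`, `reason`).
#' @export
feature_stats <- function(df, design, group_a = "Tumor", group_b = "NAT",
                          paired = FALSE) {
  cols_a <- intersect(design_samples(design, group_a), names(df))
  cols_b <- intersect(design_samples(design, group_b), names(df))
  if (length(cols_a) == 0 || length(cols_b) == 0) {
    stop("No sample columns found for condition(s) '", group_a, "' / '",
         group_b, "'.", call. = FALSE)
  }
  xa <- as.matrix(df[cols_a])
  xb <- as.matrix(df[cols_b])
  if (paired) {
    sub <- design[design$sample_id %in% c(cols_a, cols_b), ]
    pa <- sub$pair_id[match(cols_a, sub$sample_id)]
    pb <- sub$pair_id[match(cols_b, sub$sample_id)]
    common <- intersect(pa[!is.na(pa)], pb[!is.na(pb)])
    d <- xa[, match(common, pa), drop = FALSE] -
      xb[, match(common, pb), drop = FALSE]
    n <- rowSums(!is.na(d))
    md <- rowMeans(d, na.rm = TRUE)
    sdd <- apply(d, 1, stats::sd, na.rm = TRUE)
    se <- sdd / sqrt(n)
    tstat <- md / se
    tstat[sdd == 0 & md == 0] <- 0
    tstat[sdd == 0 & md != 0] <- Inf * sign(md[sdd == 0 & md != 0])
    p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
    na_ct <- nb_ct <- n
    lfc <- md
    defined <- n >= 2
  } else {
    na_ct <- rowSums(!is.na(xa))
    nb_ct <- rowSums(!is.na(xb))
    ma <- rowMeans(xa, na.rm = TRUE)
    mb <- rowMeans(xb, na.rm = TRUE)
    va <- apply(xa, 1, stats::var, na.rm = TRUE)
    vb <- apply(xb, 1, stats::var, na.rm = TRUE)
    sp2 <- ((na_ct - 1) * va + (nb_ct - 1) * vb) / (na_ct + nb_ct - 2)
    se <- sqrt(sp2 * (1 / na_ct + 1 / nb_ct))
    lfc <- ma - mb
    tstat <- lfc / se
    # degenerate zero-variance features: identical groups are a clean null,
    # separated constant groups are maximally significant
    zero <- !is.na(sp2) & sp2 == 0
    tstat[zero & lfc == 0] <- 0
    tstat[zero & lfc != 0] <- Inf * sign(lfc[zero & lfc != 0])
    p <- 2 * stats::pt(abs(tstat), df = na_ct + nb_ct - 2, lower.tail = FALSE)
    defined <- na_ct >= 2 & nb_ct >= 2
  }
  out <- tibble::tibble(
    feature_id = df$feature_id,
    log2_fc = lfc,
    fold_change = 2^lfc,
    p_value = p,
    n_a = na_ct,
    n_b = nb_ct
  )
  excluded <- tibble::tibble(
    feature_id = out$feature_id[!defined],
    reason = "fewer than 2 quantified values in a group"
  )
  out <- out[defined, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Protein differential expression call
#'
#' Labels proteins `sig_up` when fold change exceeds `fc_up` at p below
#' `alpha`, `sig_down` when below `fc_down` at p below `alpha`, otherwise
#' `not_sig`. All comparisons are strict, so a fold change exactly at the
#' cutoff is not significant. A Benjamini-Hochberg FDR column is added for
#' reporting but does not enter the call.
#'
#' @param stats Tibble from [feature_stats()].
#' @param thresholds A [glyco_thresholds()] object.
#' @return `stats` with `bh_fdr` and `protein_status` columns.
#' @export
call_protein_de <- function(stats, thresholds = glyco_thresholds()) {
  stats$bh_fdr <- stats::p.adjust(stats$p_value, method = "BH")
  stats$protein_status <- dplyr::case_when(
    stats$fold_change > thresholds$fc_up & stats$p_value < thresholds$alpha ~ "sig_up",
    stats$fold_change < thresholds$fc_down & stats$p_value < thresholds$alpha ~ "sig_down",
    TRUE ~ "not_sig"
  )
  stats
}

#' Protein-corrected glycopeptide classification
#'
#' Implements the four-branch decision tree that separates genuine
#' glycosylation changes from protein-abundance changes. A glycopeptide
#' passing the up gate (fc > `fc_up`, p < `alpha`) is called up via branch
#' `A_direct_up` when its protein is not significantly changed, not
#' quantified, or shows a smaller fold change; when the protein is
#' significantly up with a *larger* increase, the glycopeptide is called
#' down via `D_occupancy_down` (relative occupancy decreased). Symmetrically
#' for the down gate: `C_direct_down`, and `B_occupancy_up` when the protein
#' dropped even more. Everything else is `unchanged`. Exact fold-change ties
#' between glycopeptide and protein satisfy neither the direct comparison
#' nor the occupancy comparison and resolve through the protein-significance
#' clause, falling to `unchanged` when the protein is significant.
#'
#' @param gp_stats Glycopeptide tibble from [feature_stats()], with an
#'   `accession` column (add via [attach_feature_meta()] or a join) linking
#'   each glycopeptide to its protein.
#' @param protein_stats Protein tibble from [call_protein_de()] (columns
#'   `feature_id`, `fold_change`, `p_value`, `protein_status`). Glycopeptides
#'   whose accession is absent are treated as `not_quantified` and classified
#'   on their own fold change alone.
#' @param thresholds A [glyco_thresholds()] object; `use_fc_down_alt = TRUE`
#'   swaps in the relaxed cell-line down cutoff.
#' @param occupancy_requires_protein_sig When `TRUE` (default) the occupancy
#'   branches B/D require the protein itself to pass significance; when
#'   `FALSE` any quantified protein with a more extreme fold change in the
#'   same direction triggers them.
#' @param use_fc_down_alt Use `thresholds$fc_down_alt` as the down cutoff.
#' @return An object of class `glyco_differential`: the glycopeptide tibble
#'   with `protein_status`, `protein_fc`, `protein_p`, `label`
#'   (up/down/unchanged) and `branch` columns.
#' @export
classify_glycopeptides <- function(gp_stats, protein_stats = NULL,
                                   thresholds = glyco_thresholds(),
                                   occupancy_requires_protein_sig = TRUE,
                                   use_fc_down_alt = FALSE) {
  if (!"accession" %in% names(gp_stats)) {
    gp_stats$accession <- sub("\\|.*$", "", gp_stats$feature_id)
  }
  fc_dn <- if (use_fc_down_alt) thresholds$fc_down_alt else thresholds$fc_down
  fc_up <- thresholds$fc_up
  alpha <- thresholds$alpha

  if (is.null(protein_stats) || nrow(protein_stats) == 0) {
    prot <- tibble::tibble(accession = character(), protein_fc = numeric(),
                           protein_p = numeric(), protein_status = character())
  } else {
    prot <- tibble::tibble(
      accession = protein_stats$feature_id,
      protein_fc = protein_stats$fold_change,
      protein_p = protein_stats$p_value,
      protein_status = protein_stats$protein_status
    )
  }
  out <- dplyr::left_join(gp_stats, prot, by = "accession")
  out$protein_status[is.na(out$protein_status)] <- "not_quantified"

  g_fc <- out$fold_change
  g_p  <- out$p_value
  p_fc <- out$protein_fc
  st   <- out$protein_status
  up_gate <- g_fc > fc_up & g_p < alpha
  dn_gate <- g_fc < fc_dn & g_p < alpha
  no_prot_change <- st %in% c("not_sig", "not_quantified")

  quantified <- !is.na(p_fc)
  if (occupancy_requires_protein_sig) {
    branch_A <- up_gate & (no_prot_change | (quantified & g_fc > p_fc))
    branch_D <- up_gate & !branch_A & st == "sig_up" & quantified & p_fc > g_fc
    branch_C <- dn_gate & (no_prot_change | (quantified & g_fc < p_fc))
    branch_B <- dn_gate & !branch_C & st == "sig_down" & quantified & p_fc < g_fc
  } else {
    # occupancy comparison outranks the "protein not significant" clause:
    # any quantified protein with the more extreme fold change wins
    branch_A <- up_gate & (st == "not_quantified" | (quantified & g_fc > p_fc))
    branch_D <- up_gate & quantified & p_fc > g_fc
    branch_C <- dn_gate & (st == "not_quantified" | (quantified & g_fc < p_fc))
    branch_B <- dn_gate & quantified & p_fc < g_fc
  }

  out$branch <- dplyr::case_when(
    branch_A ~ "A_direct_up",
    branch_D ~ "D_occupancy_down",
    branch_C ~ "C_direct_down",
    branch_B ~ "B_occupancy_up",
    TRUE ~ "none"
  )
  out$label <- dplyr::case_when(
    out$branch %in% c("A_direct_up", "B_occupancy_up") ~ "up",
    out$branch %in% c("C_direct_down", "D_occupancy_down") ~ "down",
    TRUE ~ "unchanged"
  )
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("glyco_differential", class(tibble::tibble()))
  out
}

#' Attach glycopeptide metadata to a stats table
#'
#' Joins accession/site/peptide/composition metadata (e.g. from
#' [read_quant_table()]) onto a per-feature stats or call table by
#' `feature_id`.
#'
#' @param stats Tibble with a `feature_id` column.
#' @param meta Tibble with `feature_id` plus metadata columns.
#' @return The joined tibble (stats columns first).
#' @export
attach_feature_meta <- function(stats, meta) {
  keep <- intersect(c("feature_id", "accession", "site", "peptide", "glycan",
                      "glycan_composition", "site_in_peptide"), names(meta))
  dplyr::left_join(stats, dplyr::distinct(meta[keep]), by = "feature_id")
}

#' Differential calls broken down by glycan type
#'
#' Counts up- and downregulated glycopeptides per glycan type (the Fig-3F
#' style breakdown). Every called feature must map to a composition.
#'
#' @param calls A `glyco_differential` tibble with a `glycan` column (join
#'   one in via [attach_feature_meta()] if needed).
#' @param mannose_min_hex Passed to [classify_glycan()].
#' @return Tibble: `glycan_type`, `n_up`, `n_down`.
#' @export
de_by_glycan_type <- function(calls, mannose_min_hex = 5) {
  if (!"glycan" %in% names(calls)) {
    stop("`calls` needs a 'glycan' column; attach metadata first.",
         call. = FALSE)
  }
  unmapped <- calls$feature_id[is.na(calls$glycan) & calls$label != "unchanged"]
  if (length(unmapped) > 0) {
    stop("Called feature(s) without a glycan composition: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  called <- calls[calls$label %in% c("up", "down") & !is.na(calls$glycan), ]
  type <- classify_glycan(called$glycan, mannose_min_hex = mannose_min_hex)
  tab <- table(factor(type, levels = glycan_type_levels),
               factor(called$label, levels = c("up", "down")))
  tibble::tibble(
    glycan_type = rownames(tab),
    n_up = as.integer(tab[, "up"]),
    n_down = as.integer(tab[, "down"])
  )
}

#' Assemble the differential output table
#'
#' @param calls A `glyco_differential` tibble (metadata attached).
#' @return Tibble with the stable column order used by TSV export.
#' @export
differential_table <- function(calls) {
  cols <- c("feature_id", "accession", "site", "peptide", "glycan",
            "glycan_type", "log2_fc", "fold_change", "p_value", "bh_fdr",
            "label", "branch", "protein_status", "protein_fc", "protein_p")
  if (!"glycan_type" %in% names(calls) && "glycan" %in% names(calls)) {
    calls$glycan_type <- classify_glycan(calls$glycan)
  }
  tibble::as_tibble(calls)[intersect(cols, names(calls))]
}

#' @export
print.glyco_differential <- function(x, ...) {
  n <- table(factor(x$label, levels = c("up", "down", "unchanged")))
  cat("Protein-corrected glycopeptide classification: ", nrow(x),
      " features\n", sep = "")
  cat(sprintf("  up %d (direct %d, occupancy %d); down %d (direct %d, occupancy %d); unchanged %d\n",
              n[["up"]], sum(x$branch == "A_direct_up"),
              sum(x$branch == "B_occupancy_up"),
              n[["down"]], sum(x$branch == "C_direct_down"),
              sum(x$branch == "D_occupancy_down"), n[["unchanged"]]))
  NextMethod()
}
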