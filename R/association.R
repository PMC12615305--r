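#' Association screen thresholds
#'
#' @param rho_min Minimum Spearman correlation (default 0.6).
#' @param alpha P-value cutoff (default 0.05).
#' @param immune_fold_min Minimum fold difference for immune/stromal
#'   enrichment calls (default 1.25).
#' @return List of class `assoc_thresholds`.
#' @export
assoc_thresholds <- function(rho_min = 0.6, alpha = 0.05,
                             immune_fold_min = 1.25) {
  stopifnot(rho_min > 0, rho_min < 1, alpha > 0, alpha < 1,
            immune_fold_min >= 1)
  structure(list(rho_min = rho_min, alpha = alpha,
                 immune_fold_min = immune_fold_min),
            class = "assoc_thresholds")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   genes, tab-separated).
#' @return Named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(s) unique(s[nzchar(s)]))
  if (any(lengths(sets) == 0)) {
    stop("Empty gene set(s) in ", basename(path), ".", call. = FALSE)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Single-sample gene set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by decreasing expression (missing
#' values dropped per sample, never imputed) and each signature's score is
#' the sum over the ranked list of the difference between the weighted
#' in-set empirical CDF and the unweighted out-of-set CDF, with weights
#' `|expression|^alpha_weight`. Scores are normalized by the amplitude
#' (max minus min) of the running sum. With `alpha_weight = 0` the score
#' depends on ranks only, making it invariant to any strictly monotone
#' transform of a sample's values.
#'
#' @param expr Expression tibble: `feature_id` (gene ids) plus one numeric
#'   column per sample (typically the protein log2 ratio matrix).
#' @param sets Named list of gene-id vectors (see [read_gene_sets()]). Sets
#'   with no member among the expression rows are dropped with a warning.
#' @param design Optional design tibble restricting the sample columns.
#' @param alpha_weight Rank weighting exponent (default 0.25).
#' @param normalize Divide each score by the running-sum amplitude
#'   (default `TRUE`).
#' @return A score tibble: `signature` column plus one column per sample.
#' @export
ssgsea_scores <- function(expr, sets, design = NULL, alpha_weight = 0.25,
                          normalize = TRUE) {
  cols <- .sample_cols(expr, design, include_reference = FALSE)
  genes <- expr$feature_id
  keep <- vapply(sets, function(s) any(s %in% genes), logical(1))
  if (!any(keep)) {
    stop("No gene set overlaps the expression rows.", call. = FALSE)
  }
  if (any(!keep)) {
    warning("Dropping ", sum(!keep), " gene set(s) with no overlap: ",
            paste(names(sets)[!keep], collapse = ", "), call. = FALSE)
  }
  sets <- sets[keep]
  scores <- matrix(NA_real_, nrow = length(sets), ncol = length(cols),
                   dimnames = list(names(sets), cols))
  for (s in cols) {
    v <- expr[[s]]
    ok <- !is.na(v)
    if (!any(ok)) next
    g <- genes[ok]
    x <- v[ok]
    ord <- order(x, decreasing = TRUE)
    g <- g[ord]
    x <- x[ord]
    w <- abs(x)^alpha_weight
    for (k in seq_along(sets)) {
      inset <- g %in% sets[[k]]
      n_out <- sum(!inset)
      if (!any(inset) || n_out == 0) next
      w_in <- w * inset
      p_in <- cumsum(w_in) / sum(w_in)
      p_out <- cumsum(!inset) / n_out
      running <- p_in - p_out
      es <- sum(running)
      if (normalize) {
        amp <- max(running) - min(running)
        if (amp > 0) es <- es / amp
      }
      scores[k, s] <- es
    }
  }
  tibble::add_column(tibble::as_tibble(scores), signature = names(sets),
                     .before = 1)
}

#' Composite stroma and microenvironment scores
#'
#' Appends a `StromaScore` row (mean of the designated stromal signatures,
#' by default fibroblasts and endothelial cells) and a
#' `MicroenvironmentScore` row (mean of all immune and stromal signatures)
#' to a score matrix.
#'
#' @param scores Score tibble from [ssgsea_scores()].
#' @param stromal_signatures Character vector of stromal signature names.
#' @param all_signatures Signatures feeding the microenvironment composite
#'   (default: every non-composite row).
#' @return The score tibble with the two composite rows appended.
#' @export
composite_scores <- function(scores,
                             stromal_signatures = c("Fibroblasts",
                                                    "Endothelial_cells"),
                             all_signatures = NULL) {
  base <- scores[!scores$signature %in%
                   c("StromaScore", "MicroenvironmentScore"), ]
  if (is.null(all_signatures)) all_signatures <- base$signature
  cols <- setdiff(names(base), "signature")
  row_mean <- function(sig_names, label) {
    sub <- base[base$signature %in% sig_names, cols, drop = FALSE]
    if (nrow(sub) == 0) {
      stop("No signature rows match for ", label, ".", call. = FALSE)
    }
    out <- as.list(colMeans(as.matrix(sub), na.rm = TRUE))
    tibble::as_tibble(c(list(signature = label), out))
  }
  dplyr::bind_rows(
    base,
    row_mean(stromal_signatures, "StromaScore"),
    row_mean(all_signatures, "MicroenvironmentScore")
  )
}

#' Differential immune/stromal enrichment
#'
#' Compares per-signature enrichment scores between two conditions with
#' Student's t-tests and a fold gate. Because enrichment scores can be
#' negative, each signature's scores are shifted (minimum moved to 1, an
#' offset-invariant transform) before folds are computed, so the call is
#' unchanged by adding a constant to a signature's scores.
#'
#' @param scores Score tibble (`signature` + sample columns).
#' @param design Design tibble.
#' @param group_a,group_b Condition labels (fold and direction are a vs b).
#' @param thresholds [assoc_thresholds()].
#' @return Tibble per signature: `mean_a`, `mean_b`, `fold` (shifted-scale),
#'   `p_value`, `call` in `enriched_in_a` / `enriched_in_b` / `ns`.
#' @export
immune_differential <- function(scores, design, group_a = "Tumor",
                                group_b = "NAT",
                                thresholds = assoc_thresholds()) {
  df <- dplyr::rename(scores, feature_id = "signature")
  st <- feature_stats(df, design, group_a, group_b)
  cols_a <- intersect(design_samples(design, group_a), names(scores))
  cols_b <- intersect(design_samples(design, group_b), names(scores))
  m <- as.matrix(scores[c(cols_a, cols_b)])
  shifted <- m - apply(m, 1, min, na.rm = TRUE) + 1
  ma <- rowMeans(shifted[, cols_a, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(shifted[, cols_b, drop = FALSE], na.rm = TRUE)
  fold <- ma / mb
  out <- tibble::tibble(
    signature = scores$signature,
    mean_a = rowMeans(m[, cols_a, drop = FALSE], na.rm = TRUE),
    mean_b = rowMeans(m[, cols_b, drop = FALSE], na.rm = TRUE),
    fold = fold
  )
  out <- dplyr::left_join(
    out, tibble::tibble(signature = st$feature_id, p_value = st$p_value),
    by = "signature")
  fm <- thresholds$immune_fold_min
  out$call <- dplyr::case_when(
    is.na(out$p_value) ~ "ns",
    out$p_value < thresholds$alpha & out$fold >= fm ~ "enriched_in_a",
    out$p_value < thresholds$alpha & out$fold <= 1 / fm ~ "enriched_in_b",
    TRUE ~ "ns"
  )
  out
}

#' Identify quantified glycosyltransferases and their regulation
#'
#' Intersects a quantified proteome with a curated glycosyltransferase gene
#' list and attaches protein differential calls.
#'
#' @param protein_stats Protein tibble from [call_protein_de()] (or
#'   [feature_stats()]; calls are added if absent).
#' @param gt_list Character vector of glycosyltransferase identifiers.
#' @param thresholds [glyco_thresholds()] used if calls must be added.
#' @return The subset of `protein_stats` matching the list, with
#'   `protein_status`.
#' @export
select_glycosyltransferases <- function(protein_stats, gt_list,
                                        thresholds = glyco_thresholds()) {
  if (!"protein_status" %in% names(protein_stats)) {
    protein_stats <- call_protein_de(protein_stats, thresholds)
  }
  protein_stats[protein_stats$feature_id %in% gt_list, , drop = FALSE]
}

#' Spearman correlation screen between two feature matrices
#'
#' Computes Spearman rank correlations (mid-ranks for ties, ranks formed on
#' pairwise-complete observations) between every row of `x` and every row of
#' `y` over shared samples, with p-values from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`. Pairs are retained when `rho >
#' rho_min` (or `|rho| > rho_min` with `use_abs = TRUE`, for screens where
#' negative associations matter) and `p < alpha`.
#'
#' @param x,y Tibbles with an id column (`feature_id` or `signature`) plus
#'   shared sample columns.
#' @param thresholds [assoc_thresholds()].
#' @param min_n Minimum pairwise-complete sample count (default 5).
#' @param use_abs Screen on `|rho|` instead of positive rho.
#' @param keep_all Return all pairs with a `retained` flag instead of only
#'   the retained ones.
#' @return Tibble: `x_id`, `y_id`, `rho`, `p_value`, `n` (and `retained`
#'   when `keep_all = TRUE`).
#' @export
spearman_screen <- function(x, y, thresholds = assoc_thresholds(),
                            min_n = 5, use_abs = FALSE, keep_all = FALSE) {
  id_col <- function(df) intersect(c("feature_id", "signature"), names(df))[1]
  xid <- id_col(x); yid <- id_col(y)
  if (is.na(xid) || is.na(yid)) {
    stop("Both inputs need a 'feature_id' or 'signature' id column.",
         call. = FALSE)
  }
  common <- intersect(.sample_cols(x), .sample_cols(y))
  if (length(common) < min_n) {
    stop("Fewer than ", min_n, " shared sample columns.", call. = FALSE)
  }
  mx <- t(as.matrix(x[common]))   # samples x features
  my <- t(as.matrix(y[common]))
  rho <- suppressWarnings(
    stats::cor(mx, my, method = "spearman", use = "pairwise.complete.obs"))
  n <- crossprod((!is.na(mx)) * 1, (!is.na(my)) * 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- tibble::tibble(
    x_id = rep(x[[xid]], times = ncol(rho)),
    y_id = rep(y[[yid]], each = nrow(rho)),
    rho = as.vector(rho),
    p_value = as.vector(p),
    n = as.vector(n)
  )
  out <- out[out$n >= min_n & !is.na(out$rho), , drop = FALSE]
  eff <- if (use_abs) abs(out$rho) else out$rho
  out$retained <- eff > thresholds$rho_min & out$p_value < thresholds$alpha
  if (keep_all) return(out)
  out <- out[out$retained, , drop = FALSE]
  out$retained <- NULL
  out
}

#' Intersect correlated features with differential calls
#'
#' Joins a correlation screen's retained features against an up- (or down-)
#' regulated feature set, carrying rho/p and fold-change/branch provenance
#' for every feature in the intersection.
#'
#' @param correlated Tibble from [spearman_screen()] (retained pairs).
#' @param calls A `glyco_differential` tibble.
#' @param labels Which call labels count (default `"up"`).
#' @return Tibble: one row per (correlated pair, call) in the intersection,
#'   with `rho`, `p_value`, `fold_change`, `label`, `branch`.
#' @export
intersect_with_de <- function(correlated, calls, labels = "up") {
  de <- calls[calls$label %in% labels,
              intersect(c("feature_id", "fold_change", "p_value", "label",
                          "branch"), names(calls))]
  names(de) <- c("y_id", "de_fold_change", "de_p_value", "label", "branch")
  dplyr::inner_join(tibble::as_tibble(correlated), de, by = "y_id")
}

#' Over-representation enrichment (hypergeometric)
#'
#' Generic over-representation analysis of a query gene set against a
#' user-supplied annotation collection: for each term, the upper-tail
#' hypergeometric probability of observing at least the query/term overlap
#' within the universe, with Benjamini-Hochberg correction across terms.
#'
#' @param query Character vector of gene ids (e.g. differentially
#'   glycosylated proteins).
#' @param annotation Named list of term gene sets.
#' @param universe Character vector: the background (e.g. all quantified
#'   proteins). Query and term members outside the universe are ignored.
#' @return Tibble per term: `term`, `n_term`, `n_query`, `overlap`,
#'   `p_value`, `bh_fdr`, sorted by p.
#' @export
ora_enrichment <- function(query, annotation, universe) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  res <- purrr::map_dfr(names(annotation), function(term) {
    set <- intersect(annotation[[term]], universe)
    k <- length(intersect(query, set))
    tibble::tibble(
      term = term,
      n_term = length(set),
      n_query = length(query),
      overlap = k,
      p_value = stats::phyper(k - 1, length(set),
                              length(universe) - length(set),
                              length(query), lower.tail = FALSE)
    )
  })
  res$bh_fdr <- stats::p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value, .data$term)
}
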