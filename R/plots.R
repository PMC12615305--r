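#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA plot of samples
#'
#' @param object A `glyco_pca` from [pca_summary()].
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2 sample scores, colored by condition when
#'   available, with variance-explained axis labels.
#' @export
autoplot.glyco_pca <- function(object, ...) {
  ve <- object$variance$variance_explained
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("condition" %in% names(object$scores)) {
    p <- p + ggplot2::aes(colour = .data$condition)
  }
  p +
    ggplot2::geom_point(size = 2.5, alpha = 0.85) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Glycopeptide-versus-protein fold-change plot
#'
#' Scatter of glycopeptide log2 fold changes against their proteins',
#' colored by decision-tree branch; the diagonal marks equal change (pure
#' protein-abundance-driven behavior) and the dashed lines the fold-change
#' gates. Glycopeptides without a quantified protein are drawn at protein
#' log2 fold change 0 with open symbols.
#'
#' @param object A `glyco_differential` from [classify_glycopeptides()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glyco_differential <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$protein_log2_fc <- ifelse(is.na(d$protein_fc), 0, log2(d$protein_fc))
  d$protein_quantified <- !is.na(d$protein_fc)
  th <- log2(c(1.5, 0.67))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$protein_log2_fc,
                                  y = .data$log2_fc,
                                  colour = .data$branch,
                                  shape = .data$protein_quantified)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = th, linetype = "dashed",
                        colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "protein log2 fold change",
                  y = "glycopeptide log2 fold change",
                  colour = "branch", shape = "protein quantified") +
    ggplot2::theme_minimal()
}

#' Glycan-type proportion bar plot
#'
#' @param proportions Tibble from [type_proportions()] (optionally
#'   row-bound across cohorts with a `cohort` column).
#' @return A ggplot bar chart of the five-class mixture.
#' @export
plot_type_proportions <- function(proportions) {
  p <- ggplot2::ggplot(proportions,
                       ggplot2::aes(x = .data$glycan_type,
                                    y = .data$proportion,
                                    fill = .data$glycan_type))
  if ("cohort" %in% names(proportions)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$cohort))
  }
  p +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "proportion of glycans") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Differential counts by glycan type
#'
#' @param breakdown Tibble from [de_by_glycan_type()].
#' @return A ggplot with up counts above and down counts below zero.
#' @export
plot_de_by_glycan_type <- function(breakdown) {
  long <- tidyr::pivot_longer(breakdown, c("n_up", "n_down"),
                              names_to = "direction", values_to = "n")
  long$n <- ifelse(long$direction == "n_down", -long$n, long$n)
  long$direction <- ifelse(long$direction == "n_up", "up", "down")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$glycan_type, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "differential glycopeptides",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Glycan-type co-occurrence plot
#'
#' Bar chart of type subsets observed at the same glycosite (an UpSet-style
#' summary in long form).
#'
#' @param cooccurrence Tibble from [type_cooccurrence_at_sites()].
#' @param n_top Subsets to show.
#' @return A ggplot.
#' @export
plot_type_cooccurrence <- function(cooccurrence, n_top = 15) {
  d <- utils::head(cooccurrence, n_top)
  d$type_set <- factor(d$type_set, levels = rev(d$type_set))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_sites, y = .data$type_set)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "glycosites", y = NULL) +
    ggplot2::theme_minimal()
}
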