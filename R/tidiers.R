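#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a glycopeptide classification result
#'
#' @param x A `glyco_differential` object.
#' @param ... Unused.
#' @return A plain tibble, one row per glycopeptide, with the stable
#'   differential-table column order.
#' @export
tidy.glyco_differential <- function(x, ...) {
  differential_table(x)
}

#' One-row summary of a classification result
#'
#' @param x A `glyco_differential` object.
#' @param ... Unused.
#' @return Tibble: feature and call counts per branch.
#' @export
glance.glyco_differential <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_up = sum(x$label == "up"),
    n_down = sum(x$label == "down"),
    n_direct_up = sum(x$branch == "A_direct_up"),
    n_occupancy_up = sum(x$branch == "B_occupancy_up"),
    n_direct_down = sum(x$branch == "C_direct_down"),
    n_occupancy_down = sum(x$branch == "D_occupancy_down"),
    n_protein_not_quantified = sum(x$protein_status == "not_quantified")
  )
}

#' Tidy PCA sample scores
#'
#' @param x A `glyco_pca` object.
#' @param ... Unused.
#' @return The sample score tibble.
#' @export
tidy.glyco_pca <- function(x, ...) x$scores

#' One-row PCA summary
#'
#' @param x A `glyco_pca` object.
#' @param ... Unused.
#' @return Tibble: features used, samples, and leading variance fractions.
#' @export
glance.glyco_pca <- function(x, ...) {
  ve <- x$variance$variance_explained
  tibble::tibble(
    n_features = x$n_features,
    n_samples = nrow(x$scores),
    pc1_variance = ve[1],
    pc2_variance = ve[2],
    pc1_pc2_variance = sum(ve[1:2])
  )
}
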