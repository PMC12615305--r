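#' Read a glycopeptide or protein quantification table
#'
#' Reads a delimited (TSV/CSV) quantification table and validates its schema.
#' Glycopeptide tables need `accession`, `site`, `peptide` and
#' `glycan_composition` columns; protein tables need `accession` and
#' `unique_peptides`. Every other numeric column is treated as a per-channel
#' intensity. Glycan compositions are canonicalized on read and a
#' `feature_id` key is built (`accession|site|peptide|glycan` for
#' glycopeptides, `accession` for proteins). Duplicate feature rows are
#' summed channel-wise with a warning, matching the convention that repeated
#' spectral features of the same glycopeptide contribute jointly.
#'
#' @param path Path to a TSV or CSV file.
#' @param kind `"glycopeptide"` or `"protein"`.
#' @return A tibble with metadata columns, `feature_id`, and intensity
#'   columns. Intensities must be non-negative or missing; zeros are kept
#'   as-is here (they become missing at the log step).
#' @export
read_quant_table <- function(path, kind = c("glycopeptide", "protein")) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  required <- switch(kind,
    glycopeptide = c("accession", "site", "peptide", "glycan_composition"),
    protein      = c("accession", "unique_peptides")
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("Quantification table ", basename(path), " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta_cols <- intersect(c(required, "site_in_peptide"), names(df))
  value_cols <- setdiff(names(df), meta_cols)
  # channels with no quantified value at all parse as logical NA; keep them
  # numeric-missing
  for (v in value_cols) {
    if (is.logical(df[[v]]) && all(is.na(df[[v]]))) {
      df[[v]] <- as.numeric(df[[v]])
    }
  }
  numeric_ok <- vapply(df[value_cols], is.numeric, logical(1))
  if (any(!numeric_ok)) {
    offender <- value_cols[!numeric_ok][1]
    bad_rows <- which(!is.na(df[[offender]]) &
                        is.na(suppressWarnings(as.numeric(df[[offender]]))))
    stop("Non-numeric intensity value(s) in column '", offender, "'",
         if (length(bad_rows) > 0)
           paste0(" (e.g. data row ", bad_rows[1], ")"),
         " of ", basename(path), ".", call. = FALSE)
  }
  neg <- vapply(df[value_cols], function(v) any(v < 0, na.rm = TRUE), logical(1))
  if (any(neg)) {
    stop("Negative intensities in column(s): ",
         paste(value_cols[neg], collapse = ", "), call. = FALSE)
  }
  df <- build_feature_ids(df, kind)
  collapse_duplicate_features(df, value_cols)
}

#' Build canonical feature identifiers
#'
#' @param df Quantification tibble (see [read_quant_table()] schema).
#' @param kind `"glycopeptide"` or `"protein"`.
#' @return The tibble with a `feature_id` column first (glycopeptides also
#'   gain a canonical `glycan` column).
#' @export
build_feature_ids <- function(df, kind = c("glycopeptide", "protein")) {
  kind <- match.arg(kind)
  df <- tibble::as_tibble(df)
  if (kind == "glycopeptide") {
    df$glycan <- canonical_glycan(df$glycan_composition)
    df$feature_id <- paste(df$accession, df$site, df$peptide, df$glycan,
                           sep = "|")
  } else {
    df$feature_id <- as.character(df$accession)
  }
  dplyr::relocate(df, "feature_id")
}

# internal: sum channel intensities of rows sharing a feature_id
collapse_duplicate_features <- function(df, value_cols) {
  if (anyDuplicated(df$feature_id) == 0) return(df)
  n_dup <- sum(duplicated(df$feature_id))
  warning(n_dup, " duplicate feature row(s) collapsed by summing channel ",
          "intensities.", call. = FALSE)
  meta_cols <- setdiff(names(df), value_cols)
  meta <- dplyr::distinct(df[meta_cols], .data$feature_id, .keep_all = TRUE)
  sum_keep_na <- function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  sums <- df |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), sum_keep_na),
                     .groups = "drop")
  dplyr::relocate(dplyr::left_join(meta, sums, by = "feature_id"), "feature_id")
}

#' Channel-total batch normalization
#'
#' Scales every intensity channel of one batch so that its total intensity
#' (sum over non-missing features) equals the median channel total of that
#' batch, leaving within-channel structure untouched. This removes loading
#' and labeling-efficiency differences between channels before reference
#' ratioing.
#'
#' @param df Quantification tibble with intensity columns.
#' @param design Optional design tibble restricting which columns are treated
#'   as channels (all of the batch's channels, including the reference, are
#'   normalized).
#' @param target `"median"` (default) or `"mean"`: the channel-total summary
#'   every channel is scaled to.
#' @return The tibble with scaled intensity columns.
#' @export
normalize_batch <- function(df, design = NULL, target = c("median", "mean")) {
  target <- match.arg(target)
  cols <- .sample_cols(df, design)
  totals <- unname(vapply(df[cols], function(v) sum(v, na.rm = TRUE),
                          numeric(1)))
  empty <- totals == 0 | vapply(df[cols], function(v) all(is.na(v)), logical(1))
  if (any(empty)) {
    stop("Channel(s) with no quantified values: ",
         paste(cols[empty], collapse = ", "), call. = FALSE)
  }
  tgt <- if (target == "median") stats::median(totals) else mean(totals)
  for (j in seq_along(cols)) {
    df[[cols[j]]] <- df[[cols[j]]] * (tgt / totals[j])
  }
  df
}

#' Log2 sample-to-reference ratios within a batch
#'
#' Divides every sample channel of a batch by the batch's pooled reference
#' channel and takes log2. Features whose reference intensity is missing or
#' zero get missing ratios for the whole batch (no pseudo-reference is
#' substituted; the pipeline never imputes). The reference column itself,
#' identically zero after ratioing, is dropped.
#'
#' @param df Normalized intensity tibble for one batch.
#' @param design Design tibble; the rows matching this table's columns must
#'   contain exactly one reference channel.
#' @return Tibble of log2 ratios with the reference column removed. The
#'   number of features invalidated by a missing reference is recorded in
#'   attribute `n_reference_missing`.
#' @export
ratio_to_reference <- function(df, design) {
  cols <- .sample_cols(df, design)
  sub <- design[design$sample_id %in% cols, ]
  ref <- sub$sample_id[sub$is_reference]
  if (length(ref) != 1) {
    stop("Expected exactly one reference channel among columns, found ",
         length(ref), ".", call. = FALSE)
  }
  samples <- setdiff(cols, ref)
  refv <- df[[ref]]
  refv[!is.na(refv) & refv == 0] <- NA_real_
  n_missing_ref <- sum(is.na(refv))
  if (n_missing_ref > 0) {
    warning(n_missing_ref, " feature(s) have a missing/zero reference ",
            "intensity; their ratios are missing for this batch.",
            call. = FALSE)
  }
  for (s in samples) {
    v <- df[[s]]
    v[!is.na(v) & v == 0] <- NA_real_
    df[[s]] <- log2(v / refv)
  }
  df[[ref]] <- NULL
  attr(df, "n_reference_missing") <- n_missing_ref
  df
}

#' Integrate per-batch ratio tables
#'
#' Joins per-batch log2-ratio tables into one matrix over the union of
#' features; a feature absent from a batch is missing for that batch's
#' samples. Sample ids must not repeat across batches.
#'
#' @param batches List of tibbles as returned by [ratio_to_reference()].
#' @param design Optional design tibble used to identify sample columns.
#' @return A single tibble with all metadata and sample columns.
#' @export
integrate_batches <- function(batches, design = NULL) {
  if (!is.list(batches) || length(batches) == 0) {
    stop("`batches` must be a non-empty list of tables.", call. = FALSE)
  }
  if (length(batches) == 1) return(tibble::as_tibble(batches[[1]]))
  sample_sets <- lapply(batches, .sample_cols, design = design)
  all_samples <- unlist(sample_sets)
  if (anyDuplicated(all_samples) > 0) {
    stop("Sample id(s) appear in more than one batch: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  }
  meta_cols <- Reduce(intersect, lapply(seq_along(batches), function(i) {
    setdiff(names(batches[[i]]), sample_sets[[i]])
  }))
  out <- purrr::reduce(batches, dplyr::full_join, by = meta_cols)
  dplyr::relocate(out, dplyr::all_of(meta_cols))
}

#' Normalize a single-batch experiment
#'
#' For designs without a pooled reference (one TMT plex), channel totals are
#' equalized as in [normalize_batch()] and intensities are log2-transformed.
#' Zero intensities become missing (log of zero is undefined and zeros in
#' isobaric data denote non-detection).
#'
#' @inheritParams normalize_batch
#' @return Tibble of log2 normalized intensities.
#' @export
normalize_single_batch <- function(df, design = NULL,
                                   target = c("median", "mean")) {
  df <- normalize_batch(df, design, target = target)
  cols <- .sample_cols(df, design)
  for (s in cols) {
    v <- df[[s]]
    v[!is.na(v) & v == 0] <- NA_real_
    df[[s]] <- log2(v)
  }
  df
}

#' Missingness and unique-peptide filtering
#'
#' Retains features quantified in at least `min_fraction` of the samples
#' (inclusive threshold; reference channels never count toward the
#' denominator) and, when a `unique_peptides` column is present and
#' `min_unique_peptides` is not `NULL`, proteins identified by at least that
#' many unique peptides. No values are altered — features are only kept or
#' dropped.
#'
#' @param df Quant tibble (log2 ratios or intensities).
#' @param design Optional design tibble identifying sample columns.
#' @param min_fraction Minimum fraction of samples with a non-missing value
#'   (default 0.5).
#' @param min_unique_peptides Minimum unique peptide count for protein tables
#'   (default 2 when the column exists; set `NULL` to skip).
#' @return The filtered tibble, with a `filter_report` attribute
#'   (list: `n_input`, `n_retained`, `n_dropped_missingness`,
#'   `n_dropped_peptides`, `min_fraction`, `n_samples`).
#' @export
apply_quant_filter <- function(df, design = NULL, min_fraction = 0.5,
                               min_unique_peptides = if ("unique_peptides" %in% names(df)) 2 else NULL) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  cols <- .sample_cols(df, design, include_reference = FALSE)
  n_obs <- rowSums(!is.na(as.matrix(df[cols])))
  keep_missing <- n_obs / length(cols) >= min_fraction
  keep_pep <- rep(TRUE, nrow(df))
  if (!is.null(min_unique_peptides) && "unique_peptides" %in% names(df)) {
    keep_pep <- !is.na(df$unique_peptides) &
      df$unique_peptides >= min_unique_peptides
  }
  out <- df[keep_missing & keep_pep, , drop = FALSE]
  attr(out, "filter_report") <- list(
    n_input = nrow(df),
    n_retained = nrow(out),
    n_dropped_missingness = sum(!keep_missing),
    n_dropped_peptides = sum(keep_missing & !keep_pep),
    min_fraction = min_fraction,
    n_samples = length(cols)
  )
  out
}

#' Filter report of a filtered table
#'
#' @param df A tibble returned by [apply_quant_filter()].
#' @return The report list, or `NULL` if absent.
#' @export
filter_report <- function(df) attr(df, "filter_report")

#' Principal component summary of a quant matrix
#'
#' Runs PCA on samples using complete-case features only (features with any
#' missing value are excluded — no imputation), column-centered per
#' component, unscaled: log2 ratios already share a scale. Returns sample
#' scores and the per-component variance-explained fractions.
#'
#' @param df Quant tibble of log2 values.
#' @param design Optional design tibble; condition labels are attached to the
#'   scores when provided.
#' @return An object of class `glyco_pca`: list with `scores` (tibble:
#'   `sample_id`, `condition`, `PC1`, `PC2`, ...), `variance` (tibble:
#'   `component`, `variance_explained`), `n_features` (complete features
#'   used).
#' @export
pca_summary <- function(df, design = NULL) {
  cols <- .sample_cols(df, design, include_reference = FALSE)
  if (length(cols) < 3) stop("PCA needs at least 3 samples.", call. = FALSE)
  x <- as.matrix(df[cols])
  complete <- stats::complete.cases(x)
  if (sum(complete) < 2) {
    stop("Fewer than 2 features are quantified in every sample; ",
         "apply a stricter missingness filter first.", call. = FALSE)
  }
  x <- x[complete, , drop = FALSE]
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x, .name_repair = "minimal")
  scores <- tibble::add_column(scores, sample_id = cols, .before = 1)
  if (!is.null(design)) {
    scores <- dplyr::left_join(
      scores, design[c("sample_id", "condition")], by = "sample_id")
    scores <- dplyr::relocate(scores, "sample_id", "condition")
  }
  structure(
    list(
      scores = scores,
      variance = tibble::tibble(
        component = paste0("PC", seq_along(ve)),
        variance_explained = ve
      ),
      n_features = sum(complete)
    ),
    class = "glyco_pca"
  )
}

#' @export
print.glyco_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "samples over", x$n_features,
      "complete-case features\n")
  v <- x$variance$variance_explained
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance (PC1+PC2 = %.1f%%)\n",
              100 * v[1], 100 * v[2], 100 * (v[1] + v[2])))
  invisible(x)
}
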