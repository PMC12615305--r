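#' Read a study design file
#'
#' The design maps each quantification channel to a sample. Accepted formats
#' are delimited text (TSV/CSV) or YAML with a top-level `samples` list; both
#' must provide `sample_id`, `batch`, `channel`, `condition` and optionally
#' `pair_id` and `is_reference`. Reference channels (the pooled internal
#' standard shared across batches) are flagged with `is_reference = TRUE` or
#' `condition == "Reference"`.
#'
#' @param path Path to a `.tsv`/`.csv`/`.txt` or `.yaml`/`.yml` design file.
#' @return A validated design tibble (see [validate_study_design()]).
#' @export
read_study_design <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$samples)) raw <- raw$samples
    design <- purrr::map_dfr(raw, tibble::as_tibble)
  } else if (ext == "csv") {
    design <- readr::read_csv(path, show_col_types = FALSE)
  } else {
    design <- readr::read_tsv(path, show_col_types = FALSE)
  }
  validate_study_design(design)
}

#' Validate a study design
#'
#' Checks the structural invariants of a multiplexed design: required columns,
#' unique `sample_id` and `(batch, channel)` pairs, at most one reference
#' channel per batch (exactly one per batch in multi-batch designs), and
#' paired designs mapping each `pair_id` to exactly one Tumor and one NAT
#' sample.
#'
#' @param design A data frame with columns `sample_id`, `batch`, `channel`,
#'   `condition`, and optionally `pair_id`, `is_reference`.
#' @return The design as a tibble with normalized column types;
#'   `is_reference` is filled in from `condition == "Reference"` when absent.
#' @export
validate_study_design <- function(design) {
  design <- tibble::as_tibble(design)
  required <- c("sample_id", "batch", "channel", "condition")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    stop("Design is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"is_reference" %in% names(design)) {
    design$is_reference <- design$condition == "Reference"
  }
  design$is_reference <- as.logical(design$is_reference)
  design$is_reference[is.na(design$is_reference)] <- FALSE
  if (!"pair_id" %in% names(design)) design$pair_id <- NA_character_
  design$sample_id <- as.character(design$sample_id)
  design$batch <- as.character(design$batch)

  if (anyDuplicated(design$sample_id) > 0) {
    stop("Duplicated sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  key <- paste(design$batch, design$channel, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop("Duplicated (batch, channel) assignment in design.", call. = FALSE)
  }
  refs_per_batch <- tapply(design$is_reference, design$batch, sum)
  n_batches <- length(unique(design$batch))
  if (any(refs_per_batch > 1)) {
    stop("More than one reference channel in batch(es): ",
         paste(names(refs_per_batch)[refs_per_batch > 1], collapse = ", "),
         call. = FALSE)
  }
  if (n_batches > 1 && any(refs_per_batch != 1)) {
    stop("Multi-batch designs need exactly one reference channel per batch; ",
         "batch(es) without one: ",
         paste(names(refs_per_batch)[refs_per_batch == 0], collapse = ", "),
         call. = FALSE)
  }
  paired <- design[!is.na(design$pair_id) & !design$is_reference, ]
  if (nrow(paired) > 0) {
    chk <- dplyr::count(paired, .data$pair_id, .data$condition)
    bad <- dplyr::filter(dplyr::count(chk, .data$pair_id), .data$n != 2)
    chk_bad <- dplyr::filter(chk, .data$n != 1)
    if (nrow(bad) > 0 || nrow(chk_bad) > 0) {
      stop("Each pair_id must map to exactly one sample per condition.",
           call. = FALSE)
    }
  }
  design
}

#' Non-reference samples of a design
#'
#' @param design A validated design tibble.
#' @param conditions Optional conditions to keep.
#' @return Character vector of sample ids.
#' @export
design_samples <- function(design, conditions = NULL) {
  keep <- !design$is_reference
  if (!is.null(conditions)) keep <- keep & design$condition %in% conditions
  design$sample_id[keep]
}

# internal: sample columns of a quant table, in design order if available
.sample_cols <- function(df, design = NULL, include_reference = TRUE) {
  if (!is.null(design)) {
    ids <- design$sample_id
    if (!include_reference) ids <- ids[!design$is_reference]
    cols <- intersect(ids, names(df))
    if (length(cols) == 0) {
      stop("None of the design's sample_id values match columns of the table.",
           call. = FALSE)
    }
    return(cols)
  }
  names(df)[vapply(df, is.numeric, logical(1)) &
              !names(df) %in% c("site", "unique_peptides", "site_in_peptide")]
}
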