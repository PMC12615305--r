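#' Deduplicate glycopeptide identification records
#'
#' @param records Tibble with `accession`, `site`, `peptide` and a glycan
#'   composition column (`glycan` or `glycan_composition`).
#' @return Tibble with a canonical `glycan` column, one row per distinct
#'   (accession, site, peptide, glycan).
#' @export
as_glyco_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("accession", "site", "peptide")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("Records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"glycan" %in% names(records)) {
    if (!"glycan_composition" %in% names(records)) {
      stop("Records need a 'glycan' or 'glycan_composition' column.",
           call. = FALSE)
    }
    records$glycan <- canonical_glycan(records$glycan_composition)
  } else {
    records$glycan <- canonical_glycan(records$glycan)
  }
  dplyr::distinct(records, .data$accession, .data$site, .data$peptide,
                  .data$glycan, .keep_all = TRUE)
}

#' Landscape identification counts
#'
#' Counts distinct glycopeptides (accession, site, peptide, composition),
#' glycosites (accession, site) and glycoproteins (accession). The three
#' counts are weakly decreasing by construction.
#'
#' @param records Identification tibble (see [as_glyco_records()]).
#' @return One-row tibble: `n_glycopeptides`, `n_glycosites`,
#'   `n_glycoproteins`.
#' @export
landscape_counts <- function(records) {
  r <- as_glyco_records(records)
  tibble::tibble(
    n_glycopeptides = nrow(r),
    n_glycosites = nrow(dplyr::distinct(r, .data$accession, .data$site)),
    n_glycoproteins = dplyr::n_distinct(r$accession)
  )
}

#' Distribution of glycosites per glycoprotein
#'
#' @param records Identification tibble.
#' @return Tibble: `n_sites`, `n_proteins`, `proportion` (sums to 1).
#' @export
sites_per_protein_distribution <- function(records) {
  r <- as_glyco_records(records)
  per <- r |>
    dplyr::distinct(.data$accession, .data$site) |>
    dplyr::count(.data$accession, name = "n_sites") |>
    dplyr::count(.data$n_sites, name = "n_proteins")
  per$proportion <- per$n_proteins / sum(per$n_proteins)
  per
}

#' Distribution of glycans per glycosite (microheterogeneity)
#'
#' Tabulates how many distinct glycan compositions decorate each site, in
#' configurable bins (default 1 / 2 / 3-5 / >5).
#'
#' @param records Identification tibble.
#' @param breaks Increasing integer upper bin edges; the final bin is
#'   open-ended. Default `c(1, 2, 5)` gives bins 1, 2, 3-5, >5.
#' @return Tibble: `bin`, `n_sites`, `proportion`.
#' @export
glycans_per_site_distribution <- function(records, breaks = c(1, 2, 5)) {
  r <- as_glyco_records(records)
  per <- r |>
    dplyr::distinct(.data$accession, .data$site, .data$glycan) |>
    dplyr::count(.data$accession, .data$site, name = "n_glycans")
  edges <- c(0, breaks, Inf)
  lab <- character(length(breaks) + 1)
  lo <- c(1, breaks + 1)
  hi <- c(breaks, Inf)
  lab <- ifelse(lo == hi, as.character(lo),
                ifelse(is.infinite(hi), paste0(">", lo - 1),
                       paste0(lo, "-", hi)))
  per$bin <- cut(per$n_glycans, breaks = edges, labels = lab)
  out <- dplyr::count(per, .data$bin, name = "n_sites", .drop = FALSE)
  out$proportion <- out$n_sites / sum(out$n_sites)
  out
}

#' Sequon motif proportions
#'
#' Classifies each distinct glycosite by its N-X-S/T/C motif and returns the
#' proportions of NXT, NXS and NXC over classifiable sites. Sites whose
#' motif cannot be resolved (sequon extends past the peptide with no
#' flanking context, or X = proline) are excluded from the denominator; the
#' number excluded is reported in attribute `n_unresolved`.
#'
#' @param records Identification tibble with a `site_in_peptide` column
#'   (1-based position of the site's asparagine within `peptide`).
#' @param protein_seqs Optional named character vector of protein sequences
#'   (names = accessions) used to resolve sequons that extend past the
#'   peptide.
#' @return Tibble: `motif`, `n_sites`, `proportion` over NXT/NXS/NXC.
#' @export
sequon_proportions <- function(records, protein_seqs = NULL) {
  r <- as_glyco_records(records)
  if (!"site_in_peptide" %in% names(r)) {
    stop("Records need a 'site_in_peptide' column for sequon analysis.",
         call. = FALSE)
  }
  sites <- dplyr::distinct(r, .data$accession, .data$site, .keep_all = TRUE)
  context <- rep("", nrow(sites))
  if (!is.null(protein_seqs)) {
    idx <- match(sites$accession, names(protein_seqs))
    has <- !is.na(idx)
    context[has] <- substr(protein_seqs[idx[has]],
                           sites$site[has] + 1L, sites$site[has] + 2L)
  }
  motif <- classify_sequon(sites$peptide, sites$site_in_peptide,
                           context = context)
  ok <- motif != "invalid"
  if (!any(ok)) stop("No classifiable sequons in records.", call. = FALSE)
  tab <- table(droplevels(motif[ok], exclude = "invalid"))
  out <- tibble::tibble(
    motif = factor(c("NXT", "NXS", "NXC"), levels = c("NXT", "NXS", "NXC")),
    n_sites = as.integer(tab[c("NXT", "NXS", "NXC")])
  )
  out$n_sites[is.na(out$n_sites)] <- 0L
  out$proportion <- out$n_sites / sum(out$n_sites)
  attr(out, "n_unresolved") <- sum(!ok)
  out
}

#' Glycan-type proportions
#'
#' Computes the five-class glycan-type mixture, either over site-specific
#' glycan compositions (each distinct site/composition pairing counts once)
#' or over unique compositions (the multiset is deduplicated to distinct
#' composition strings first).
#'
#' @param x Identification tibble, or a character vector of composition
#'   strings (a multiset).
#' @param level `"site_specific"` or `"unique_composition"`.
#' @param mannose_min_hex Passed to [classify_glycan()].
#' @return Tibble: `glycan_type`, `n`, `proportion` (sums to 1).
#' @export
type_proportions <- function(x, level = c("site_specific", "unique_composition"),
                             mannose_min_hex = 5) {
  level <- match.arg(level)
  if (is.character(x)) {
    glycans <- canonical_glycan(x)
  } else {
    r <- as_glyco_records(x)
    glycans <- dplyr::distinct(r, .data$accession, .data$site, .data$glycan)$glycan
  }
  if (level == "unique_composition") glycans <- unique(glycans)
  type <- classify_glycan(glycans, mannose_min_hex = mannose_min_hex)
  tab <- table(type)
  out <- tibble::tibble(
    glycan_type = glycan_type_levels,
    n = as.integer(tab[glycan_type_levels])
  )
  out$proportion <- out$n / sum(out$n)
  out
}

#' Compare two cohorts' glycan repertoires
#'
#' Set algebra between two identification cohorts at either the
#' site-specific level (distinct accession/site/composition triples) or the
#' unique-composition level (distinct composition strings), yielding the
#' counts exclusive to each cohort and shared by both.
#'
#' @param a,b Identification tibbles for the two cohorts.
#' @param level `"site_specific"` or `"unique_composition"`.
#' @return One-row tibble: `level`, `exclusive_a`, `exclusive_b`, `shared`.
#'   `exclusive_a + shared` equals cohort A's total, likewise for B.
#' @export
compare_cohorts <- function(a, b,
                            level = c("site_specific", "unique_composition")) {
  level <- match.arg(level)
  keyset <- function(x) {
    r <- as_glyco_records(x)
    if (level == "site_specific") {
      unique(paste(r$accession, r$site, r$glycan, sep = "|"))
    } else {
      unique(r$glycan)
    }
  }
  ka <- keyset(a)
  kb <- keyset(b)
  tibble::tibble(
    level = level,
    exclusive_a = length(setdiff(ka, kb)),
    exclusive_b = length(setdiff(kb, ka)),
    shared = length(intersect(ka, kb))
  )
}

#' Top glycans by number of sites
#'
#' Ranks glycan compositions by the number of distinct glycosites bearing
#' them; ties are broken lexicographically on the canonical composition
#' string so the output is deterministic.
#'
#' @param records Identification tibble.
#' @param n Number of top compositions to return (default 10).
#' @return Tibble: `glycan`, `glycan_type`, `n_sites`, descending.
#' @export
top_glycans_by_site_count <- function(records, n = 10) {
  r <- as_glyco_records(records)
  out <- r |>
    dplyr::distinct(.data$accession, .data$site, .data$glycan) |>
    dplyr::count(.data$glycan, name = "n_sites") |>
    dplyr::arrange(dplyr::desc(.data$n_sites), .data$glycan) |>
    utils::head(n)
  out$glycan_type <- classify_glycan(out$glycan)
  out[c("glycan", "glycan_type", "n_sites")]
}

#' Glycoform diversity per protein
#'
#' @param records Identification tibble.
#' @return Tibble per accession: `n_unique_glycans` (distinct compositions
#'   observed on the protein), `n_sites`, sorted by glycan diversity.
#' @export
glycoform_diversity_per_protein <- function(records) {
  r <- as_glyco_records(records)
  r |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      n_unique_glycans = dplyr::n_distinct(.data$glycan),
      n_sites = dplyr::n_distinct(.data$site),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_unique_glycans),
                   dplyr::desc(.data$n_sites), .data$accession)
}

#' Glycan-type co-occurrence at glycosites
#'
#' For every glycosite, forms the set of glycan types observed there; counts
#' how often each type subset occurs. Each site contributes exactly one
#' subset, so counts sum to the number of sites. The long format (one row
#' per subset with a `+`-joined label) is ready for UpSet-style plotting.
#'
#' @param records Identification tibble.
#' @param mannose_min_hex Passed to [classify_glycan()].
#' @return Tibble: `type_set` (label), `n_types`, `n_sites`, descending.
#' @export
type_cooccurrence_at_sites <- function(records, mannose_min_hex = 5) {
  r <- as_glyco_records(records)
  r$glycan_type <- as.character(
    classify_glycan(r$glycan, mannose_min_hex = mannose_min_hex))
  per_site <- r |>
    dplyr::distinct(.data$accession, .data$site, .data$glycan_type) |>
    dplyr::group_by(.data$accession, .data$site) |>
    dplyr::summarise(
      type_set = paste(sort(unique(.data$glycan_type)), collapse = "+"),
      n_types = dplyr::n_distinct(.data$glycan_type),
      .groups = "drop"
    )
  per_site |>
    dplyr::count(.data$type_set, .data$n_types, name = "n_sites") |>
    dplyr::arrange(dplyr::desc(.data$n_sites), .data$type_set)
}
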