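#' Glycan type labels
#'
#' The five-class composition-only partition used throughout the package:
#' high-mannose, sialylated, fucosylated, complex/hybrid, and
#' fucosylated-sialylated. Terminal decorations (fucose, sialic acid) take
#' precedence over the high-mannose rule, so a branched sialylated glycan such
#' as N4H5F0S2 is typed `sialylated` even though its core is complex.
#'
#' @format Character vector of the five type labels, in display order.
#' @export
glycan_type_levels <- c(
  "mannose", "sialylated", "fucosylated", "complex_hybrid",
  "fucosylated_sialylated"
)

#' Parse N-glycan composition strings
#'
#' Parses monosaccharide composition strings of the form `"N#H#F#S#"` giving
#' the counts of HexNAc (N), hexose (H), fucose (F) and sialic acid / NeuAc
#' (S). Parsing is case-insensitive and tolerates vendor orderings that
#' permute the four letters; the canonical uppercase `N..H..F..S..` form is
#' returned in the `glycan` column. All four fields must be present exactly
#' once.
#'
#' @param x Character vector of composition strings, e.g. `"N4H5F0S2"`.
#' @param strict Logical; when `TRUE` (default) compositions with fewer than
#'   two HexNAc residues trigger a warning, since every N-glycan carries a
#'   chitobiose (HexNAc2) core. Such rows are still returned.
#' @return A tibble with one row per input: `input` (the original string),
#'   `glycan` (canonical form), and integer counts `hexnac`, `hex`, `fuc`,
#'   `neuac`.
#' @examples
#' parse_glycan_composition(c("N4H5F0S2", "n2h6f0s0"))
#' @export
parse_glycan_composition <- function(x, strict = TRUE) {
  if (!is.character(x)) {
    stop("`x` must be a character vector of composition strings.", call. = FALSE)
  }
  xs <- toupper(trimws(x))
  counts <- matrix(NA_integer_, nrow = length(xs), ncol = 4,
                   dimnames = list(NULL, c("N", "H", "F", "S")))
  # a composition is a sequence of exactly four <letter><int> tokens, letters
  # N,H,F,S each appearing once, in any order
  token_re <- "([NHFS])([0-9]+)"
  full_re  <- "^([NHFS][0-9]+){4}$"
  ok_shape <- !is.na(xs) & grepl(full_re, xs)
  bad <- which(!is.na(xs) & !ok_shape)
  if (length(bad) > 0) {
    stop(
      "Malformed glycan composition string(s): ",
      paste(utils::head(unique(x[bad]), 5), collapse = ", "),
      if (length(bad) > 5) " ..." else "",
      "\nExpected four fields N<int>H<int>F<int>S<int> (any order, case-insensitive).",
      call. = FALSE
    )
  }
  m <- stringr::str_match_all(xs, token_re)
  for (i in seq_along(xs)) {
    if (is.na(xs[i])) next
    tok <- m[[i]]
    if (anyDuplicated(tok[, 2]) > 0) {
      stop("Duplicated field '", tok[duplicated(tok[, 2]), 2][1],
           "' in glycan composition '", x[i], "'.", call. = FALSE)
    }
    counts[i, tok[, 2]] <- as.integer(tok[, 3])
  }
  out <- tibble::tibble(
    input  = x,
    glycan = ifelse(is.na(xs), NA_character_,
                    sprintf("N%dH%dF%dS%d",
                            counts[, "N"], counts[, "H"],
                            counts[, "F"], counts[, "S"])),
    hexnac = unname(counts[, "N"]),
    hex    = unname(counts[, "H"]),
    fuc    = unname(counts[, "F"]),
    neuac  = unname(counts[, "S"])
  )
  if (strict) {
    n_low <- sum(out$hexnac < 2, na.rm = TRUE)
    if (n_low > 0) {
      warning(n_low, " composition(s) have fewer than 2 HexNAc residues and ",
              "are implausible as N-glycans (core = HexNAc2).", call. = FALSE)
    }
  }
  out
}

#' Canonicalize composition strings
#'
#' @param x Character vector of composition strings.
#' @return Character vector in canonical `N#H#F#S#` form.
#' @export
canonical_glycan <- function(x) {
  parse_glycan_composition(x, strict = FALSE)$glycan
}

#' Classify glycan compositions into five types
#'
#' Applies the composition-only partition: any fucose together with any sialic
#' acid gives `fucosylated_sialylated`; sialic acid alone `sialylated`; fucose
#' alone `fucosylated`; no terminal decoration with exactly two HexNAc and at
#' least `mannose_min_hex` hexoses gives `mannose` (high-mannose, Man5 and
#' up); everything else is `complex_hybrid`. The partition is exhaustive and
#' mutually exclusive.
#'
#' @param x Character vector of composition strings, or a data frame as
#'   returned by [parse_glycan_composition()] (columns `hexnac`, `hex`, `fuc`,
#'   `neuac`).
#' @param mannose_min_hex Minimum hexose count for the high-mannose class
#'   (default 5, i.e. Man5). Compositions with HexNAc2 but fewer hexoses
#'   (paucimannose) fall into `complex_hybrid`.
#' @return Factor with levels [glycan_type_levels], same length as the input.
#' @examples
#' classify_glycan(c("N2H6F0S0", "N4H5F0S2", "N4H5F1S1", "N3H4F0S0"))
#' @export
classify_glycan <- function(x, mannose_min_hex = 5) {
  if (is.character(x)) {
    x <- parse_glycan_composition(x, strict = FALSE)
  }
  stopifnot(all(c("hexnac", "hex", "fuc", "neuac") %in% names(x)))
  lab <- dplyr::case_when(
    x$fuc > 0 & x$neuac > 0 ~ "fucosylated_sialylated",
    x$neuac > 0             ~ "sialylated",
    x$fuc > 0               ~ "fucosylated",
    x$hexnac == 2 & x$hex >= mannose_min_hex ~ "mannose",
    TRUE                    ~ "complex_hybrid"
  )
  factor(lab, levels = glycan_type_levels)
}

#' Classify the N-glycosylation sequon of a peptide site
#'
#' Reads the N-X-S/T/C motif at a glycosite. `site_index` is the 1-based
#' position of the asparagine within `peptide`. The motif is `NXT`, `NXS` or
#' `NXC` according to the residue two positions downstream, and `invalid` when
#' X (the +1 residue) is proline or the +2 residue is none of S/T/C. When the
#' +2 residue falls outside the peptide, flanking context can be supplied via
#' `context`; without it the motif is `invalid` (such sites are excluded from
#' motif tabulations).
#'
#' @param peptide Character vector of amino-acid sequences.
#' @param site_index Integer vector, 1-based position of the glycosylated
#'   asparagine within each peptide.
#' @param context Optional character vector of downstream flanking residues
#'   (the amino acids immediately following the peptide in the protein), used
#'   when the sequon extends past the peptide C terminus.
#' @return Factor with levels `NXT`, `NXS`, `NXC`, `invalid`.
#' @examples
#' classify_sequon(c("LNGTK", "NPSA", "NACD"), c(2, 1, 1))
#' @export
classify_sequon <- function(peptide, site_index, context = NULL) {
  peptide <- toupper(peptide)
  n <- length(peptide)
  site_index <- rep_len(as.integer(site_index), n)
  if (is.null(context)) context <- rep("", n) else context <- rep_len(toupper(context), n)
  res <- substr(peptide, site_index, site_index)
  if (any(res != "N", na.rm = TRUE)) {
    bad <- which(res != "N")[1]
    stop("Residue at site_index is '", res[bad], "', not 'N' (peptide '",
         peptide[bad], "', position ", site_index[bad], ").", call. = FALSE)
  }
  ext <- paste0(peptide, context)
  x1 <- substr(ext, site_index + 1L, site_index + 1L)
  x2 <- substr(ext, site_index + 2L, site_index + 2L)
  lab <- dplyr::case_when(
    x1 == "" | x2 == "" ~ "invalid",   # sequon extends past available sequence
    x1 == "P"           ~ "invalid",
    x2 == "T"           ~ "NXT",
    x2 == "S"           ~ "NXS",
    x2 == "C"           ~ "NXC",
    TRUE                ~ "invalid"
  )
  factor(lab, levels = c("NXT", "NXS", "NXC", "invalid"))
}
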