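# shared fixture builders; everything is generated in code

toy_design <- function(n_per_group = 3, batch = "1", with_ref = FALSE,
                       conditions = c("Tumor", "NAT")) {
  d <- tibble::tibble(
    sample_id = c(paste0("A", seq_len(n_per_group)),
                  paste0("B", seq_len(n_per_group))),
    batch = batch,
    channel = paste0("ch", seq_len(2 * n_per_group)),
    condition = rep(conditions, each = n_per_group),
    pair_id = rep(paste0("p", seq_len(n_per_group)), 2),
    is_reference = FALSE
  )
  if (with_ref) {
    d <- dplyr::bind_rows(d, tibble::tibble(
      sample_id = paste0("REF_B", batch), batch = batch,
      channel = paste0("ch", 2 * n_per_group + 1),
      condition = "Reference", pair_id = NA_character_, is_reference = TRUE
    ))
  }
  validate_study_design(d)
}

# quant tibble from a named list of sample columns
toy_quant <- function(feature_id, ...) {
  tibble::tibble(feature_id = feature_id, ...)
}

# independent scalar reimplementation of the four verbal classification
# rules, structured as nested if/else (the package uses vectorized algebra)
oracle_classify <- function(gp_fc, gp_p, prot, th = glyco_thresholds()) {
  # prot: list(fc=, status=) or NULL for not quantified
  quantified <- !is.null(prot)
  status <- if (quantified) prot$status else "not_quantified"
  if (gp_fc > th$fc_up && gp_p < th$alpha) {
    if (!quantified || status %in% c("not_sig", "not_quantified")) {
      return("A_direct_up")
    }
    if (gp_fc > prot$fc) return("A_direct_up")
    if (status == "sig_up" && prot$fc > gp_fc) return("D_occupancy_down")
    return("none")
  }
  if (gp_fc < th$fc_down && gp_p < th$alpha) {
    if (!quantified || status %in% c("not_sig", "not_quantified")) {
      return("C_direct_down")
    }
    if (gp_fc < prot$fc) return("C_direct_down")
    if (status == "sig_down" && prot$fc < gp_fc) return("B_occupancy_up")
    return("none")
  }
  "none"
}

# run classify_glycopeptides on scalar inputs, returning the branch
classify_one <- function(gp_fc, gp_p, prot_fc = NA, prot_p = NA, ...) {
  gp <- tibble::tibble(feature_id = "P1|10|PEP|N2H5F0S0", accession = "P1",
                       fold_change = gp_fc, log2_fc = log2(gp_fc),
                       p_value = gp_p)
  prot <- NULL
  if (!is.na(prot_fc)) {
    prot <- call_protein_de(tibble::tibble(
      feature_id = "P1", fold_change = prot_fc, log2_fc = log2(prot_fc),
      p_value = prot_p))
  }
  res <- classify_glycopeptides(gp, prot, ...)
  list(branch = res$branch, label = res$label,
       protein_status = res$protein_status)
}

protein_status_of <- function(fc, p, th = glyco_thresholds()) {
  if (fc > th$fc_up && p < th$alpha) "sig_up"
  else if (fc < th$fc_down && p < th$alpha) "sig_down"
  else "not_sig"
}
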