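#' Simulate a targeted qPCR panel with planted expression differences
#'
#' Builds raw Ct values for a small gene panel plus the `ACTB` reference
#' gene, matching the biopsy design of the expression cohort (LS biopsies
#' at every visit, NL at week 0). True relative log2 expression of gene g
#' is 0 in NL, `qpcr_log2_deltas[g]` in baseline LS, and
#' `(1 - f(arm, t)) * qpcr_log2_deltas[g]` after treatment, so planted
#' differences appear downstream as negative delta-delta-Ct.
#'
#' @param config a [cohort_config()] object.
#' @return list with `qpcr` (tibble: `gene`, `sample_id`, `patient_id`,
#'   `arm`, `week`, `tissue`, `replicate`, `ct`) and `truth`
#'   (planted log2 deltas and fractions).
#' @export
simulate_qpcr_fixture <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed + 2L)

  deltas <- config$qpcr_log2_deltas
  genes <- c(names(deltas), "ACTB")
  nfr <- config$normalization_fraction

  samples <- list()
  for (arm in config$arms) {
    for (i in seq_len(config$n_patients_per_arm)) {
      pid <- sprintf("%s_P%02d", arm, i)
      samples[[length(samples) + 1]] <- tibble(
        sample_id = sprintf("%s_NL_wk00", pid), patient_id = pid,
        arm = arm, week = 0, tissue = "NL")
      for (w in config$weeks) {
        samples[[length(samples) + 1]] <- tibble(
          sample_id = sprintf("%s_LS_wk%02d", pid, w), patient_id = pid,
          arm = arm, week = w, tissue = "LS")
      }
    }
  }
  samples <- dplyr::bind_rows(samples)

  f_lookup <- stats::setNames(nfr$f, paste(nfr$arm, nfr$week))
  expr_of <- function(gene, arm, week, tissue) {
    if (gene == "ACTB") return(0)
    d <- deltas[[gene]]
    if (tissue == "NL") return(0)
    if (week == 0) return(d)
    (1 - f_lookup[[paste(arm, week)]]) * d
  }

  tab <- tidyr::expand_grid(samples, gene = genes,
                            replicate = seq_len(config$qpcr_n_replicates))
  true_expr <- purrr::pmap_dbl(
    list(tab$gene, tab$arm, tab$week, tab$tissue), expr_of)
  # log2 normalized expression = -delta Ct, so Ct = reference Ct - expression
  tab$ct <- config$qpcr_reference_ct - true_expr +
    stats::rnorm(nrow(tab), 0, config$qpcr_noise_sd)

  list(
    qpcr = dplyr::select(tab, "gene", "sample_id", "patient_id", "arm",
                         "week", "tissue", "replicate", "ct"),
    truth = list(log2_deltas = deltas,
                 normalization_fraction = nfr,
                 reference_gene = "ACTB")
  )
}
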