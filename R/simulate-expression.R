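#' Simulate a paired-biopsy expression cohort with planted ground truth
#'
#' Generates log2 expression for a multi-arm psoriasis skin substudy:
#' per patient one nonlesional (NL) biopsy at week 0 and lesional (LS)
#' biopsies at every configured visit. Signature genes carry a planted
#' disease effect that treatment removes according to the configured
#' normalization fractions; scar genes retain a residual effect in healed
#' (PASI100) biopsies. See [cohort_config()] for the generative model.
#'
#' @param config a [cohort_config()] object.
#' @return list with components
#'   * `expr`: tibble, `feature_id` plus one column per sample (log2 scale);
#'   * `annot`: sample annotation tibble (`sample_id`, `patient_id`, `arm`,
#'     `week`, `tissue`, `pasi`, `pasi100`, `pasi_improvement`);
#'   * `truth`: list with `signature_features`, `disease_delta` (named),
#'     `normalization_fraction`, `scar_features`, `scar_residual_delta`.
#' @export
#' @examples
#' cohort <- simulate_expression_cohort(
#'   cohort_config(n_patients_per_arm = 4, n_features = 60,
#'                 n_signature_features = 12, seed = 42))
#' head(cohort$annot)
simulate_expression_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)

  nf <- config$n_features
  feature_ids <- sprintf("F%05d", seq_len(nf))
  baseline <- stats::runif(nf, 4, 12)

  sig_idx <- sort(sample.int(nf, config$n_signature_features))
  D <- numeric(nf)
  if (length(sig_idx)) {
    magnitude <- abs(stats::rnorm(length(sig_idx), config$disease_delta_mean,
                                  config$disease_delta_sd))
    sgn <- sample(c(-1, 1), length(sig_idx), replace = TRUE)
    D[sig_idx] <- sgn * magnitude
  }
  scar_idx <- sort(sample(sig_idx, config$n_scar_features))

  f_of <- function(arm, week) {
    if (week == 0) return(0)
    nfr <- config$normalization_fraction
    nfr$f[nfr$arm == arm & nfr$week == week]
  }

  # enumerate biopsies in a fixed order: arm, patient, (NL wk0, LS per week)
  rows <- list()
  for (arm in config$arms) {
    for (i in seq_len(config$n_patients_per_arm)) {
      pid <- sprintf("%s_P%02d", arm, i)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = sprintf("%s_NL_wk00", pid), patient_id = pid, arm = arm,
        week = 0, tissue = "NL")
      for (w in config$weeks) {
        keep <- w == 0 || stats::runif(1) <= config$retention
        if (keep) {
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sprintf("%s_LS_wk%02d", pid, w), patient_id = pid,
            arm = arm, week = w, tissue = "LS")
        }
      }
    }
  }
  annot <- dplyr::bind_rows(rows)
  ns <- nrow(annot)

  mu <- matrix(baseline, nrow = nf, ncol = ns)
  for (j in seq_len(ns)) {
    if (annot$tissue[j] == "LS") {
      mu[, j] <- mu[, j] + (1 - f_of(annot$arm[j], annot$week[j])) * D
    }
  }
  X <- mu + matrix(stats::rnorm(nf * ns, 0, config$noise_sd), nrow = nf)
  dimnames(X) <- list(feature_ids, annot$sample_id)

  # clinical response coupled to each patient's realized normalization
  pasi0 <- pmin(pmax(stats::rnorm(length(unique(annot$patient_id)),
                                  config$pasi_baseline_mean,
                                  config$pasi_baseline_sd), 12), 72)
  names(pasi0) <- unique(annot$patient_id)

  annot$pasi <- unname(pasi0[annot$patient_id])
  annot$pasi100 <- FALSE
  annot$pasi_improvement <- ifelse(annot$week == 0, 0, NA_real_)

  d2 <- sum(D[sig_idx]^2)
  follow <- which(annot$tissue == "LS" & annot$week > 0)
  for (j in follow) {
    b0 <- annot$sample_id == paste0(annot$patient_id[j], "_LS_wk00")
    if (!any(b0)) next
    dx <- X[sig_idx, j] - X[sig_idx, which(b0)]
    f_real <- if (d2 > 0) -sum(dx * D[sig_idx]) / d2 else 0
    raw <- 100 * min(max(f_real, 0), 1) + stats::rnorm(1, 0, config$pasi_noise_sd)
    annot$pasi_improvement[j] <- raw
    annot$pasi100[j] <- raw >= 100
    annot$pasi[j] <- if (raw >= 100) 0 else
      max(0, pasi0[annot$patient_id[j]] * (1 - min(raw, 100) / 100))
  }

  # healed biopsies keep a residual disease effect at the scar genes
  healed <- which(annot$pasi100)
  if (length(healed) && length(scar_idx)) {
    resid <- sign(D[scar_idx]) * config$scar_residual_delta
    noise <- matrix(stats::rnorm(length(scar_idx) * length(healed), 0, config$noise_sd),
                    nrow = length(scar_idx))
    X[scar_idx, healed] <- baseline[scar_idx] + resid + noise
  }

  truth <- list(
    signature_features = feature_ids[sig_idx],
    disease_delta = stats::setNames(D[sig_idx], feature_ids[sig_idx]),
    normalization_fraction = config$normalization_fraction,
    scar_features = feature_ids[scar_idx],
    scar_residual_delta = config$scar_residual_delta
  )

  expr <- dplyr::bind_cols(tibble(feature_id = feature_ids),
                           as_tibble(as.data.frame(X)))
  list(expr = expr, annot = annot, truth = truth)
}
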