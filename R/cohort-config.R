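#' Configuration for synthetic biomarker cohorts
#'
#' Defines the study conditions emulated by the synthetic generators: a
#' three-arm randomized psoriasis trial (guselkumab, adalimumab, placebo
#' crossing over to guselkumab at week 16) with lesional (LS) biopsies at
#' weeks 0/4/24/48 and a nonlesional (NL) biopsy at week 0, longitudinal
#' serum sampling at the same visits plus an independent healthy-control
#' cohort, and a targeted qPCR panel.
#'
#' The expression model is specified directly on the log2 scale. For a
#' signature gene g with disease effect `D_g` (|D| drawn from
#' Normal(`disease_delta_mean`, `disease_delta_sd`) with random sign):
#' NL values are Normal(baseline_g, `noise_sd`); LS at week 0 adds `D_g`;
#' LS at week t adds `(1 - f(arm, t)) * D_g` where f is the per-arm,
#' per-week normalization fraction. Scar genes in biopsies from visits at
#' which the patient has reached complete clearance (PASI100) retain a
#' residual `sign(D_g) * scar_residual_delta` instead.
#'
#' PASI percent improvement at each lesional visit is a noisy monotone
#' function of the patient's realized transcriptomic normalization:
#' `100 * clip(f_realized, 0, 1) + Normal(0, pasi_noise_sd)`, where
#' f_realized is the projection of the patient's log2 change onto the
#' planted signature. Raw values of 100 or more define PASI100.
#'
#' @param n_patients_per_arm patients per treatment arm in the skin cohort.
#' @param arms treatment arm labels; subset of `c("GUS","ADA","PBO_GUS")`.
#' @param weeks biopsy/serum visit weeks; must include 0.
#' @param n_features total expression features simulated.
#' @param n_signature_features number of features given a planted disease
#'   effect (the ground-truth signature); at most `n_features`.
#' @param disease_delta_mean,disease_delta_sd mean and sd of the absolute
#'   log2 LS-NL disease effect.
#' @param noise_sd residual log2-scale sd for every expression measurement.
#' @param normalization_fraction data frame (`arm`, `week`, `f`) giving the
#'   fraction of the disease effect removed by treatment at each visit;
#'   f must lie in \[0, 1.5\]. Defaults to the published week-4/48 values
#'   with interpolated week-24 values (see the methods vignette).
#' @param n_scar_features number of signature genes that retain a residual
#'   effect in healed skin.
#' @param scar_residual_delta absolute residual log2 effect for scar genes
#'   in healed (PASI100) lesional biopsies.
#' @param pasi_baseline_mean,pasi_baseline_sd baseline PASI distribution
#'   (clipped to the moderate-to-severe entry range \[12, 72\]).
#' @param pasi_noise_sd sd of the noise coupling PASI improvement to
#'   transcriptomic normalization.
#' @param retention per-visit probability that a follow-up biopsy was
#'   collected (1 = no dropout).
#' @param serum_n_per_arm named integer vector of serum-substudy patients
#'   per arm.
#' @param n_controls healthy-control serum donors.
#' @param serum_baseline data frame (`analyte`, `gm_pso_total`, `gm_hc`,
#'   `lloq`) of per-analyte baseline geometric means (pg/ml); defaults to
#'   the published baseline table.
#' @param serum_effects data frame (`analyte`, `arm`, `week`,
#'   `log2_change`) of planted treatment effects; defaults to the
#'   published longitudinal effects.
#' @param serum_subject_sd,serum_residual_sd log2-scale between-subject and
#'   within-subject (residual) sd of serum concentrations.
#' @param qpcr_log2_deltas named numeric vector of planted baseline LS-NL
#'   log2 expression differences for the qPCR panel genes.
#' @param qpcr_reference_ct mean cycle threshold of the reference gene.
#' @param qpcr_noise_sd per-replicate Ct noise sd (0 = noise-free).
#' @param qpcr_n_replicates technical replicates per (gene, sample).
#' @param seed integer seed; identical configs with identical seeds yield
#'   bit-identical cohorts.
#' @return an object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients_per_arm = 4, n_features = 50,
#'                      n_signature_features = 10, seed = 1)
#' cohort <- simulate_expression_cohort(cfg)
#' dim(cohort$expr)
cohort_config <- function(n_patients_per_arm = 20,
                          arms = c("GUS", "ADA", "PBO_GUS"),
                          weeks = c(0, 4, 24, 48),
                          n_features = 1000,
                          n_signature_features = 200,
                          disease_delta_mean = 2,
                          disease_delta_sd = 0.3,
                          noise_sd = 0.5,
                          normalization_fraction = default_normalization_fractions(arms, weeks),
                          n_scar_features = 10,
                          scar_residual_delta = 0.8,
                          pasi_baseline_mean = 18,
                          pasi_baseline_sd = 6,
                          pasi_noise_sd = 10,
                          retention = 1,
                          serum_n_per_arm = c(GUS = 40, ADA = 38, PBO_GUS = 40),
                          n_controls = 25,
                          serum_baseline = serum_baseline_reference(),
                          serum_effects = serum_effect_reference(),
                          serum_subject_sd = 0.8,
                          serum_residual_sd = 0.6,
                          qpcr_log2_deltas = c(QG01 = 11, QG02 = 2.5, QG03 = 1,
                                               QG04 = -1.5, QG05 = 0.5),
                          qpcr_reference_ct = 20,
                          qpcr_noise_sd = 0,
                          qpcr_n_replicates = 3,
                          seed = 1L) {
  cfg <- list(
    n_patients_per_arm = as.integer(n_patients_per_arm),
    arms = arms, weeks = sort(unique(weeks)),
    n_features = as.integer(n_features),
    n_signature_features = as.integer(n_signature_features),
    disease_delta_mean = disease_delta_mean,
    disease_delta_sd = disease_delta_sd,
    noise_sd = noise_sd,
    normalization_fraction = as_tibble(normalization_fraction),
    n_scar_features = as.integer(n_scar_features),
    scar_residual_delta = scar_residual_delta,
    pasi_baseline_mean = pasi_baseline_mean,
    pasi_baseline_sd = pasi_baseline_sd,
    pasi_noise_sd = pasi_noise_sd,
    retention = retention,
    serum_n_per_arm = serum_n_per_arm,
    n_controls = as.integer(n_controls),
    serum_baseline = as_tibble(serum_baseline),
    serum_effects = as_tibble(serum_effects),
    serum_subject_sd = serum_subject_sd,
    serum_residual_sd = serum_residual_sd,
    qpcr_log2_deltas = qpcr_log2_deltas,
    qpcr_reference_ct = qpcr_reference_ct,
    qpcr_noise_sd = qpcr_noise_sd,
    qpcr_n_replicates = qpcr_n_replicates,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Default per-arm, per-week normalization fractions
#'
#' Week-4 and week-48 values are the published mean improvements per arm;
#' week-24 values are chosen so that the adalimumab response peaks at week
#' 24 while guselkumab improves monotonically, and the crossover arm is
#' flat until its switch to active treatment at week 16.
#'
#' @param arms,weeks arm labels and visit weeks to cover.
#' @return tibble with columns `arm`, `week`, `f`.
#' @export
default_normalization_fractions <- function(arms = c("GUS", "ADA", "PBO_GUS"),
                                            weeks = c(0, 4, 24, 48)) {
  full <- tibble::tribble(
    ~arm,      ~week,   ~f,
    "GUS",         4, 0.65,
    "GUS",        24, 0.90,
    "GUS",        48, 1.06,
    "ADA",         4, 0.44,
    "ADA",        24, 0.85,
    "ADA",        48, 0.79,
    "PBO_GUS",     4, 0.00,
    "PBO_GUS",    24, 0.75,
    "PBO_GUS",    48, 1.00
  )
  full[full$arm %in% arms & full$week %in% weeks, ]
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients_per_arm < 1) stop_validation("need at least one patient per arm")
  if (!all(cfg$arms %in% c("GUS", "ADA", "PBO_GUS"))) {
    stop_validation("arms must be a subset of GUS, ADA, PBO_GUS")
  }
  if (!0 %in% cfg$weeks) stop_validation("weeks must include the baseline visit (0)")
  if (cfg$n_signature_features > cfg$n_features) {
    stop_validation("n_signature_features cannot exceed n_features")
  }
  if (cfg$n_scar_features > cfg$n_signature_features) {
    stop_validation("scar features must be a subset of the signature")
  }
  if (cfg$noise_sd <= 0 || cfg$disease_delta_sd <= 0) {
    stop_validation("all standard deviations must be positive")
  }
  nf <- cfg$normalization_fraction
  if (!all(c("arm", "week", "f") %in% names(nf))) {
    stop_validation("normalization_fraction needs columns arm, week, f")
  }
  if (any(nf$f < 0 | nf$f > 1.5)) {
    stop_validation("normalization fractions must lie in [0, 1.5]")
  }
  need <- expand.grid(arm = cfg$arms, week = setdiff(cfg$weeks, 0),
                      stringsAsFactors = FALSE)
  have <- paste(nf$arm, nf$week)
  miss <- !paste(need$arm, need$week) %in% have
  if (any(miss)) {
    stop_validation(paste0("normalization_fraction is missing (arm, week) combinations: ",
                           paste(paste(need$arm[miss], need$week[miss]), collapse = "; ")))
  }
  sb <- cfg$serum_baseline
  if (any(sb$gm_pso_total <= 0) || any(sb$gm_hc <= 0)) {
    stop_validation("serum geometric means must be positive")
  }
  if (cfg$retention <= 0 || cfg$retention > 1) stop_validation("retention must be in (0, 1]")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  skin cohort:  ", x$n_patients_per_arm, "patients/arm,",
      length(x$arms), "arms, weeks", paste(x$weeks, collapse = "/"), "\n")
  cat("  features:     ", x$n_features, "total,", x$n_signature_features,
      "signature,", x$n_scar_features, "scar\n")
  cat("  effect sizes: |D| ~ N(", x$disease_delta_mean, ",", x$disease_delta_sd,
      "), noise sd", x$noise_sd, "\n")
  cat("  serum:        ", sum(x$serum_n_per_arm), "patients +", x$n_controls,
      "controls,", nrow(x$serum_baseline), "analytes\n")
  cat("  seed:         ", x$seed, "\n")
  invisible(x)
}
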