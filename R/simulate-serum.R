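#' Simulate a longitudinal serum cytokine cohort
#'
#' Concentrations are log-normal around per-group geometric means with a
#' subject random intercept: for patient s on arm a at week t,
#' `log2 conc = log2(gm_analyte) + u_s + planted log2 change(a, t) + e`,
#' with `u_s ~ N(0, serum_subject_sd)` and `e ~ N(0, serum_residual_sd)`.
#' Healthy controls are sampled at week 0 only around their own geometric
#' means. Draws below the analyte's lower limit of quantification are
#' flagged (`below_lloq`), with the raw draw retained so that LLOQ policy
#' is an analysis choice (see [apply_lloq_policy()]).
#'
#' @param config a [cohort_config()] object.
#' @return list with components
#'   * `serum`: long tibble (`subject_id`, `group`, `week`, `analyte`,
#'     `concentration` (pg/ml), `below_lloq`, `lloq`);
#'   * `truth`: list with the per-analyte geometric means and the planted
#'     per-(analyte, arm, week) log2 changes.
#' @export
simulate_serum_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed + 1L)

  sb <- config$serum_baseline
  eff <- config$serum_effects
  analytes <- sb$analyte
  arms <- intersect(names(config$serum_n_per_arm), config$arms)
  weeks <- config$weeks

  subjects <- dplyr::bind_rows(
    purrr::map(arms, function(a) tibble(
      subject_id = sprintf("%s_S%03d", a, seq_len(config$serum_n_per_arm[[a]])),
      group = a)),
    tibble(subject_id = sprintf("HC_S%03d", seq_len(config$n_controls)),
           group = "HC"))

  grid <- tidyr::expand_grid(subjects, analyte = analytes) %>%
    tidyr::expand_grid(week = weeks) %>%
    dplyr::filter(.data$group != "HC" | .data$week == 0)

  # subject-by-analyte random intercepts, fixed draw order
  key <- paste(grid$subject_id, grid$analyte)
  ukey <- unique(key)
  u <- stats::setNames(stats::rnorm(length(ukey), 0, config$serum_subject_sd), ukey)

  base_lookup <- stats::setNames(log2(sb$gm_pso_total), sb$analyte)
  hc_lookup <- stats::setNames(log2(sb$gm_hc), sb$analyte)
  lloq_lookup <- stats::setNames(sb$lloq, sb$analyte)

  eff_key <- paste(eff$analyte, eff$arm, eff$week)
  eff_lookup <- stats::setNames(eff$log2_change, eff_key)
  planted <- ifelse(grid$group == "HC" | grid$week == 0, 0,
                    unname(eff_lookup[paste(grid$analyte, grid$group, grid$week)]))
  if (anyNA(planted)) stop_validation("serum_effects is missing planted (analyte, arm, week) values")

  mu <- unname(ifelse(grid$group == "HC", hc_lookup[grid$analyte],
                      base_lookup[grid$analyte]))
  log2c <- mu + unname(u[key]) + planted +
    stats::rnorm(nrow(grid), 0, config$serum_residual_sd)

  serum <- grid %>%
    dplyr::mutate(
      concentration = 2^log2c,
      lloq = unname(lloq_lookup[.data$analyte]),
      below_lloq = .data$concentration < .data$lloq
    ) %>%
    dplyr::arrange(.data$analyte, .data$group, .data$subject_id, .data$week)

  truth <- list(
    geometric_means = sb[, c("analyte", "gm_pso_total", "gm_hc")],
    planted_log2_changes = eff,
    case_control_log2_ratio = stats::setNames(
      log2(sb$gm_pso_total / sb$gm_hc), sb$analyte)
  )
  list(serum = serum, truth = truth)
}
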