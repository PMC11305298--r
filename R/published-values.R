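#' Published baseline serum cytokine geometric means
#'
#' Baseline serum cytokine concentrations from the VOYAGE 1 biomarker
#' substudy, reported as geometric means (pg/ml) per randomized arm, for
#' the pooled psoriasis population (n = 118) and for an independent
#' demographically matched healthy control cohort (n = 25), together with
#' the published case-control fold change and the assay lower limits of
#' quantification. These values serve two roles: they are worked-example
#' inputs for [fold_change_from_geometric_means()] and they seed the
#' serum defaults of [cohort_config()].
#'
#' @return tibble with columns `analyte`, `gm_pbo`, `gm_gus`, `gm_ada`,
#'   `gm_pso_total`, `gm_hc`, `fc_printed`, `lloq` (pg/ml; 0 when the assay
#'   floor is not applicable).
#' @export
#' @examples
#' serum_baseline_reference()
serum_baseline_reference <- function() {
  tibble::tribble(
    ~analyte,  ~gm_pbo, ~gm_gus, ~gm_ada, ~gm_pso_total,  ~gm_hc, ~fc_printed, ~lloq,
    "IL-17A",     0.91,    1.07,    1.55,          1.14,    0.41,        2.77, 0.034,
    "IL-17F",     4.25,    5.75,    5.07,          4.99,    1.59,        3.14, 0.39,
    "IL-22",     27.87,   26.00,   36.04,         29.57,   11.29,        2.62, 0.24,
    "IL-23",      0.88,    1.05,    1.02,          0.98,    0.83,        1.18, 0.1,
    "CXCL8",     15.69,   12.03,   15.01,         14.15,   10.14,        1.40, 0,
    "CCL22",   1919.20, 2132.25, 2285.01,       2101.87, 1295.24,        1.62, 0,
    "CCL4",     119.58,  117.24,  118.54,        118.47,   81.59,        1.45, 0
  )
}

#' Published longitudinal serum effects (log2 change from baseline)
#'
#' Model-adjusted mean log2 changes from baseline (emmeans from the
#' VOYAGE 1 serum biomarker analysis) per analyte, arm and week. Negative
#' values are reductions. Used as the planted per-(arm, week) treatment
#' effects in the default synthetic serum cohort.
#'
#' @return tibble with columns `analyte`, `arm`, `week`, `log2_change`.
#' @export
serum_effect_reference <- function() {
  wide <- tibble::tribble(
    ~analyte, ~week,     ~ADA,      ~GUS, ~PBO_GUS,
    "IL-17A",     4, -0.59813, -1.00896, -0.21953,
    "IL-17A",    24, -1.29601, -1.70926, -1.48229,
    "IL-17A",    48, -0.94491, -1.69498, -1.67378,
    "IL-17F",     4, -0.72682, -1.27187, -0.28974,
    "IL-17F",    24, -1.30587, -1.92576, -1.65035,
    "IL-17F",    48, -1.37161, -2.09804, -2.10672,
    "IL-22",      4, -0.42821, -0.77461, -0.10187,
    "IL-22",     24, -0.66416, -1.07006, -0.77268,
    "IL-22",     48, -0.63489, -1.21593, -1.08685,
    "IL-23",      4, -0.26747, -0.04884, -0.10608,
    "IL-23",     24, -0.14350, -0.01792, -0.10088,
    "IL-23",     48, -0.20941, -0.04847, -0.06347,
    "CXCL8",      4, -0.20747, -0.16878, -0.19330,
    "CXCL8",     24, -0.28877, -0.23708, -0.34386,
    "CXCL8",     48, -0.25963, -0.27151, -0.18253,
    "CCL22",      4, -0.49239, -0.34511, -0.07272,
    "CCL22",     24, -0.62614, -0.50527, -0.50814,
    "CCL22",     48, -0.74717, -0.56404, -0.62944,
    "CCL4",       4, -0.70247,  0.00884, -0.05653,
    "CCL4",      24, -0.52527, -0.05264, -0.15329,
    "CCL4",      48, -0.57141, -0.05385, -0.05105
  )
  tidyr::pivot_longer(wide, cols = c("ADA", "GUS", "PBO_GUS"),
                      names_to = "arm", values_to = "log2_change")
}

#' Case-control fold change from geometric means
#'
#' The linear fold change between two groups measured on a positive scale
#' is the ratio of their geometric means (equivalently 2 to the difference
#' of mean log2 concentrations).
#'
#' @param gm_case,gm_control positive geometric means.
#' @return numeric fold change (case / control).
#' @export
#' @examples
#' fold_change_from_geometric_means(4.99, 1.59) # 3.14
fold_change_from_geometric_means <- function(gm_case, gm_control) {
  if (any(gm_case <= 0) || any(gm_control <= 0)) {
    stop_validation("geometric means must be positive")
  }
  gm_case / gm_control
}
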