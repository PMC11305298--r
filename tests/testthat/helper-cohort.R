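# Shared small fixtures used across test files. Everything here is
# deterministic; the cached cohort avoids re-simulating in every file.

small_config <- function(seed = 101, ...) {
  cohort_config(n_patients_per_arm = 6, n_features = 120,
                n_signature_features = 30, n_scar_features = 4,
                seed = seed, ...)
}

.cohort_cache <- new.env(parent = emptyenv())

cached_small_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- simulate_expression_cohort(small_config())
  }
  .cohort_cache$cohort
}

# Hand-built noise-free two-patient, one-arm expression fixture:
#   gene GA: D = 2, week-4 treatment delta -1  -> PI  50
#   gene GB: D = 2, week-4 treatment delta -2  -> PI 100
#   gene GC: D = 0.05 (below the stability floor) -> unstable
manual_improvement_fixture <- function() {
  samples <- c("P1_NL", "P2_NL", "P1_LS0", "P2_LS0", "P1_LS4", "P2_LS4")
  X <- rbind(
    GA = c(5, 5, 7, 7, 6, 6),
    GB = c(5, 5, 7, 7, 5, 5),
    GC = c(5, 5, 5.05, 5.05, 5.05, 5.05)
  )
  colnames(X) <- samples
  annot <- tibble::tibble(
    sample_id = samples,
    patient_id = rep(c("P1", "P2"), 3),
    arm = "GUS",
    week = c(0, 0, 0, 0, 4, 4),
    tissue = c("NL", "NL", "LS", "LS", "LS", "LS"),
    pasi = 20
  )
  list(expr = X, annot = annot,
       signature = tibble::tibble(feature_id = c("GA", "GB", "GC"),
                                  disease_delta = c(2, 2, 0.05)))
}

# Hand-built healed-skin fixture for the molecular scar:
#   SA: D = 2, healed residual +0.8 (same sign), PI 60   -> in scar
#   SB: D = 2, healed residual 0,   PI 100               -> clean
#   SC: D = -2, healed residual +0.8 (opposite sign)     -> excluded
#   SD: D = 2, healed residual +2  (PI 0, |FC| 4)        -> in scar
manual_scar_fixture <- function() {
  samples <- c("P1_NL", "P2_NL", "P1_LS0", "P2_LS0", "P1_LS24", "P2_LS24")
  X <- rbind(
    SA = c(5, 5, 7, 7, 5.8, 5.8),
    SB = c(5, 5, 7, 7, 5, 5),
    SC = c(7, 7, 5, 5, 7.8, 7.8),
    SD = c(5, 5, 7, 7, 7, 7)
  )
  colnames(X) <- samples
  annot <- tibble::tibble(
    sample_id = samples,
    patient_id = rep(c("P1", "P2"), 3),
    arm = "GUS",
    week = c(0, 0, 0, 0, 24, 24),
    tissue = c("NL", "NL", "LS", "LS", "LS", "LS"),
    pasi = c(20, 20, 20, 20, 0, 0),
    pasi100 = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  list(expr = X, annot = annot,
       signature = tibble::tibble(feature_id = c("SA", "SB", "SC", "SD"),
                                  disease_delta = c(2, 2, -2, 2)))
}

# Long serum panel from per-group log2 concentration vectors
manual_serum_panel <- function(case_log2, hc_log2, analyte = "IL-17F",
                               lloq = 0) {
  tibble::tibble(
    subject_id = c(sprintf("GUS_S%02d", seq_along(case_log2)),
                   sprintf("HC_S%02d", seq_along(hc_log2))),
    group = c(rep("GUS", length(case_log2)), rep("HC", length(hc_log2))),
    week = 0,
    analyte = analyte,
    concentration = 2^c(case_log2, hc_log2),
    below_lloq = FALSE,
    lloq = lloq
  )
}
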