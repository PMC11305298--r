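#' Molecular scar: residual disease expression in healed skin
#'
#' Identifies the subset of signature genes that remain differentially
#' expressed in healed lesional skin (HLS): lesional biopsies taken at
#' visits where the patient had reached complete clearance (PASI100).
#' A gene belongs to the scar when, over the arm's healed biopsies, its
#' percent improvement is strictly below `pi_max` AND its residual fold
#' change versus the arm's nonlesional baseline mean strictly exceeds
#' `fc_min` in absolute value with the same sign as the disease effect.
#'
#' Improvement is recomputed with the treatment delta averaged over healed
#' biopsies only (each against the patient's baseline lesional biopsy);
#' the disease delta is the arm's baseline mean, as in
#' [gene_improvement()]. The residual reference is the arm's own
#' nonlesional baseline mean, and residuals opposite in direction to the
#' disease effect do not count as scar.
#'
#' @inheritParams gene_improvement
#' @param arm single treatment arm to evaluate.
#' @param pi_max improvement ceiling (percent, exclusive).
#' @param fc_min minimum residual absolute signed fold change (exclusive).
#' @return a `scar_result` object: `arm`, `healed_sample_ids`, a `features`
#'   tibble (`feature_id`, `disease_delta`, `residual_delta`,
#'   `residual_fold_change`, `pi_in_hls`, `unstable`, `in_scar`) and
#'   `scar_feature_ids`.
#' @export
molecular_scar <- function(expr, annot, signature, arm, pi_max = 75,
                           fc_min = 1.5, stability_floor = 0.1) {
  X <- as_expression_matrix(expr)
  annot <- validate_annotation(annot)
  feats <- signature_feature_ids(signature)
  feats <- feats[feats %in% rownames(X)]
  if (!length(feats)) stop_insufficient("no signature features in expression matrix")

  arm_annot <- annot[annot$arm == arm, , drop = FALSE]
  healed <- arm_annot[arm_annot$tissue == "LS" & arm_annot$week > 0 &
                        arm_annot$pasi100, , drop = FALSE]
  if (!nrow(healed)) {
    stop_insufficient(paste0("arm ", arm, " has no healed (PASI100) lesional biopsy"))
  }
  base_ls <- arm_annot[arm_annot$tissue == "LS" & arm_annot$week == 0, ]
  base_ids <- stats::setNames(base_ls$sample_id, base_ls$patient_id)
  healed <- healed[healed$patient_id %in% names(base_ids), , drop = FALSE]
  if (!nrow(healed)) {
    stop_insufficient("healed biopsies lack matching baseline lesional biopsies")
  }

  pairs <- baseline_pairs(arm_annot)
  if (!nrow(pairs)) stop_insufficient(paste0("arm ", arm, " has no complete baseline pair"))
  D <- rowMeans(expr_cols(X, pairs$ls_sample)[feats, , drop = FALSE] -
                expr_cols(X, pairs$nl_sample)[feats, , drop = FALSE])

  H <- expr_cols(X, healed$sample_id)[feats, , drop = FALSE]
  B <- expr_cols(X, base_ids[healed$patient_id])[feats, , drop = FALSE]
  Tg <- rowMeans(H - B)
  unstable <- abs(D) < stability_floor
  pi_hls <- ifelse(unstable, NA_real_, -100 * Tg / D)

  nl_mean <- rowMeans(expr_cols(X, pairs$nl_sample)[feats, , drop = FALSE])
  residual_delta <- rowMeans(H) - nl_mean
  residual_fc <- signed_fold(residual_delta)

  in_scar <- !unstable &
    pi_hls < pi_max &
    abs(residual_fc) > fc_min &
    sign(residual_delta) == sign(D)

  features <- tibble(
    feature_id = feats,
    disease_delta = unname(D),
    residual_delta = unname(residual_delta),
    residual_fold_change = unname(residual_fc),
    pi_in_hls = unname(pi_hls),
    unstable = unname(unstable),
    in_scar = unname(in_scar)
  )
  structure(
    list(arm = arm,
         healed_sample_ids = healed$sample_id,
         features = features,
         scar_feature_ids = feats[in_scar],
         pi_max = pi_max, fc_min = fc_min),
    class = "scar_result"
  )
}

#' @export
print.scar_result <- function(x, ...) {
  cat("<scar_result> arm ", x$arm, ": ", length(x$scar_feature_ids),
      " of ", nrow(x$features), " signature genes in scar (",
      length(x$healed_sample_ids), " healed biopsies)\n", sep = "")
  invisible(x)
}

#' @export
tidy.scar_result <- function(x, ...) x$features

#' @export
glance.scar_result <- function(x, ...) {
  tibble(
    arm = x$arm,
    n_healed_samples = length(x$healed_sample_ids),
    n_signature = nrow(x$features),
    n_scar = length(x$scar_feature_ids),
    pct_scar = 100 * length(x$scar_feature_ids) / nrow(x$features)
  )
}
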