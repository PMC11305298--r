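#' Per-gene percent improvement (normalization) of the disease signature
#'
#' For each signature gene, arm and follow-up week, computes
#' `PI = -100 * T_g / D_g`, where `T_g` is the mean log2 treatment change
#' (lesional at week t minus lesional at week 0) across the arm's patients
#' with both biopsies and `D_g` is the arm's mean baseline disease delta
#' (lesional minus nonlesional at week 0) across its complete pairs.
#' 100 means the disease effect is fully normalized; values above 100
#' (overshoot) and below 0 are valid. Genes whose arm-level |D_g| falls
#' below `stability_floor` are flagged `unstable` and get `NA` improvement
#' to prevent ratio blow-up.
#'
#' @param expr expression matrix or data frame (log2).
#' @param annot sample annotation.
#' @param signature a [select_signature()] object (or a data frame with a
#'   `feature_id` column).
#' @param arms treatment arms to evaluate (default: all non-control arms
#'   present).
#' @param weeks follow-up weeks to evaluate (default: all weeks > 0
#'   present for each arm).
#' @param stability_floor minimum |D_g| (log2) for a stable ratio.
#' @return tibble of improvement records: `feature_id`, `arm`, `week`,
#'   `treatment_delta`, `disease_delta`, `pi_percent`, `unstable`,
#'   `n_patients`.
#' @export
gene_improvement <- function(expr, annot, signature, arms = NULL, weeks = NULL,
                             stability_floor = 0.1) {
  X <- as_expression_matrix(expr)
  annot <- validate_annotation(annot)
  feats <- signature_feature_ids(signature)
  feats <- feats[feats %in% rownames(X)]
  if (!length(feats)) stop_insufficient("no signature features present in the expression matrix")

  arms_req <- arms %||% setdiff(unique(annot$arm), "HC")
  explicit_weeks <- !is.null(weeks)

  out <- list()
  for (arm in arms_req) {
    arm_annot <- annot[annot$arm == arm, , drop = FALSE]
    pairs <- baseline_pairs(arm_annot)
    if (!nrow(pairs)) stop_insufficient(paste0("arm ", arm, " has no complete week-0 LS/NL pair"))
    Dmat <- expr_cols(X, pairs$ls_sample)[feats, , drop = FALSE] -
      expr_cols(X, pairs$nl_sample)[feats, , drop = FALSE]
    D <- rowMeans(Dmat)

    wk_avail <- sort(unique(arm_annot$week[arm_annot$tissue == "LS" & arm_annot$week > 0]))
    wk_req <- weeks %||% wk_avail
    for (w in wk_req) {
      ls_t <- arm_annot[arm_annot$tissue == "LS" & arm_annot$week == w, ]
      ls_0 <- arm_annot[arm_annot$tissue == "LS" & arm_annot$week == 0, ]
      both <- intersect(ls_t$patient_id, ls_0$patient_id)
      if (!length(both)) {
        if (explicit_weeks) {
          stop_insufficient(paste0("no patient in arm ", arm,
                                   " has LS biopsies at both week 0 and week ", w))
        }
        next
      }
      t_ids <- ls_t$sample_id[match(both, ls_t$patient_id)]
      b_ids <- ls_0$sample_id[match(both, ls_0$patient_id)]
      Tg <- rowMeans(expr_cols(X, t_ids)[feats, , drop = FALSE] -
                     expr_cols(X, b_ids)[feats, , drop = FALSE])
      unstable <- abs(D) < stability_floor
      pi <- ifelse(unstable, NA_real_, -100 * Tg / D)
      out[[length(out) + 1]] <- tibble(
        feature_id = feats, arm = arm, week = w,
        treatment_delta = unname(Tg), disease_delta = unname(D),
        pi_percent = unname(pi), unstable = unname(unstable),
        n_patients = length(both))
    }
  }
  if (!length(out)) stop_insufficient("no (arm, week) combination with eligible patients")
  dplyr::bind_rows(out)
}

signature_feature_ids <- function(signature) {
  if (inherits(signature, "disease_signature")) return(signature$features$feature_id)
  if (is.data.frame(signature) && "feature_id" %in% names(signature)) {
    return(as.character(signature$feature_id))
  }
  if (is.character(signature)) return(signature)
  stop_validation("`signature` must be a disease_signature, a data frame with feature_id, or a character vector")
}

signature_deltas <- function(signature) {
  if (inherits(signature, "disease_signature")) {
    return(stats::setNames(signature$features$disease_delta,
                           signature$features$feature_id))
  }
  if (is.data.frame(signature) && all(c("feature_id", "disease_delta") %in% names(signature))) {
    return(stats::setNames(signature$disease_delta, signature$feature_id))
  }
  stop_validation("`signature` must carry per-feature disease deltas")
}

#' Summarize percent improvement per arm and week
#'
#' Mean improvement over stable signature genes plus, for each threshold,
#' the percentage of signature genes strictly above it. Threshold
#' percentages are denominated by the full signature count (stable and
#' unstable), so on a common record set the above-90 percentage can never
#' exceed the above-75 percentage.
#'
#' @param records output of [gene_improvement()].
#' @param thresholds improvement thresholds (percent).
#' @return tibble per (arm, week): `mean_pi`, one `pct_above_<t>` column
#'   per threshold, `n_genes_used`, `n_signature`.
#' @export
improvement_summary <- function(records, thresholds = c(75, 90)) {
  if (!nrow(records)) stop_insufficient("no improvement records")
  records %>%
    dplyr::group_by(.data$arm, .data$week) %>%
    dplyr::group_modify(function(g, key) {
      stable <- !g$unstable & !is.na(g$pi_percent)
      if (!any(stable)) {
        stop_insufficient(paste0("all improvement records unstable for ",
                                 key$arm, " week ", key$week))
      }
      row <- tibble(mean_pi = mean(g$pi_percent[stable]))
      for (t in thresholds) {
        row[[paste0("pct_above_", t)]] <- 100 * sum(g$pi_percent[stable] > t) / nrow(g)
      }
      row$n_genes_used <- sum(stable)
      row$n_signature <- nrow(g)
      row
    }) %>%
    dplyr::ungroup()
}

#' Overlap of genes achieving an improvement threshold across arms
#'
#' For each week, forms the per-arm sets of stable signature genes with
#' improvement strictly above `threshold` and reports shared (all arms)
#' and arm-unique counts, as counts and as percentages of the signature.
#'
#' @param records output of [gene_improvement()] covering at least 2 arms.
#' @param threshold improvement threshold (percent).
#' @return tibble per (week, arm): `n_achieved`, `pct_achieved`,
#'   `n_unique`, `pct_unique`, `n_shared`, `pct_shared`; the achieved sets
#'   are attached as the `sets` attribute (a list keyed by week).
#' @export
improvement_overlap <- function(records, threshold = 75) {
  arms <- unique(records$arm)
  if (length(arms) < 2) stop_insufficient("overlap needs records from at least 2 arms")
  n_signature <- dplyr::n_distinct(records$feature_id)
  sets_by_week <- list()
  out <- list()
  for (w in sort(unique(records$week))) {
    rw <- records[records$week == w, ]
    if (!all(arms %in% rw$arm)) {
      missing <- setdiff(arms, unique(rw$arm))
      stop_insufficient(paste0("arm(s) without records at week ", w, ": ",
                               paste(missing, collapse = ", ")))
    }
    achieved <- purrr::map(stats::setNames(arms, arms), function(a) {
      g <- rw[rw$arm == a & !rw$unstable & !is.na(rw$pi_percent), ]
      g$feature_id[g$pi_percent > threshold]
    })
    shared <- Reduce(intersect, achieved)
    sets_by_week[[as.character(w)]] <- achieved
    for (a in arms) {
      others <- unlist(achieved[setdiff(arms, a)], use.names = FALSE)
      uniq <- setdiff(achieved[[a]], others)
      out[[length(out) + 1]] <- tibble(
        week = w, arm = a, threshold = threshold,
        n_achieved = length(achieved[[a]]),
        pct_achieved = 100 * length(achieved[[a]]) / n_signature,
        n_unique = length(uniq),
        pct_unique = 100 * length(uniq) / n_signature,
        n_shared = length(shared),
        pct_shared = 100 * length(shared) / n_signature)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "sets") <- sets_by_week
  attr(res, "n_signature") <- n_signature
  res
}

#' Per-biopsy improvement score by projection onto the disease signature
#'
#' Scores each follow-up lesional biopsy by projecting its log2 change
#' from the patient's baseline lesional biopsy onto the signature's
#' disease deltas:
#' `score = 100 * (-sum(dx_g * D_g) / sum(D_g^2))` over stable signature
#' genes. A biopsy whose change exactly cancels the disease effect scores
#' 100. Samples without a baseline biopsy are skipped with a warning.
#' This per-sample definition is this package's choice of a sample-level
#' analogue of the per-gene statistic (a published per-biopsy definition
#' does not exist); outputs are labelled accordingly.
#'
#' @inheritParams gene_improvement
#' @return tibble: `sample_id`, `patient_id`, `arm`, `week`,
#'   `improvement_score`.
#' @export
sample_improvement <- function(expr, annot, signature, stability_floor = 0.1) {
  X <- as_expression_matrix(expr)
  annot <- validate_annotation(annot)
  D <- signature_deltas(signature)
  D <- D[names(D) %in% rownames(X)]
  D <- D[abs(D) >= stability_floor]
  if (!length(D)) stop_insufficient("no stable signature features available")
  d2 <- sum(D^2)

  follow <- annot[annot$tissue == "LS" & annot$week > 0, ]
  base <- annot[annot$tissue == "LS" & annot$week == 0, ]
  base_ids <- stats::setNames(base$sample_id, base$patient_id)

  has_base <- follow$patient_id %in% names(base_ids)
  if (any(!has_base)) {
    warn(paste0("skipping ", sum(!has_base),
                " sample(s) without a week-0 lesional biopsy"))
  }
  follow <- follow[has_base, ]
  if (!nrow(follow)) stop_insufficient("no follow-up biopsies with baseline available")

  dx <- X[names(D), follow$sample_id, drop = FALSE] -
    X[names(D), base_ids[follow$patient_id], drop = FALSE]
  score <- -100 * colSums(dx * D) / d2
  tibble(
    sample_id = follow$sample_id,
    patient_id = follow$patient_id,
    arm = follow$arm,
    week = follow$week,
    improvement_score = unname(score)
  )
}

#' Correlate transcriptomic and clinical (PASI) improvement
#'
#' Pearson correlation with a two-sided p-value between per-biopsy
#' transcriptomic improvement scores and the corresponding PASI percent
#' improvements.
#'
#' @param scores numeric vector of transcriptomic improvement scores, or a
#'   data frame with columns `improvement_score` and `pasi_improvement`.
#' @param pasi_improvements numeric vector matched to `scores` (ignored if
#'   `scores` is a data frame).
#' @return one-row tibble: `pearson_r`, `p_value`, `n`.
#' @export
correlate_with_clinical <- function(scores, pasi_improvements = NULL) {
  if (is.data.frame(scores)) {
    if (!all(c("improvement_score", "pasi_improvement") %in% names(scores))) {
      stop_validation("data frame input needs columns improvement_score and pasi_improvement")
    }
    x <- scores$improvement_score
    y <- scores$pasi_improvement
  } else {
    x <- scores
    y <- pasi_improvements
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_insufficient("need at least 3 paired observations")
  ct <- stats::cor.test(x, y)
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' PASI percent improvement per follow-up lesional biopsy
#'
#' Computes `100 * (pasi_week0 - pasi_week_t) / pasi_week0` for every
#' lesional biopsy after baseline, using the patient's week-0 lesional
#' PASI as reference.
#'
#' @param annot sample annotation with a `pasi` column.
#' @return tibble: `sample_id`, `patient_id`, `arm`, `week`,
#'   `pasi_improvement`.
#' @export
pasi_improvement <- function(annot) {
  annot <- validate_annotation(annot)
  base <- annot[annot$tissue == "LS" & annot$week == 0, ]
  p0 <- stats::setNames(base$pasi, base$patient_id)
  follow <- annot[annot$tissue == "LS" & annot$week > 0, ]
  follow <- follow[follow$patient_id %in% names(p0), ]
  tibble(
    sample_id = follow$sample_id,
    patient_id = follow$patient_id,
    arm = follow$arm,
    week = follow$week,
    pasi_improvement = unname(100 * (p0[follow$patient_id] - follow$pasi) / p0[follow$patient_id])
  )
}
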