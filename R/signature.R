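#' Paired lesional vs nonlesional differential expression at baseline
#'
#' For every feature, computes the mean paired log2 difference between
#' lesional and nonlesional biopsies at week 0 across patients with a
#' complete pair, a two-sided paired t-test (Student t with n - 1 degrees
#' of freedom), the signed linear fold change, and Benjamini-Hochberg
#' adjusted q-values. Patients missing either biopsy are excluded from
#' every feature's test.
#'
#' Zero-variance conventions: if all paired differences are exactly zero
#' the test reports t = 0, p = 1; if they are identical but nonzero, p = 0
#' with `degenerate = TRUE`.
#'
#' @param expr expression matrix or data frame (log2; features x samples).
#' @param annot sample annotation (see [validate_annotation()]).
#' @return tibble with one row per feature: `feature_id`, `n_pairs`,
#'   `mean_paired_delta`, `fold_change`, `t_statistic`, `p_value`,
#'   `q_value`, `degenerate`.
#' @export
#' @seealso [select_signature()], [compare_signatures()]
paired_lesional_de <- function(expr, annot) {
  X <- as_expression_matrix(expr)
  annot <- validate_annotation(annot)
  pairs <- baseline_pairs(annot)
  pairs <- pairs[pairs$ls_sample %in% colnames(X) & pairs$nl_sample %in% colnames(X), ]
  if (nrow(pairs) < 2) {
    stop_insufficient("need at least 2 patients with complete week-0 LS/NL pairs")
  }
  delta <- expr_cols(X, pairs$ls_sample) - expr_cols(X, pairs$nl_sample)
  st <- row_paired_t(delta)
  tibble(
    feature_id = rownames(X),
    n_pairs = st$n_pairs,
    mean_paired_delta = st$mean_delta,
    fold_change = signed_fold(st$mean_delta),
    t_statistic = st$t_statistic,
    p_value = st$p_value,
    q_value = bh_adjust(st$p_value),
    degenerate = st$degenerate
  )
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up false discovery rate adjustment with monotonicity
#' enforcement; output order matches input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop_validation("p-values must be numeric")
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) stop_validation("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select the disease signature from paired differential expression
#'
#' Keeps features with |fold change| strictly greater than `fc_min` and
#' q-value strictly below `fdr_max` (the published selection rule uses
#' FC > 1.5 and FDR < 0.05 to compensate for the compressed dynamic range
#' of perfect-match-only arrays).
#'
#' @param stats output of [paired_lesional_de()].
#' @param fc_min minimum absolute signed fold change (exclusive).
#' @param fdr_max maximum q-value (exclusive).
#' @return a `disease_signature` object: selected features with their
#'   disease deltas and the thresholds used.
#' @export
select_signature <- function(stats, fc_min = 1.5, fdr_max = 0.05) {
  if (!nrow(stats)) stop_validation("`stats` is empty")
  keep <- abs(stats$fold_change) > fc_min & stats$q_value < fdr_max &
    stats$mean_paired_delta != 0
  features <- tibble(
    feature_id = stats$feature_id[keep],
    disease_delta = stats$mean_paired_delta[keep]
  )
  structure(
    list(features = features, fc_min = fc_min, fdr_max = fdr_max),
    class = "disease_signature"
  )
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("<disease_signature> ", nrow(x$features), " features (|FC| > ",
      x$fc_min, ", FDR < ", x$fdr_max, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.disease_signature <- function(x, ...) x$features

#' @export
glance.disease_signature <- function(x, ...) {
  tibble(n_features = nrow(x$features), fc_min = x$fc_min, fdr_max = x$fdr_max)
}

#' Concordance between an observed and a reference disease signature
#'
#' Over features shared between `stats` and `reference`, reports the
#' fraction with the same (nonzero) direction of differential expression,
#' the Pearson correlation of the log2 deltas, and the ordinary
#' least-squares slope of the observed deltas on the reference deltas
#' (slopes below 1 indicate a compressed dynamic range).
#'
#' @param stats output of [paired_lesional_de()].
#' @param reference data frame with columns `feature_id` and `log2_delta`,
#'   or a named numeric vector of reference log2 deltas.
#' @return one-row tibble: `n_compared`, `agreement_fraction`, `pearson_r`,
#'   `regression_slope`.
#' @export
compare_signatures <- function(stats, reference) {
  if (is.numeric(reference) && !is.null(names(reference))) {
    reference <- tibble(feature_id = names(reference), log2_delta = unname(reference))
  }
  if (!all(c("feature_id", "log2_delta") %in% names(reference))) {
    stop_validation("`reference` needs columns feature_id and log2_delta")
  }
  shared <- dplyr::inner_join(
    stats[, c("feature_id", "mean_paired_delta")],
    as_tibble(reference)[, c("feature_id", "log2_delta")],
    by = "feature_id")
  if (nrow(shared) < 3) stop_insufficient("fewer than 3 shared features")
  obs <- shared$mean_paired_delta
  ref <- shared$log2_delta
  tibble(
    n_compared = nrow(shared),
    agreement_fraction = mean(obs * ref > 0),
    pearson_r = stats::cor(ref, obs),
    regression_slope = stats::cov(ref, obs) / stats::var(ref)
  )
}
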