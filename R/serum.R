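#' Geometric mean of positive concentrations
#'
#' @param values positive numeric vector.
#' @return exp of the mean log value.
#' @export
#' @examples
#' geometric_mean(c(2, 8)) # 4
geometric_mean <- function(values) {
  if (!length(values)) stop_validation("no values supplied")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_validation("geometric mean requires positive finite values")
  }
  exp(mean(log(values)))
}

#' Apply a lower-limit-of-quantification policy to a serum panel
#'
#' Records flagged `below_lloq` are imputed at half the analyte's LLOQ
#' (`"half"`, default), at the LLOQ itself (`"floor"`), or removed
#' (`"exclude"`).
#'
#' @param panel long serum tibble with `concentration`, `below_lloq` and
#'   `lloq` columns.
#' @param policy one of `"half"`, `"floor"`, `"exclude"`.
#' @return the panel with the policy applied.
#' @export
apply_lloq_policy <- function(panel, policy = c("half", "floor", "exclude")) {
  policy <- match.arg(policy)
  if (!all(c("concentration", "below_lloq") %in% names(panel))) {
    stop_validation("panel needs concentration and below_lloq columns")
  }
  flagged <- panel$below_lloq %in% TRUE
  if (!any(flagged)) return(panel)
  if (is.null(panel[["lloq"]])) stop_validation("panel needs an lloq column to impute")
  if (policy == "exclude") return(panel[!flagged, , drop = FALSE])
  repl <- if (policy == "half") panel$lloq[flagged] / 2 else panel$lloq[flagged]
  panel$concentration[flagged] <- repl
  panel
}

# Welch two-sample t on log2 values with zero-variance conventions
welch_log2 <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop_insufficient("each group needs at least 2 subjects")
  est <- mean(x) - mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(list(estimate = est, se = 0,
                statistic = if (est == 0) 0 else sign(est) * Inf,
                df = length(x) + length(y) - 2,
                p.value = if (est == 0) 1 else 0))
  }
  tt <- stats::t.test(x, y)
  list(estimate = est, se = tt$stderr, statistic = unname(tt$statistic),
       df = unname(tt$parameter), p.value = tt$p.value)
}

serum_checks <- function(panel) {
  need <- c("subject_id", "group", "week", "analyte", "concentration")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop_validation(paste0("serum panel missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(panel$concentration <= 0)) stop_validation("concentrations must be positive")
  as_tibble(panel)
}

#' Baseline case-control contrasts for serum analytes
#'
#' Per analyte, compares all psoriasis patients (every non-HC group) with
#' healthy controls at week 0: fold change as the ratio of geometric means,
#' a Welch t-test on log2 concentrations (Welch-Satterthwaite degrees of
#' freedom), and Benjamini-Hochberg q-values across the analytes tested.
#'
#' @param panel long serum tibble (`subject_id`, `group`, `week`,
#'   `analyte`, `concentration`, optional `below_lloq`/`lloq`).
#' @param analytes analytes to test (default: all present).
#' @param lloq_policy handling of below-LLOQ records, see
#'   [apply_lloq_policy()].
#' @return tibble per analyte: `analyte`, `comparison`, `estimate` (log2),
#'   `fold_change`, `gm_case`, `gm_control`, `standard_error`,
#'   `t_statistic`, `df`, `p_value`, `q_value`.
#' @export
baseline_case_control <- function(panel, analytes = NULL, lloq_policy = "half") {
  panel <- serum_checks(panel)
  if ("below_lloq" %in% names(panel)) panel <- apply_lloq_policy(panel, lloq_policy)
  base <- panel[panel$week == 0, , drop = FALSE]
  analytes <- analytes %||% unique(base$analyte)
  rows <- purrr::map(analytes, function(a) {
    d <- base[base$analyte == a, ]
    x <- log2(d$concentration[d$group != "HC"])
    y <- log2(d$concentration[d$group == "HC"])
    if (length(x) < 2 || length(y) < 2) {
      stop_insufficient(paste0("analyte ", a, ": each group needs at least 2 subjects"))
    }
    wt <- welch_log2(x, y)
    tibble(
      analyte = a, comparison = "PsO vs HC",
      estimate = wt$estimate, fold_change = 2^wt$estimate,
      gm_case = 2^mean(x), gm_control = 2^mean(y),
      standard_error = wt$se, t_statistic = wt$statistic, df = wt$df,
      p_value = wt$p.value)
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- bh_adjust(res$p_value)
  res
}

#' Within-arm change from baseline for serum analytes
#'
#' Paired t-tests of log2 concentration at week t against baseline within
#' one treatment arm, per analyte; subjects missing either visit are
#' excluded. Benjamini-Hochberg adjustment spans all rows returned by the
#' call (one comparison family).
#'
#' @inheritParams baseline_case_control
#' @param arm treatment arm(s) to evaluate.
#' @param week follow-up week(s) (> 0).
#' @return tibble per (analyte, arm, week): `estimate` (mean paired log2
#'   change), `fold_change`, `t_statistic`, `df`, `n_pairs`, `p_value`,
#'   `q_value`, `degenerate`.
#' @export
within_arm_change <- function(panel, arm, week, analytes = NULL,
                              lloq_policy = "half") {
  panel <- serum_checks(panel)
  if ("below_lloq" %in% names(panel)) panel <- apply_lloq_policy(panel, lloq_policy)
  analytes <- analytes %||% unique(panel$analyte)
  combos <- tidyr::expand_grid(arm = arm, week = week, analyte = analytes)
  rows <- purrr::pmap(combos, function(arm, week, analyte) {
    if (week == 0) stop_validation("follow-up week must be > 0")
    d <- panel[panel$group == arm & panel$analyte == analyte, ]
    w0 <- d[d$week == 0, ]
    wt <- d[d$week == week, ]
    both <- intersect(w0$subject_id, wt$subject_id)
    if (length(both) < 2) {
      stop_insufficient(paste0(analyte, " / ", arm, " week ", week,
                               ": fewer than 2 complete pairs"))
    }
    diffs <- log2(wt$concentration[match(both, wt$subject_id)]) -
      log2(w0$concentration[match(both, w0$subject_id)])
    st <- row_paired_t(matrix(diffs, nrow = 1))
    tibble(
      analyte = analyte, arm = arm, week = week,
      comparison = paste0("week ", week, " vs baseline"),
      estimate = st$mean_delta, fold_change = 2^st$mean_delta,
      t_statistic = st$t_statistic, df = length(both) - 1,
      n_pairs = length(both), p_value = st$p_value,
      degenerate = st$degenerate)
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- bh_adjust(res$p_value)
  res
}

#' Between-arm contrast at a visit, adjusted for baseline (ANCOVA)
#'
#' Per analyte, fits `log2(conc at week t) ~ arm + log2(conc at baseline)`
#' by least squares over subjects of the two arms with both visits. The
#' reported contrast is the adjusted difference (`arm_a` minus `arm_b`);
#' adjusted group means (emmeans) are evaluated at the pooled baseline
#' mean. Benjamini-Hochberg q-values span the analytes tested.
#'
#' @inheritParams baseline_case_control
#' @param week follow-up week (> 0).
#' @param arm_a,arm_b the two arms contrasted.
#' @return tibble per analyte: `estimate` (log2, arm_a - arm_b),
#'   `fold_change`, `standard_error`, `df`, `emmean_a`, `emmean_b`,
#'   `t_statistic`, `p_value`, `q_value`.
#' @export
between_arm_ancova <- function(panel, week, arm_a = "GUS", arm_b = "ADA",
                               analytes = NULL, lloq_policy = "half") {
  panel <- serum_checks(panel)
  if ("below_lloq" %in% names(panel)) panel <- apply_lloq_policy(panel, lloq_policy)
  if (week == 0) stop_validation("follow-up week must be > 0")
  analytes <- analytes %||% unique(panel$analyte)
  rows <- purrr::map(analytes, function(a) {
    d <- panel[panel$analyte == a & panel$group %in% c(arm_a, arm_b), ]
    wide <- tidyr::pivot_wider(
      d[d$week %in% c(0, week), c("subject_id", "group", "week", "concentration")],
      names_from = "week", values_from = "concentration")
    wide <- wide[stats::complete.cases(wide), ]
    if (sum(wide$group == arm_a) < 2 || sum(wide$group == arm_b) < 2) {
      stop_insufficient(paste0("analyte ", a, ": each arm needs at least 2 subjects with both visits"))
    }
    y <- log2(wide[[as.character(week)]])
    x0 <- log2(wide[["0"]])
    g <- factor(wide$group, levels = c(arm_b, arm_a))
    fit <- stats::lm(y ~ g + x0)
    cf <- stats::coef(fit)
    if (anyNA(cf)) stop_validation(paste0("analyte ", a, ": rank-deficient ANCOVA design"))
    est <- unname(cf[2])
    se <- sqrt(stats::vcov(fit)[2, 2])
    dfree <- fit$df.residual
    tval <- est / se
    x0m <- mean(x0)
    tibble(
      analyte = a, week = week,
      comparison = paste(arm_a, "-", arm_b),
      estimate = est, fold_change = 2^est,
      standard_error = se, df = dfree,
      emmean_a = unname(cf[1] + cf[2] + cf[3] * x0m),
      emmean_b = unname(cf[1] + cf[3] * x0m),
      t_statistic = tval,
      p_value = 2 * stats::pt(-abs(tval), dfree))
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- bh_adjust(res$p_value)
  res
}
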