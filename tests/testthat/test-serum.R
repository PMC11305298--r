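test_that("geometric mean and the printed fold-change identity", {
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_equal(geometric_mean(5), 5)
  expect_error(geometric_mean(c(1, -1)), class = "psopd_error_validation")
  expect_error(geometric_mean(numeric()), class = "psopd_error_validation")
  expect_equal(fold_change_from_geometric_means(4.99, 1.59), 4.99 / 1.59)
  expect_error(fold_change_from_geometric_means(1, 0),
               class = "psopd_error_validation")
})

test_that("LLOQ policies impute or exclude flagged records", {
  panel <- tibble::tibble(
    subject_id = c("a", "b"), group = "GUS", week = 0, analyte = "IL-17A",
    concentration = c(0.01, 5), below_lloq = c(TRUE, FALSE), lloq = 0.034)
  half <- apply_lloq_policy(panel, "half")
  expect_equal(half$concentration, c(0.017, 5))
  floor <- apply_lloq_policy(panel, "floor")
  expect_equal(floor$concentration, c(0.034, 5))
  excl <- apply_lloq_policy(panel, "exclude")
  expect_equal(excl$subject_id, "b")
  expect_error(apply_lloq_policy(panel[, -6], "half"),
               class = "psopd_error_validation")
})

test_that("baseline case-control reproduces the Welch t hand example", {
  # log2 concentrations 1,2,3 vs 2,3,4: t = -sqrt(3/2), df = 4
  panel <- manual_serum_panel(case_log2 = c(1, 2, 3), hc_log2 = c(2, 3, 4))
  out <- baseline_case_control(panel)
  expect_equal(out$estimate, -1)
  expect_equal(out$fold_change, 0.5)
  expect_equal(out$t_statistic, -sqrt(1.5))
  expect_equal(out$df, 4)
  expect_equal(out$p_value, 2 * pt(-sqrt(1.5), 4))
  expect_equal(out$gm_case, 4)   # geometric mean of 2,4,8
  expect_equal(out$gm_control, 8)
})

test_that("case-control matches stats::t.test on random panels", {
  set.seed(61)
  case <- rnorm(15, 2, 1)
  hc <- rnorm(12, 1, 1.3)
  out <- baseline_case_control(manual_serum_panel(case, hc))
  tt <- t.test(case, hc)
  expect_equal(out$t_statistic, unname(tt$statistic))
  expect_equal(out$df, unname(tt$parameter))
  expect_equal(out$p_value, tt$p.value)
  expect_equal(out$fold_change, out$gm_case / out$gm_control)
})

test_that("zero-variance serum groups follow the degenerate conventions", {
  same <- baseline_case_control(manual_serum_panel(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  apart <- baseline_case_control(manual_serum_panel(c(3, 3, 3), c(2, 2, 2)))
  expect_equal(apart$t_statistic, Inf)
  expect_equal(apart$p_value, 0)
})

test_that("within-arm change matches a paired t-test", {
  set.seed(62)
  n <- 10
  base <- rnorm(n, 3, 1)
  follow <- base + rnorm(n, -0.8, 0.4)
  panel <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:n), 2),
    group = "GUS",
    week = rep(c(0, 4), each = n),
    analyte = "IL-22",
    concentration = 2^c(base, follow))
  out <- within_arm_change(panel, arm = "GUS", week = 4)
  tt <- t.test(follow, base, paired = TRUE)
  expect_equal(out$estimate, unname(tt$estimate))
  expect_equal(out$t_statistic, unname(tt$statistic))
  expect_equal(out$p_value, tt$p.value)
  expect_equal(out$n_pairs, n)
  expect_equal(out$fold_change, 2^out$estimate)
})

test_that("within-arm change excludes incomplete subjects and validates weeks", {
  panel <- tibble::tibble(
    subject_id = c("a", "a", "b", "c", "c"),
    group = "ADA", week = c(0, 24, 0, 0, 24),
    analyte = "CCL22",
    concentration = 2^c(3, 2, 3, 5, 3))
  out <- within_arm_change(panel, arm = "ADA", week = 24)
  expect_equal(out$n_pairs, 2)  # subject b has no follow-up
  expect_equal(out$estimate, mean(c(2 - 3, 3 - 5)))
  expect_error(within_arm_change(panel, arm = "ADA", week = 0),
               class = "psopd_error_validation")
  expect_error(within_arm_change(panel, arm = "GUS", week = 24),
               class = "psopd_error_insufficient_data")
})

test_that("between-arm ANCOVA agrees with emmeans on the same model", {
  set.seed(63)
  n <- 16
  subj <- sprintf("S%02d", 1:(2 * n))
  grp <- rep(c("GUS", "ADA"), each = n)
  b <- rnorm(2 * n, 3, 0.8)
  y <- b + ifelse(grp == "GUS", -1.2, -0.5) + rnorm(2 * n, 0, 0.5)
  panel <- tibble::tibble(
    subject_id = rep(subj, 2), group = rep(grp, 2),
    week = rep(c(0, 24), each = 2 * n),
    analyte = "IL-17F", concentration = 2^c(b, y))
  out <- between_arm_ancova(panel, week = 24)

  dat <- data.frame(y = y, g = factor(grp, levels = c("ADA", "GUS")), x0 = b)
  fit <- lm(y ~ g + x0, data = dat)
  em <- emmeans::emmeans(fit, "g")
  ctr <- as.data.frame(emmeans::contrast(em, method = list(d = c(-1, 1))))
  expect_equal(out$estimate, ctr$estimate)
  expect_equal(out$standard_error, ctr$SE)
  expect_equal(out$df, ctr$df)
  expect_equal(out$p_value, ctr$p.value)
  emdf <- as.data.frame(em)
  expect_equal(out$emmean_a, emdf$emmean[emdf$g == "GUS"])
  expect_equal(out$emmean_b, emdf$emmean[emdf$g == "ADA"])
})

test_that("planted serum effects are recovered from the simulated cohort", {
  cfg <- cohort_config(seed = 71)
  sim <- simulate_serum_cohort(cfg)
  wc <- within_arm_change(sim$serum, arm = "GUS", week = 4,
                          analytes = "IL-17F")
  planted <- cfg$serum_effects$log2_change[
    cfg$serum_effects$analyte == "IL-17F" &
      cfg$serum_effects$arm == "GUS" & cfg$serum_effects$week == 4]
  # subject intercepts cancel in the paired change; residual sd 0.6 over
  # 40 pairs gives a standard error near 0.13, so 0.5 is a > 3.5-sigma band
  expect_lt(abs(wc$estimate - planted), 0.5)
  cc <- baseline_case_control(sim$serum, analytes = "IL-17F")
  expect_lt(abs(cc$estimate - sim$truth$case_control_log2_ratio[["IL-17F"]]),
            0.75)
})

test_that("BH families span exactly the analytes of one call", {
  set.seed(64)
  panels <- lapply(c("A1", "A2", "A3"), function(a) {
    manual_serum_panel(rnorm(8, 2), rnorm(8, 2), analyte = a)
  })
  panel <- dplyr::bind_rows(panels)
  out <- baseline_case_control(panel)
  expect_equal(out$q_value, p.adjust(out$p_value, "BH"))
  one <- baseline_case_control(panel, analytes = "A2")
  expect_equal(one$q_value, one$p_value)
})

test_that("serum panels are validated on ingestion", {
  bad <- tibble::tibble(subject_id = "a", group = "GUS", week = 0,
                        analyte = "IL-17A", concentration = -1)
  expect_error(baseline_case_control(bad), class = "psopd_error_validation")
  expect_error(baseline_case_control(bad[, -5]),
               class = "psopd_error_validation")
})
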