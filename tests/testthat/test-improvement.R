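test_that("gene improvement reproduces hand-computed values on a noise-free fixture", {
  fx <- manual_improvement_fixture()
  rec <- gene_improvement(fx$expr, fx$annot, fx$signature)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$pi_percent[rec$feature_id == "GA"], 50)
  expect_equal(rec$pi_percent[rec$feature_id == "GB"], 100)
  expect_true(rec$unstable[rec$feature_id == "GC"])
  expect_true(is.na(rec$pi_percent[rec$feature_id == "GC"]))
  expect_equal(unique(rec$n_patients), 2)
  expect_equal(rec$disease_delta[rec$feature_id == "GA"], 2)
  expect_equal(rec$treatment_delta[rec$feature_id == "GB"], -2)
})

test_that("percent improvement is invariant to rescaling the log2 matrix", {
  fx <- manual_improvement_fixture()
  a <- gene_improvement(fx$expr, fx$annot, fx$signature)
  b <- gene_improvement(3 * fx$expr, fx$annot, fx$signature,
                        stability_floor = 0.3)
  expect_equal(a$pi_percent[1:2], b$pi_percent[1:2])
})

test_that("improvement summary denominates thresholds by the full signature", {
  fx <- manual_improvement_fixture()
  rec <- gene_improvement(fx$expr, fx$annot, fx$signature)
  s <- improvement_summary(rec)
  expect_equal(s$mean_pi, 75)          # mean of 50 and 100 over stable genes
  expect_equal(s$pct_above_75, 100 / 3)  # only GB, out of 3 signature genes
  expect_equal(s$pct_above_90, 100 / 3)
  expect_equal(s$n_genes_used, 2)
  expect_equal(s$n_signature, 3)
  s2 <- improvement_summary(rec, thresholds = c(40, 60))
  expect_equal(s2$pct_above_40, 200 / 3)
})

test_that("requesting an impossible week errors; default mode skips it", {
  fx <- manual_improvement_fixture()
  expect_error(gene_improvement(fx$expr, fx$annot, fx$signature, weeks = 24),
               class = "psopd_error_insufficient_data")
  rec <- gene_improvement(fx$expr, fx$annot, fx$signature)
  expect_equal(unique(rec$week), 4)
})

test_that("overshoot above 100 percent is reported uncapped", {
  fx <- manual_improvement_fixture()
  X <- fx$expr
  X["GA", c("P1_LS4", "P2_LS4")] <- 4.5   # delta -2.5 on D = 2 -> PI 125
  rec <- gene_improvement(X, fx$annot, fx$signature)
  expect_equal(rec$pi_percent[rec$feature_id == "GA"], 125)
})

test_that("improvement recovery on a simulated cohort tracks the planted fractions", {
  co <- cached_small_cohort()
  sig <- select_signature(paired_lesional_de(co$expr, co$annot))
  rec <- gene_improvement(co$expr, co$annot, sig)
  s <- improvement_summary(rec)
  planted <- co$truth$normalization_fraction
  merged <- merge(s, planted, by = c("arm", "week"))
  expect_equal(nrow(merged), nrow(s))
  # loose per-cohort check; the tight distributional claim lives in the
  # acceptance suite with replicates
  expect_true(all(abs(merged$mean_pi - 100 * merged$f) < 15))
})

test_that("improvement overlap set arithmetic is exact on constructed records", {
  rec <- tibble::tibble(
    feature_id = rep(c("g1", "g2", "g3", "g4"), 2),
    arm = rep(c("GUS", "ADA"), each = 4),
    week = 24,
    treatment_delta = -1, disease_delta = 2,
    pi_percent = c(90, 80, 50, 95,   # GUS: g1, g2, g4 above 75
                   85, 60, 40, 92),  # ADA: g1, g4 above 75
    unstable = FALSE, n_patients = 5)
  ov <- improvement_overlap(rec, threshold = 75)
  gus <- ov[ov$arm == "GUS", ]
  ada <- ov[ov$arm == "ADA", ]
  expect_equal(gus$n_achieved, 3)
  expect_equal(ada$n_achieved, 2)
  expect_equal(gus$n_shared, 2)   # g1, g4
  expect_equal(ada$n_shared, 2)
  expect_equal(gus$n_unique, 1)   # g2
  expect_equal(ada$n_unique, 0)
  expect_equal(gus$pct_achieved, 75)
  sets <- attr(ov, "sets")[["24"]]
  expect_setequal(sets$GUS, c("g1", "g2", "g4"))
  expect_setequal(intersect(sets$GUS, sets$ADA), c("g1", "g4"))
})

test_that("overlap requires at least two arms and full week coverage", {
  rec <- tibble::tibble(feature_id = "g1", arm = "GUS", week = 4,
                        treatment_delta = -1, disease_delta = 2,
                        pi_percent = 80, unstable = FALSE, n_patients = 5)
  expect_error(improvement_overlap(rec),
               class = "psopd_error_insufficient_data")
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec, arm = "ADA", week = 24))
  expect_error(improvement_overlap(rec2),
               class = "psopd_error_insufficient_data")
})

test_that("sample improvement scores follow the projection definition", {
  fx <- manual_improvement_fixture()
  sig <- fx$signature[fx$signature$feature_id != "GC", ]
  sc <- sample_improvement(fx$expr, fx$annot, sig)
  # dx = (-1, -2), D = (2, 2): score = 100 * (1*2 + 2*2) / 8 = 75
  expect_equal(sc$improvement_score, c(75, 75))
  expect_equal(sc$week, c(4, 4))
})

test_that("sample improvement skips biopsies without a baseline, with a warning", {
  fx <- manual_improvement_fixture()
  annot <- dplyr::bind_rows(fx$annot, tibble::tibble(
    sample_id = "P3_LS4", patient_id = "P3", arm = "GUS", week = 4,
    tissue = "LS", pasi = 20))
  X <- cbind(fx$expr, P3_LS4 = c(5, 5, 5))
  sig <- fx$signature[fx$signature$feature_id != "GC", ]
  expect_warning(sc <- sample_improvement(X, annot, sig), "week-0")
  expect_false("P3_LS4" %in% sc$sample_id)
})

test_that("clinical correlation matches cor.test", {
  set.seed(31)
  x <- rnorm(20)
  y <- x + rnorm(20, 0, 0.5)
  out <- correlate_with_clinical(x, y)
  ct <- cor.test(x, y)
  expect_equal(out$pearson_r, unname(ct$estimate))
  expect_equal(out$p_value, ct$p.value)
  expect_equal(out$n, 20)
  expect_error(correlate_with_clinical(1:2, 1:2),
               class = "psopd_error_insufficient_data")
})

test_that("transcriptomic and PASI improvement correlate in the simulated cohort", {
  co <- cached_small_cohort()
  sig_truth <- tibble::tibble(feature_id = co$truth$signature_features,
                              disease_delta = unname(co$truth$disease_delta))
  sc <- sample_improvement(co$expr, co$annot, sig_truth)
  pi <- pasi_improvement(co$annot)
  joined <- merge(sc, pi, by = "sample_id")
  out <- correlate_with_clinical(joined$improvement_score,
                                 joined$pasi_improvement)
  expect_gt(out$pearson_r, 0.5)
  expect_lt(out$p_value, 0.01)
})

test_that("pasi_improvement computes percent change from the baseline PASI", {
  annot <- tibble::tibble(
    sample_id = c("b", "f1", "f2"), patient_id = "P1", arm = "GUS",
    week = c(0, 4, 24), tissue = "LS", pasi = c(20, 10, 0))
  out <- pasi_improvement(annot)
  expect_equal(out$pasi_improvement, c(50, 100))
})

test_that("molecular scar calls match the hand-built healed-skin fixture", {
  fx <- manual_scar_fixture()
  scar <- molecular_scar(fx$expr, fx$annot, fx$signature, arm = "GUS")
  expect_setequal(scar$scar_feature_ids, c("SA", "SD"))
  f <- scar$features
  expect_equal(f$pi_in_hls[f$feature_id == "SA"], 60)
  expect_equal(f$residual_fold_change[f$feature_id == "SA"], 2^0.8)
  expect_equal(f$pi_in_hls[f$feature_id == "SB"], 100)
  expect_false(f$in_scar[f$feature_id == "SB"])
  # SC has a residual of the wrong sign: must not count as scar
  expect_false(f$in_scar[f$feature_id == "SC"])
  expect_equal(f$pi_in_hls[f$feature_id == "SD"], 0)
  expect_equal(length(scar$healed_sample_ids), 2)
})

test_that("scar boundaries are strict at PI 75 and |FC| 1.5", {
  fx <- manual_scar_fixture()
  X <- fx$expr
  # residual exactly log2(1.5): |FC| not strictly above 1.5 -> excluded
  X["SA", c("P1_LS24", "P2_LS24")] <- 5 + log2(1.5)
  # PI exactly 75: treatment delta -1.5 on D = 2
  X["SD", c("P1_LS24", "P2_LS24")] <- 7 - 1.5
  scar <- molecular_scar(X, fx$annot, fx$signature, arm = "GUS")
  f <- scar$features
  expect_false(f$in_scar[f$feature_id == "SA"])
  expect_equal(f$pi_in_hls[f$feature_id == "SD"], 75)
  expect_false(f$in_scar[f$feature_id == "SD"])
})

test_that("molecular scar errors without healed biopsies", {
  fx <- manual_scar_fixture()
  annot <- fx$annot
  annot$pasi100 <- FALSE
  expect_error(molecular_scar(fx$expr, annot, fx$signature, arm = "GUS"),
               class = "psopd_error_insufficient_data")
  expect_error(molecular_scar(fx$expr, fx$annot, fx$signature, arm = "ADA"),
               class = "psopd_error_insufficient_data")
})

test_that("scar_result methods expose the call summary", {
  fx <- manual_scar_fixture()
  scar <- molecular_scar(fx$expr, fx$annot, fx$signature, arm = "GUS")
  expect_output(print(scar), "2 of 4 signature genes")
  expect_equal(nrow(tidy(scar)), 4)
  g <- glance(scar)
  expect_equal(g$n_scar, 2)
  expect_equal(g$pct_scar, 50)
  expect_equal(g$n_healed_samples, 2)
})

test_that("simulated scar genes are found among the planted signature", {
  co <- cached_small_cohort()
  sig_truth <- tibble::tibble(feature_id = co$truth$signature_features,
                              disease_delta = unname(co$truth$disease_delta))
  healed <- co$annot[co$annot$arm == "GUS" & co$annot$pasi100, ]
  expect_gte(nrow(healed), 1)  # the cached seed produces healed biopsies
  scar <- molecular_scar(co$expr, co$annot, sig_truth, arm = "GUS")
  expect_true(all(scar$scar_feature_ids %in% co$truth$signature_features))
  expect_gte(length(scar$scar_feature_ids), 1)
  expect_gt(mean(scar$scar_feature_ids %in% co$truth$scar_features), 0.5)
})
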