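test_that("paired differential expression matches stats::t.test gene by gene", {
  set.seed(11)
  n_pairs <- 7
  genes <- sprintf("g%02d", 1:10)
  ls <- matrix(rnorm(10 * n_pairs, 6, 1), 10,
               dimnames = list(genes, sprintf("P%d_LS", 1:n_pairs)))
  nl <- matrix(rnorm(10 * n_pairs, 6, 1), 10,
               dimnames = list(genes, sprintf("P%d_NL", 1:n_pairs)))
  X <- cbind(ls, nl)
  annot <- tibble::tibble(
    sample_id = colnames(X),
    patient_id = rep(sprintf("P%d", 1:n_pairs), 2),
    arm = "GUS", week = 0,
    tissue = rep(c("LS", "NL"), each = n_pairs),
    pasi = 20)
  de <- paired_lesional_de(X, annot)
  for (g in genes) {
    tt <- t.test(ls[g, ], nl[g, ], paired = TRUE)
    row <- de[de$feature_id == g, ]
    expect_equal(row$mean_paired_delta, unname(tt$estimate))
    expect_equal(row$t_statistic, unname(tt$statistic))
    expect_equal(row$p_value, tt$p.value)
    expect_equal(row$n_pairs, n_pairs)
  }
  expect_equal(de$q_value, p.adjust(de$p_value, "BH"))
  expect_equal(de$fold_change, signed_fold(de$mean_paired_delta))
})

test_that("hand-checked paired t: differences 1.9/2.0/2.1 give t = 20*sqrt(3)", {
  X <- rbind(g1 = c(6.9, 7.0, 7.1, 5, 5, 5))
  colnames(X) <- c("P1_LS", "P2_LS", "P3_LS", "P1_NL", "P2_NL", "P3_NL")
  annot <- tibble::tibble(
    sample_id = colnames(X), patient_id = rep(c("P1", "P2", "P3"), 2),
    arm = "ADA", week = 0, tissue = rep(c("LS", "NL"), each = 3), pasi = 20)
  de <- paired_lesional_de(X, annot)
  expect_equal(de$mean_paired_delta, 2)
  # t = mean / (sd/sqrt(n)) = 2 / (0.1/sqrt(3)) = 20*sqrt(3)
  expect_equal(de$t_statistic, 20 * sqrt(3))
  expect_equal(de$p_value, 2 * pt(-20 * sqrt(3), df = 2))
  expect_equal(de$fold_change, 4)
})

test_that("zero-variance conventions: flat and constant-shift genes", {
  X <- rbind(flat = c(5, 6, 5, 6),       # identical LS/NL per patient
             shift = c(7, 8, 5, 6))      # constant nonzero difference
  colnames(X) <- c("P1_LS", "P2_LS", "P1_NL", "P2_NL")
  annot <- tibble::tibble(
    sample_id = colnames(X), patient_id = rep(c("P1", "P2"), 2),
    arm = "GUS", week = 0, tissue = rep(c("LS", "NL"), each = 2), pasi = 20)
  de <- paired_lesional_de(X, annot)
  flat <- de[de$feature_id == "flat", ]
  expect_equal(flat$t_statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_false(flat$degenerate)
  shift <- de[de$feature_id == "shift", ]
  expect_equal(shift$t_statistic, Inf)
  expect_equal(shift$p_value, 0)
  expect_true(shift$degenerate)
})

test_that("bh_adjust matches the worked example and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(21)
  p <- runif(50)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})

test_that("bh_adjust is permutation-equivariant and order-preserving", {
  set.seed(22)
  p <- runif(30)
  perm <- sample(30)
  q <- bh_adjust(p)
  expect_equal(bh_adjust(p[perm]), q[perm])
  o <- order(p)
  expect_true(all(diff(q[o]) >= 0))
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
})

test_that("bh_adjust rejects p-values outside [0, 1]", {
  expect_error(bh_adjust(c(0.5, 1.2)), class = "psopd_error_validation")
  expect_error(bh_adjust(c(-0.1)), class = "psopd_error_validation")
  expect_error(bh_adjust("a"), class = "psopd_error_validation")
})

test_that("signature selection thresholds are strict", {
  stats_tbl <- tibble::tibble(
    feature_id = c("at_fc", "at_q", "in_both", "zero"),
    n_pairs = 10,
    mean_paired_delta = c(log2(1.5), 1, 1, 0),
    fold_change = c(1.5, 2, 2, 1),
    t_statistic = 5, p_value = 0.001,
    q_value = c(0.01, 0.05, 0.01, 0.01),
    degenerate = FALSE)
  sig <- select_signature(stats_tbl)
  expect_equal(sig$features$feature_id, "in_both")
  expect_equal(sig$features$disease_delta, 1)
})

test_that("disease_signature methods print, tidy and glance", {
  fx <- manual_improvement_fixture()
  sig <- structure(list(features = fx$signature, fc_min = 1.5, fdr_max = 0.05),
                   class = "disease_signature")
  expect_output(print(sig), "3 features")
  expect_equal(tidy(sig), fx$signature)
  g <- glance(sig)
  expect_equal(g$n_features, 3)
  expect_equal(g$fc_min, 1.5)
})

test_that("signature recovery on a simulated cohort is near-complete with few false picks", {
  co <- cached_small_cohort()
  sig <- select_signature(paired_lesional_de(co$expr, co$annot))
  found <- sig$features$feature_id
  truth <- co$truth$signature_features
  expect_gt(mean(truth %in% found), 0.95)
  # false discovery proportion bounded by the nominal FDR with slack
  expect_lt(mean(!found %in% truth), 0.10)
  # estimated effects carry the planted signs
  planted <- co$truth$disease_delta[found[found %in% truth]]
  est <- sig$features$disease_delta[match(names(planted), sig$features$feature_id)]
  expect_true(all(sign(est) == sign(planted)))
})

test_that("compare_signatures computes agreement, correlation and slope", {
  ref <- tibble::tibble(feature_id = sprintf("g%d", 1:6),
                        log2_delta = c(2, -2, 1, -1, 3, -3))
  stats_tbl <- tibble::tibble(feature_id = ref$feature_id,
                              mean_paired_delta = 0.5 * ref$log2_delta)
  cmp <- compare_signatures(stats_tbl, ref)
  expect_equal(cmp$n_compared, 6)
  expect_equal(cmp$agreement_fraction, 1)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$regression_slope, 0.5)
  # named-vector reference form agrees
  cmp2 <- compare_signatures(stats_tbl,
                             setNames(ref$log2_delta, ref$feature_id))
  expect_equal(cmp2, cmp)
})

test_that("compare_signatures needs at least 3 shared features", {
  ref <- tibble::tibble(feature_id = c("a", "b"), log2_delta = c(1, 2))
  stats_tbl <- tibble::tibble(feature_id = c("a", "b"),
                              mean_paired_delta = c(1, 2))
  expect_error(compare_signatures(stats_tbl, ref),
               class = "psopd_error_insufficient_data")
})

test_that("duplicate feature ids are rejected with the offending id", {
  X <- rbind(c(1, 2), c(3, 4))
  rownames(X) <- c("dupg", "dupg")
  colnames(X) <- c("s1", "s2")
  annot <- tibble::tibble(sample_id = c("s1", "s2"), patient_id = "P1",
                          arm = "GUS", week = 0, tissue = c("LS", "NL"),
                          pasi = 20)
  expect_error(paired_lesional_de(X, annot), regexp = "dupg",
               class = "psopd_error_validation")
})
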