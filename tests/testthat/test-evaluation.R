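test_that("aggregation averages slices to subjects to cohort, stratified by vendor", {
  rec <- metric_records(c("s1", "s1"), "A", "m_vs_3", "idp", 0, c(1, 2), c(0.2, 0.4))
  agg <- aggregate_records(rec)
  expect_equal(agg$subject$value, 0.3)

  rec2 <- metric_records(c("s1", "s2"), c("A", "B"), "m_vs_3", "idp", 0, 1,
                         c(0.3, 0.5))
  agg2 <- aggregate_records(rec2)
  expect_equal(agg2$cohort$value, 0.4)
  expect_equal(agg2$by_vendor$value[agg2$by_vendor$vendor == "A"], 0.3)
  expect_equal(agg2$by_vendor$value[agg2$by_vendor$vendor == "B"], 0.5)

  # slice order does not matter
  rec_shuf <- rec[c(2, 1), ]
  expect_equal(aggregate_records(rec_shuf)$subject$value, 0.3)

  mixed <- rbind(rec, metric_records("s1", "A", "m_vs_3", "psnr", NA, 1, 30))
  expect_error(aggregate_records(mixed), "mixed metrics")
})

test_that("pairwise comparison handles self-comparison and zero-variance shifts", {
  ra <- metric_records(c("s1", "s2", "s3"), "A", "m1", "idp", 0, 1, c(0.3, 0.4, 0.5))
  self <- compare_pairwise(ra, transform(ra, comparison = "m1b"))
  expect_equal(self$mean_difference, 0)
  expect_true(self$ci95[1] <= 0 && self$ci95[2] >= 0)
  expect_equal(self$p_value, 1)

  rb <- transform(ra, value = value - 0.1, comparison = "m2")
  shift <- compare_pairwise(ra, rb)
  expect_equal(shift$mean_difference, 0.1)
  expect_equal(shift$ci95, c(0.1, 0.1))
  expect_lt(shift$p_value, .Machine$double.xmin)

  rc <- metric_records(c("s8", "s9"), "A", "m3", "idp", 0, 1, c(0.1, 0.2))
  expect_error(compare_pairwise(ra, rc), "subject")
})

test_that("cluster-robust comparison agrees in sign and detects real shifts", {
  set.seed(42)
  subj <- rep(sprintf("s%02d", 1:10), each = 6)
  base <- rep(rnorm(10, 0.5, 0.05), each = 6)
  ra <- metric_records(subj, "A", "m1", "idp", 0, rep(1:6, 10),
                       base + 0.05 + rnorm(60, 0, 0.01))
  rb <- metric_records(subj, "A", "m2", "idp", 0, rep(1:6, 10),
                       base + rnorm(60, 0, 0.01))
  cr <- compare_pairwise(ra, rb, method = "cluster_robust")
  expect_equal(cr$mean_difference, 0.05, tolerance = 0.05)
  expect_lt(cr$p_value, 0.001)
  expect_true(cr$ci95[1] <= cr$mean_difference &&
                cr$mean_difference <= cr$ci95[2])
})

test_that("paired-comparison CIs and type-I error are calibrated", {
  # type I: two arms with identical construction, different draws
  set.seed(314)
  rejections <- 0; n_rep <- 200
  for (i in seq_len(n_rep)) {
    va <- rnorm(20, 0.5, 0.02); vb <- rnorm(20, 0.5, 0.02)
    ids <- sprintf("s%02d", 1:20)
    cmp <- compare_pairwise(metric_records(ids, "A", "x", "idp", 0, 1, va),
                            metric_records(ids, "A", "y", "idp", 0, 1, vb))
    if (cmp$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_rep, 0.01)
  expect_lt(rejections / n_rep, 0.10)
})

test_that("anchor analysis rewards only genuinely better methods", {
  set.seed(21)
  n <- 10
  ids <- sprintf("s%02d", 1:n)
  base_vals <- runif(n, 0.30, 0.34)
  rec <- rbind(
    metric_records(ids, "A", "orig1.5_vs_3", "idp", 0, 1, base_vals),
    metric_records(ids, "A", "good_vs_3", "idp", 0, 1, base_vals - 0.10),
    metric_records(ids, "A", "same_vs_3", "idp", 0, 1, base_vals),
    metric_records(ids, "A", "oracle_vs_3", "idp", 0, 1, rep(0, n)))
  rep_rec <- metric_records(rep(ids[1:4], each = 2), "A",
                            "repeat1.5_vs_repeat1.5", "idp", 0,
                            rep(1:2, 4), runif(8, 0.05, 0.07))
  rep_idp <- mean(sapply(ids[1:4], function(s)
    mean(rep_rec$value[rep_rec$subject_id == s])))
  ar <- anchor_analysis(rec, rep_rec, alpha = 0.001)
  v <- ar$verdicts
  expect_true(v$beats_baseline[v$comparison == "good_vs_3"])
  expect_true(v$beats_baseline[v$comparison == "oracle_vs_3"])
  expect_false(v$beats_baseline[v$comparison == "same_vs_3"])
  # oracle sits below the repeat floor by exactly the floor value
  expect_equal(v$gap_to_repeat_baseline[v$comparison == "oracle_vs_3"],
               -rep_idp)
  expect_true(v$below_repeat_floor[v$comparison == "oracle_vs_3"])
  expect_false(v$below_repeat_floor[v$comparison == "good_vs_3"])
  expect_error(anchor_analysis(rec[rec$comparison != "orig1.5_vs_3", ], rep_rec),
               "baseline")
})

test_that("repeat-noise-matched methods cannot beat the repeat floor by much", {
  # a stochastic candidate whose noise equals the repeat-scan noise has the
  # same expected IDP as the repeat pairs (up to Monte-Carlo error)
  h <- make_high_field_subject("f", 2, 64, "A", 31)
  p <- degradation_params(noise_sigma = 0.02, blur_fwhm_px = 1, seed = 4)
  low <- degrade_to_low_field(h, p)
  reps <- lapply(1:6, function(i)
    make_repeat_scan(low, repeat_seed = 3000 + i))
  rep_vals <- c(); cand_vals <- c()
  for (i in 1:3) {
    r1 <- reps[[2 * i - 1]]; r2 <- reps[[2 * i]]
    for (k in 1:2) {
      rep_vals <- c(rep_vals,
                    idp(quantized_pair(r1$slices[[k]], r2$slices[[k]]), 0)$idp)
      cand_vals <- c(cand_vals,
                     idp(quantized_pair(low$slices[[k]], r1$slices[[k]]), 0)$idp)
    }
  }
  se <- stats::sd(rep_vals) / sqrt(length(rep_vals)) +
    stats::sd(cand_vals) / sqrt(length(cand_vals))
  expect_gt(mean(cand_vals), mean(rep_vals) - 2 * max(se, 0.005))
})

test_that("method ranking orders by the metric's better direction with tie flags", {
  ids <- c("s1", "s2")
  rec <- rbind(
    metric_records(ids, "A", "oracle_vs_3", "idp", 0, 1, c(0, 0)),
    metric_records(ids, "A", "m1_vs_3", "idp", 0, 1, c(0.4, 0.4)),
    metric_records(ids, "A", "m2_vs_3", "idp", 0, 1, c(0.2, 0.2)))
  rk <- rank_methods(rec, "idp", 0)
  expect_equal(rk$comparison, c("oracle_vs_3", "m2_vs_3", "m1_vs_3"))
  expect_false(any(rk$tied))

  rec_psnr <- rbind(
    metric_records(ids, "A", "a_vs_3", "psnr", NA, 1, c(30, 30)),
    metric_records(ids, "A", "b_vs_3", "psnr", NA, 1, c(40, 40)),
    metric_records(ids, "A", "c_vs_3", "psnr", NA, 1, c(30, 30)))
  rk2 <- rank_methods(rec_psnr, "psnr")
  expect_equal(rk2$comparison[1], "b_vs_3")     # higher PSNR is better
  expect_true(all(rk2$tied[rk2$comparison %in% c("a_vs_3", "c_vs_3")]))
  expect_equal(rk2$comparison[2:3], c("a_vs_3", "c_vs_3"))  # alphabetical tie-break
  expect_error(rank_methods(rec, "volume"), "unknown metric")
  # subject order invariance
  rk3 <- rank_methods(rec[nrow(rec):1, ], "idp", 0)
  expect_equal(rk3$comparison, rk$comparison)
})
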