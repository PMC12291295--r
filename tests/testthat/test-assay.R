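test_that("a noiseless linear time course is recovered exactly", {
  est <- estimate_reactivation_rate(toy_timecourse(30))
  expect_equal(est$rate, 30, tolerance = 1e-9)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-9)
  expect_equal(est$n_points, 18)
  expect_false(est$baseline_subtracted)
})

test_that("a recorded blank baseline is subtracted without moving the slope", {
  plain <- estimate_reactivation_rate(toy_timecourse(30))
  shifted <- estimate_reactivation_rate(
    toy_timecourse(30, baseline_mg_l = 1, blank_mpa_mg_l = 1))
  expect_equal(shifted$rate, plain$rate, tolerance = 1e-9)
  expect_true(shifted$baseline_subtracted)
  # a blank baseline below the LLOQ is not subtracted
  sub_lloq <- estimate_reactivation_rate(
    toy_timecourse(30, baseline_mg_l = 0.2, blank_mpa_mg_l = 0.2))
  expect_false(sub_lloq$baseline_subtracted)
})

test_that("slope matches the closed-form normal-equation solution", {
  set.seed(42)
  tc <- simulate_assay_timecourse(25, "sample", cohort_design(seed = 1))
  est <- estimate_reactivation_rate(tc)
  o <- ols_oracle(tc$data$time_h, mg_per_l_to_um(tc$data$mpa_mg_l, "MPA"))
  expect_equal(est$rate, o$slope, tolerance = 1e-9)
  expect_equal(est$intercept, o$intercept, tolerance = 1e-9)
  expect_equal(est$stderr, o$se_slope, tolerance = 1e-9)
})

test_that("unit coherence: fitting in mg/L then converting equals fitting in uM", {
  set.seed(43)
  tc <- simulate_assay_timecourse(40, "sample", cohort_design(seed = 1))
  est <- estimate_reactivation_rate(tc)
  slope_mgl <- ols_oracle(tc$data$time_h, tc$data$mpa_mg_l)$slope
  expect_equal(mg_per_l_to_um(slope_mgl, "MPA"), est$rate,
               tolerance = 1e-9)
})

test_that("rate estimation is unbiased under multiplicative assay noise", {
  d <- cohort_design(baseline_contamination_prob = 0, seed = 1)
  set.seed(77)
  est <- replicate(1000, estimate_reactivation_rate(
    simulate_assay_timecourse(49.5, "sample", d),
    warn_depletion = FALSE)$rate)
  expect_lt(abs(mean(est) - 49.5), 1)
})

test_that("estimated rates track the cohort truth tightly", {
  d <- cohort_design(seed = 5)
  co <- simulate_cohort(d)
  set.seed(5)
  est <- vapply(seq_len(nrow(co)), function(i) {
    estimate_reactivation_rate(
      simulate_assay_timecourse(co[i, ], "sample", d),
      warn_depletion = FALSE)$rate
  }, numeric(1))
  expect_gt(cor(est, co$true_rate, method = "spearman"), 0.95)
})

test_that("LLOQ substitution counts and substitutes only positive sub-LLOQ values", {
  tc <- toy_timecourse(30)
  # push the first post-zero replicate below the LLOQ
  tc$data$mpa_mg_l[tc$data$time_h == 0.25] <- 0.1
  est <- estimate_reactivation_rate(tc)
  expect_equal(est$below_lloq_points, 3)
})

test_that("rate estimation rejects wrong kinds and degenerate grids", {
  neg <- toy_timecourse(0, kind = "negative_control")
  expect_error(estimate_reactivation_rate(neg), "kind")
  expect_error(toy_timecourse(10, times = c(0, 0)), "distinct")
})

test_that("control QC applies the +/-20% limits and the CV formula", {
  ref <- 35
  pos <- lapply(1:3, function(i) toy_timecourse(ref, kind = "positive_control",
                                                sample_id = paste0("p", i)))
  neg <- toy_timecourse(0, kind = "negative_control")
  qc <- qc_controls(neg, pos, ref)
  expect_equal(qc$cv_percent, 0)
  expect_true(all(qc$positive_pass))
  expect_true(qc$negative_pass)
  expect_equal(qc$lower, 0.8 * ref)
  expect_equal(qc$upper, 1.2 * ref)
  # one run at 1.3x the reference fails alone
  pos_bad <- c(pos[1:2], list(toy_timecourse(1.3 * ref,
                                             kind = "positive_control")))
  qc2 <- qc_controls(neg, pos_bad, ref)
  expect_equal(unname(qc2$positive_pass), c(TRUE, TRUE, FALSE))
  expect_error(qc_controls(neg, pos, -1), "reference_mean")
  expect_error(qc_controls(neg, pos[1], ref), "positive-control")
})

test_that("a hydrolysing negative control is caught", {
  neg <- toy_timecourse(5, kind = "negative_control")
  pos <- lapply(1:2, function(i) toy_timecourse(35, kind = "positive_control"))
  qc <- qc_controls(neg, pos, 35)
  expect_false(qc$negative_pass)
})

test_that("inhibition profiles classify the dose-response shape", {
  mk <- function(rate, conc) toy_timecourse(rate, amoxapine_mg_ml = conc,
                                            sample_id = paste0("c", conc))
  flat <- lapply(c(0, 0.1, 0.5), function(cc) mk(20, cc))
  expect_equal(attr(inhibition_profile(flat), "diagnostic"),
               "no inhibition")
  dec <- Map(mk, c(50, 30, 10, 2, 0), c(0, 0.1, 0.5, 2, 5))
  prof <- inhibition_profile(dec)
  expect_equal(attr(prof, "diagnostic"), "monotone non-increasing")
  expect_equal(prof$rate[1],
               estimate_reactivation_rate(dec[[1]])$rate)
  bump <- Map(mk, c(50, 10, 30), c(0, 0.1, 0.5))
  expect_equal(attr(inhibition_profile(bump), "diagnostic"), "non-monotone")
  expect_error(inhibition_profile(Map(mk, c(10, 20), c(0.5, 0.5))),
               "duplicate")
  expect_error(inhibition_profile(Map(mk, c(10, 20), c(0.1, 0.5))),
               "including 0")
})

test_that("4-MU activity follows the standard curve and is gain-invariant", {
  std <- data.frame(nmol = c(1, 2), rfu = c(100, 200))
  kin <- data.frame(time_min = c(0, 10, 20), rfu = c(0, 100, 200))
  expect_equal(as.numeric(gus_activity_4mu(kin, std)), 0.1)
  flat <- data.frame(time_min = c(0, 10, 20), rfu = c(50, 50, 50))
  expect_equal(as.numeric(gus_activity_4mu(flat, std)), 0)
  scale2 <- function(df) transform(df, rfu = 2 * rfu)
  expect_equal(as.numeric(gus_activity_4mu(scale2(kin), scale2(std))), 0.1)
  bad <- data.frame(nmol = c(1, 2), rfu = c(200, 100))
  expect_error(gus_activity_4mu(kin, bad), "standard-curve slope")
})

test_that("fold spread reproduces the cohort range arithmetic", {
  expect_equal(fold_range(c(6, 20, 86)), 86 / 6)
  expect_error(fold_range(c(0, 5)), "positive")
})
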