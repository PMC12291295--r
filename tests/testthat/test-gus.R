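toy_counts <- function(values, lengths, libs) {
  ids <- paste0("m", seq_len(nrow(values)))
  dimnames(values) <- list(ids, paste0("s", seq_len(ncol(values))))
  feature_table(values, "counts",
                setNames(libs, colnames(values)),
                data.frame(marker_id = ids, length_bp = lengths,
                           taxon = "t", stringsAsFactors = FALSE))
}

test_that("RPKM unit case, zero case and joint-scaling invariance", {
  ft <- toy_counts(matrix(c(1000, 0), 2, 1), c(1000L, 1500L), 1e6)
  r <- compute_rpkm(ft)
  expect_equal(unname(r$values[, 1]), c(1000, 0))
  ft2 <- toy_counts(matrix(c(2000, 0), 2, 1), c(1000L, 1500L), 2e6)
  expect_equal(compute_rpkm(ft2)$values, r$values)
})

test_that("prevalence filter keeps the inclusive boundary", {
  vals <- rbind(
    m_half = c(rep(1, 5), rep(0, 5)),   # 5/10 -> kept at 0.5
    m_four = c(rep(1, 4), rep(0, 6)),   # 4/10 -> dropped
    m_all = rep(2, 10),
    m_none = rep(0, 10),
    m_six = c(rep(3, 6), rep(0, 4)),
    m_one = c(1, rep(0, 9))
  )
  colnames(vals) <- paste0("s", 1:10)
  ft <- feature_table(vals, "rpkm")
  kept <- rownames(prevalence_filter(ft, 0.5)$values)
  expect_equal(kept, c("m_half", "m_all", "m_six"))
  expect_error(prevalence_filter(ft, 0), "min_fraction")
  expect_error(prevalence_filter(ft, 1.5), "min_fraction")
})

test_that("marker correlations match a brute-force rank oracle", {
  rates <- c(s1 = 6, s2 = 20, s3 = 35, s4 = 50, s5 = 70, s6 = 86)
  vals <- rbind(
    up = c(1, 2, 3, 4, 5, 6),
    down = c(6, 5, 4, 3, 2, 1),
    tied = c(1, 1, 2, 2, 3, 3),
    noise = c(4, 1, 5, 2, 6, 3)
  )
  colnames(vals) <- names(rates)
  ft <- feature_table(vals, "rpkm")
  res <- correlate_markers_with_rates(ft, rates)
  expect_equal(res$rho[res$marker_id == "up"], 1)
  expect_equal(res$rho[res$marker_id == "down"], -1)
  expect_equal(res$marker_id[1], "up")  # sorted by decreasing rho
  # brute-force oracle: Pearson correlation of average ranks
  rank_cor <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  for (m in rownames(vals)) {
    expect_equal(res$rho[res$marker_id == m], rank_cor(vals[m, ], rates),
                 tolerance = 1e-12)
  }
  # BH across the tested set matches the step-up definition
  expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)
  expect_error(correlate_markers_with_rates(ft, rates * 0 + 1),
               "constant rate")
})

test_that("Welch comparison of group totals matches the closed form", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                 dimnames = list("m1", paste0("s", 1:6)))
  ft <- feature_table(vals, "rpkm")
  groups <- setNames(rep(c("patient", "healthy"), each = 3),
                     paste0("s", 1:6))
  res <- compare_group_totals(ft, groups)
  # hand Welch: means 2 and 5, s^2 = 1 each, n = 3
  se <- sqrt(1 / 3 + 1 / 3)
  expect_equal(res$statistic, (2 - 5) / se, tolerance = 1e-12)
  expect_equal(res$df, se^4 / (2 * (1 / 3)^2 / 2), tolerance = 1e-12)
  # location invariance
  ft2 <- feature_table(vals + 100, "rpkm")
  expect_equal(compare_group_totals(ft2, groups)$statistic, res$statistic,
               tolerance = 1e-12)
})

test_that("the causal marker dominates the screen and inert abundance does not", {
  top <- character(10)
  for (s in 1:10) {
    d <- cohort_design(seed = 500 + s)
    d$groups <- data.frame(label = "week_3_6", n_subjects = 40L,
                           rate_mean = 49.5, rate_sd = 18.1)
    co <- simulate_cohort(d)
    ft <- simulate_gus_gene_table(co, seed = 600 + s)
    assoc <- correlate_markers_with_rates(
      prevalence_filter(compute_rpkm(ft)),
      setNames(co$true_rate, co$subject_id))
    top[s] <- assoc$marker_id[1]
    if (s == 1) {
      # the most abundant marker is inert: top of the abundance ranking,
      # absent from the top of the correlation ranking
      ab_top <- assoc$marker_id[which.max(assoc$mean_abundance)]
      expect_equal(ab_top, "FP_GUS_B1")
      expect_false(ab_top %in% assoc$marker_id[1:3])
    }
  }
  expect_gte(mean(top == "FP_GUS_A1"), 0.9)
})

test_that("an all-inert catalog yields a null screen", {
  cat0 <- default_gus_catalog()
  cat0$causal_weight[cat0$marker_id == "FP_GUS_A1"] <- 1e-9
  cat0$causal_weight[!cat0$marker_id == "FP_GUS_A1"] <- 0
  frac_sig <- vapply(1:5, function(s) {
    d <- cohort_design(seed = 700 + s)
    d$groups <- data.frame(label = "week_3_6", n_subjects = 40L,
                           rate_mean = 49.5, rate_sd = 18.1)
    co <- simulate_cohort(d)
    ft <- simulate_gus_gene_table(co, catalog = cat0, seed = 800 + s)
    assoc <- correlate_markers_with_rates(
      prevalence_filter(compute_rpkm(ft)),
      setNames(co$true_rate, co$subject_id))
    mean(assoc$q_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac_sig), 0.05)
})

test_that("gene-table simulation is deterministic and catalog-validated", {
  co <- simulate_cohort(cohort_design(seed = 2))
  a <- simulate_gus_gene_table(co, seed = 9)
  b <- simulate_gus_gene_table(co, seed = 9)
  expect_identical(a$values, b$values)
  expect_error(simulate_gus_gene_table(co, catalog = default_gus_catalog()[0, ],
                                       seed = 1),
               "non-empty")
})
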