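test_that("Shannon index matches closed forms and majorization", {
  expect_equal(shannon(rep(25, 4)), log(4))
  expect_equal(shannon(c(100, 0, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  # concentrating mass strictly decreases H
  expect_lt(shannon(c(0.7, 0.15, 0.15)), shannon(c(0.5, 0.25, 0.25)))
  expect_equal(shannon(rep(1, 8), base = 2), 3)
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches the definition formula", {
  m <- cbind(a = c(60, 30, 10), b = c(30, 30, 40), c = c(60, 30, 10),
             d = c(0, 0, 100))
  rownames(m) <- paste0("t", 1:3)
  bc <- bray_curtis(m)
  expect_equal(bc["a", "b"], (30 + 0 + 30) / 200)
  expect_equal(bc["a", "c"], 0)
  expect_equal(bc["b", "d"], (30 + 30 + 60) / 200)  # partial overlap
  disjoint <- cbind(x = c(50, 50, 0, 0), y = c(0, 0, 50, 50))
  rownames(disjoint) <- paste0("t", 1:4)
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)
  # formula oracle on random pairs + metric properties
  set.seed(1)
  r <- matrix(stats::runif(30), 5, 6,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
  bc2 <- bray_curtis(r)
  oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(bc2[i, j], oracle(r[, i], r[, j]), tolerance = 1e-12)
  }
  expect_equal(bc2, t(bc2))
  expect_true(all(diag(bc2) == 0))
  expect_true(all(bc2 >= 0 & bc2 <= 1))
  # invariance under joint rescaling of the abundances
  expect_equal(bray_curtis(7.3 * r), bc2, tolerance = 1e-12)
})

test_that("PERMANOVA separates groups and matches adonis2", {
  # perfect separation: R^2 = 1, p at the permutation floor
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- c("a", "a", "b", "b")
  all_perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  all_perms <- all_perms[apply(all_perms, 1,
                               function(p) length(unique(p)) == 4), ]
  res <- permanova(d, g, permutations = all_perms)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  # only the 3 distinct pairings of 4 samples exist; the observed split is
  # one of them, so the exhaustive p sits exactly at its floor of 1/3
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  # agreement with the reference implementation on a random instance
  set.seed(5)
  m <- matrix(stats::runif(60), 6, 10,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  m <- sweep(m, 2, colSums(m), "/") * 100
  bc <- bray_curtis(m)
  g2 <- rep(c("a", "b"), each = 5)
  mine <- permanova(bc, g2, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(bc) ~ g2, permutations = 99)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-9)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-9)
  # continuous covariate route also matches adonis2
  x <- stats::rnorm(10)
  mine_c <- permanova(bc, x, n_perm = 49, seed = 1)
  ref_c <- vegan::adonis2(stats::as.dist(bc) ~ x, permutations = 49)
  expect_equal(mine_c$statistic, ref_c$F[1], tolerance = 1e-9)
  expect_equal(mine_c$r_squared, ref_c$R2[1], tolerance = 1e-9)
  expect_error(permanova(bc, rep("a", 10)), "constant predictor")
})

test_that("PERMANOVA permutation p equals exhaustive enumeration at n = 6", {
  set.seed(8)
  m <- matrix(stats::runif(36, 1, 10), 6, 6,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:6)))
  bc <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 3)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  res <- permanova(bc, g, permutations = perms)
  # enumeration oracle over all 720 relabelings with Anderson's formula
  f_obs <- pseudo_f_oracle(bc, g)
  f_all <- apply(perms, 1, function(p) pseudo_f_oracle(bc[p, p], g))
  expect_equal(res$statistic, f_obs, tolerance = 1e-9)
  expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("PERMANOVA permutation p is uniform under the null", {
  set.seed(99)
  ps <- vapply(1:120, function(i) {
    m <- matrix(stats::runif(48, 1, 10), 4, 12)
    dimnames(m) <- list(paste0("t", 1:4), paste0("s", 1:12))
    permanova(bray_curtis(m), rep(c("a", "b"), 6), n_perm = 99,
              seed = i)$p_value
  }, numeric(1))
  # p-values live on a discrete 1/100 grid; ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("within-group distance test pools the right pair counts", {
  set.seed(3)
  m <- matrix(stats::runif(64, 1, 10), 8, 8,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:8)))
  bc <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 4)
  res <- within_group_distance_test(bc, g)
  expect_equal(unname(res$n_pairs), c(6, 6))  # C(4,2) each
  expect_true(res$nonindependence_caveat)
  # identical multisets give t = 0
  d0 <- matrix(0, 4, 4)
  d0[lower.tri(d0)] <- c(0.2, 0.3, 0.4, 0.3, 0.4, 0.4)
  d0 <- d0 + t(d0)
  dd <- rbind(cbind(d0, matrix(0.9, 4, 4)), cbind(matrix(0.9, 4, 4), d0))
  dimnames(dd) <- list(paste0("s", 1:8), paste0("s", 1:8))
  res0 <- within_group_distance_test(dd, g)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(unname(res0$means), c(mean(d0[lower.tri(d0)]),
                                     mean(d0[lower.tri(d0)])))
  expect_error(within_group_distance_test(bc, c(rep("a", 7), "b")),
               "at least 2 samples")
})

make_table <- function(vals, groups, subjects = NULL) {
  n <- ncol(vals)
  colnames(vals) <- paste0("s", seq_len(n))
  if (is.null(rownames(vals))) rownames(vals) <- paste0("t", seq_len(nrow(vals)))
  vals <- sweep(vals, 2, colSums(vals), "/") * 100
  abundance_table(vals, data.frame(
    sample_id = colnames(vals),
    subject_id = if (is.null(subjects)) colnames(vals) else subjects,
    group = groups, library_size = 1e7,
    stringsAsFactors = FALSE))
}

test_that("restriction filter enforces both inclusive thresholds", {
  # taxon rows built so renormalisation is avoided: construct directly
  vals <- rbind(
    at_limit = c(rep(0.01, 5), rep(0.005, 5)),   # 0.01% in half -> kept
    below = rep(0.009, 10),                      # never reaches 0.01%
    abundant = rep(50, 10),
    rare = c(0.02, rep(0.001, 9))                # in 10% of samples
  )
  filler <- 100 - colSums(vals)
  vals <- rbind(vals, filler = filler)
  colnames(vals) <- paste0("s", 1:10)
  tab <- abundance_table(vals, data.frame(
    sample_id = colnames(vals), subject_id = colnames(vals),
    group = rep(c("pre_tx", "week_1"), each = 5), library_size = 1e7,
    stringsAsFactors = FALSE))
  kept <- restriction_filter(tab, c("pre_tx", "week_1"))
  expect_true("at_limit" %in% kept)
  expect_true("abundant" %in% kept)
  expect_false("below" %in% kept)
  expect_false("rare" %in% kept)
  expect_error(restriction_filter(tab, c("pre_tx", "week_1"),
                                  min_rel = -1), "min_rel")
})

test_that("differential screen: identical groups give unit fold changes", {
  set.seed(4)
  base <- matrix(stats::runif(40, 1, 10), 4, 10)
  tab <- make_table(cbind(base[, 1:5], base[, 1:5]),
                    rep(c("a", "b"), each = 5))
  da <- differential_abundance_screen(tab, c("a", "b"))
  expect_equal(da$fold_change, rep(1, 4), tolerance = 1e-12)
})

test_that("rank-sum component of the screen matches full enumeration", {
  a <- c(1.2, 3.4, 2.2)
  b <- c(5.1, 4.4, 6.3)
  w <- suppressWarnings(stats::wilcox.test(a, b))
  # enumeration oracle over all choose(6,3) group assignments
  pooled <- c(a, b)
  combs <- utils::combn(6, 3)
  stat <- function(idx) sum(rank(pooled)[idx]) - 3 * 4 / 2
  w_obs <- stat(1:3)
  w_all <- apply(combs, 2, stat)
  p_exact <- mean(abs(w_all - 4.5) >= abs(w_obs - 4.5))
  expect_equal(w$p.value, p_exact, tolerance = 1e-12)
  res <- wilcoxon_rank_sum(a, b)
  expect_equal(res$p_value, w$p.value)
  expect_equal(res$statistic, unname(w$statistic))
})

test_that("the screen recovers the simulated mucin-degrader collapse", {
  d <- cohort_design(seed = 31)
  d$groups <- data.frame(label = c("pre_tx", "week_1"),
                         n_subjects = c(200L, 200L),
                         rate_mean = c(30.3, 27.2), rate_sd = c(17.6, 16.9))
  co <- simulate_cohort(d)
  tab <- simulate_taxa_table(co, seed = 32)
  kept <- restriction_filter(tab, c("pre_tx", "week_1"))
  expect_true("Akkermansia_muciniphila" %in% kept)
  da <- differential_abundance_screen(tab, c("pre_tx", "week_1"),
                                      taxa = kept)
  fc <- da$fold_change[da$taxon == "Akkermansia_muciniphila"]
  # configured collapse: 2.52% -> 0.14% (with pseudocount ~17.4-fold)
  expect_gt(fc, 12)
  expect_lt(fc, 26)
  expect_lt(da$q_value[da$taxon == "Akkermansia_muciniphila"], 0.001)
})

test_that("taxa tables are normalised, group-shifted and deterministic", {
  co <- simulate_cohort(cohort_design(seed = 41))
  tab <- simulate_taxa_table(co, seed = 42)
  expect_equal(unname(colSums(tab$values)), rep(100, ncol(tab$values)),
               tolerance = 1e-9)
  expect_identical(tab$values, simulate_taxa_table(co, seed = 42)$values)
  # single-group design: no systematic shift between arbitrary halves
  d1 <- cohort_design(seed = 43)
  d1$groups <- data.frame(label = "pre_tx", n_subjects = 400L,
                          rate_mean = 30.3, rate_sd = 17.6)
  co1 <- simulate_cohort(d1)
  tab1 <- simulate_taxa_table(co1, seed = 44)
  gm <- function(x) exp(mean(log(x)))
  half <- seq_len(200)
  ratio <- gm(tab1$values["SGB0001", half]) /
    gm(tab1$values["SGB0001", -half])
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.18)
})

test_that("library-size filtering and subject selection utilities work", {
  vals <- matrix(rep(c(60, 40), 4), 2, 4,
                 dimnames = list(c("t1", "t2"), paste0("s", 1:4)))
  md <- data.frame(sample_id = paste0("s", 1:4),
                   subject_id = c("u1", "u1", "u2", "u3"),
                   group = "healthy",
                   library_size = c(5e6, 1e6, 4e6, 3e6),
                   stringsAsFactors = FALSE)
  tab <- abundance_table(vals, md)
  filt <- filter_min_library(tab, 2.9e6)
  expect_equal(colnames(filt$values), c("s1", "s3", "s4"))
  sel <- select_highest_library(tab)
  expect_equal(sort(colnames(sel$values)), c("s1", "s3", "s4"))
  expect_error(filter_min_library(tab, 1e9), "no samples")
})
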