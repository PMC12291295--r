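# Shared fixture builders and independent numeric oracles.

# Noiseless assay time course with MPA(t) = rate * t (uM), triplicates.
toy_timecourse <- function(rate_um_h, times = c(0, 0.25, 0.5, 1, 1.5, 2),
                           nrep = 3, kind = "sample",
                           baseline_mg_l = 0, blank_mpa_mg_l = NA_real_,
                           mpag_start_um = 200, lloq_mg_l = 0.25,
                           amoxapine_mg_ml = NA_real_,
                           sample_id = "toy") {
  grid <- expand.grid(replicate = seq_len(nrep), time_h = times)
  mpa <- um_to_mg_per_l(rate_um_h * grid$time_h, "MPA") + baseline_mg_l
  mpag <- um_to_mg_per_l(mpag_start_um - rate_um_h * grid$time_h, "MPAG")
  assay_timecourse(
    sample_id = sample_id, kind = kind,
    data = data.frame(time_h = grid$time_h, replicate = grid$replicate,
                      mpa_mg_l = mpa, mpag_mg_l = mpag),
    blank_mpa_mg_l = blank_mpa_mg_l, lloq_mg_l = lloq_mg_l,
    amoxapine_mg_ml = amoxapine_mg_ml
  )
}

# Single synthetic subject row for PK simulation.
toy_subject <- function(f = 0.3, rate = 50, dose_scale = 12, ka = 2.5,
                        ke = 0.35, ka2 = 3, tau = 6.5, id = "s1",
                        group = "week_3_6") {
  data.frame(subject_id = id, group = group, true_rate = rate,
             true_ehr_fraction = f, dose_scale = dose_scale, ka = ka,
             ke = ke, ka2 = ka2, tau_recirc = tau,
             stringsAsFactors = FALSE)
}

# Composite Simpson quadrature on a uniform grid (odd number of points).
simpson <- function(f, a, b, n = 4001) {
  if (n %% 2 == 0) n <- n + 1
  x <- seq(a, b, length.out = n)
  h <- (b - a) / (n - 1)
  w <- c(1, rep(c(4, 2), length.out = n - 2), 1)
  h / 3 * sum(w * f(x))
}

# Closed-form OLS via the normal equations (independent of lm()).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 2
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  list(intercept = beta[1], slope = beta[2], se_slope = unname(se[2]))
}

# Anderson's within/between-group partition of a distance matrix:
# an independent route to the PERMANOVA pseudo-F for a single factor.
pseudo_f_oracle <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# Step-up BH definition: q(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(pmin(ps[i:m] * m / (i:m), 1))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
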