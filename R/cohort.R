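#' Default study groups for the synthetic cohort
#'
#' Group sizes and reactivation-rate summary statistics (mean and SD in
#' uM/h) for the five sampling occasions emulated by the generator: kidney
#' transplant recipients pre-transplantation, 1 week, 3-6 weeks and 1 year
#' post-transplantation, and healthy individuals.
#'
#' @return A data frame with columns `label`, `n_subjects`, `rate_mean`,
#'   `rate_sd`.
#' @export
default_cohort_groups <- function() {
  data.frame(
    label = c("pre_tx", "week_1", "week_3_6", "year_1", "healthy"),
    n_subjects = c(22L, 21L, 11L, 8L, 15L),
    rate_mean = c(30.3, 27.2, 49.5, 32.5, 19.2),
    rate_sd = c(17.6, 16.9, 18.1, 7.6, 12.3),
    stringsAsFactors = FALSE
  )
}

#' Cohort simulation design
#'
#' Collects every parameter of the synthetic-cohort generator: group
#' structure, the floor applied to reactivation rates, the copula coupling
#' between a subject's reactivation rate and its recycled (enterohepatically
#' recirculated) fraction, noise levels, assay and pharmacokinetic sampling
#' grids, and control-sample parameters.
#'
#' @param groups Data frame with columns `label`, `n_subjects`, `rate_mean`,
#'   `rate_sd` (uM/h); defaults to [default_cohort_groups()].
#' @param rate_floor Lower truncation for reactivation rates, uM/h.
#' @param rate_cap Upper truncation for reactivation rates, uM/h; defaults
#'   to the substrate-exhaustion bound of the assay (starting MPAG divided
#'   by the incubation length), the fastest rate the linear assay can
#'   measure.
#' @param copula_rho Rank coupling in `[-1, 1]` between the true reactivation
#'   rate and the true recycled fraction, targeted as the cohort-level
#'   Spearman correlation.
#' @param ehr_fraction_range Length-2 numeric `(low, high)` in `[0, 1]`: the
#'   range of true recycled fractions.
#' @param assay_noise_cv,pk_noise_cv Multiplicative lognormal noise
#'   coefficients of variation for assay and plasma concentrations.
#' @param baseline_contamination_prob Probability that a fecal lysate carries
#'   a constant MPA baseline above the LLOQ (recorded in a blank control).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param assay_times Incubation sampling grid in hours.
#' @param n_replicates Replicates per assay time point.
#' @param mpag_start_um Starting MPAG substrate concentration, uM.
#' @param lloq_mg_l Lower limit of quantification of the concentration
#'   assay, mg/L.
#' @param achim_rate Reference reactivation rate of the standardized
#'   positive-control culture, uM/h.
#' @param control_rate_cv Between-run lognormal CV of the positive-control
#'   rate around `achim_rate`.
#' @param pk_shape Named list of population pharmacokinetic shape constants:
#'   `ka` (primary absorption, 1/h), `ke` (elimination, 1/h), `ka2`
#'   (reabsorption of recirculated drug, 1/h), `tau_recirc` (recirculation
#'   lag, h; must place the secondary peak in the 6-10 h window).
#' @param dose_scale_gm,dose_scale_cv Geometric mean (mg/L) and lognormal CV
#'   of the subject-level amplitude of the primary concentration component.
#' @param pk_times Nominal blood-sampling grid over the 12 h dosing
#'   interval.
#' @param pk_time_jitter_h Half-width (h) of the uniform jitter applied to
#'   recorded sampling times (the first, pre-dose sample is kept at 0).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups = default_cohort_groups(),
                          rate_floor = 2,
                          rate_cap = 100,
                          copula_rho = 0.76,
                          ehr_fraction_range = c(0.05, 0.55),
                          assay_noise_cv = 0.05,
                          pk_noise_cv = 0.05,
                          baseline_contamination_prob = 0.1,
                          seed = 1L,
                          assay_times = c(0, 0.25, 0.5, 1, 1.5, 2),
                          n_replicates = 3L,
                          mpag_start_um = 200,
                          lloq_mg_l = 0.25,
                          achim_rate = 35,
                          control_rate_cv = 0.03,
                          pk_shape = list(ka = 2.5, ke = 0.35, ka2 = 3,
                                          tau_recirc = 6.5),
                          dose_scale_gm = 12,
                          dose_scale_cv = 0.25,
                          pk_times = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6,
                                       7, 8, 9, 10, 11, 12),
                          pk_time_jitter_h = 0.05) {
  stopifnot(is.data.frame(groups))
  req <- c("label", "n_subjects", "rate_mean", "rate_sd")
  if (!all(req %in% names(groups))) {
    stop("'groups' must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(groups) == 0) stop("'groups' must contain at least one group")
  if (any(groups$n_subjects < 1)) stop("each group needs n_subjects >= 1")
  if (any(groups$rate_sd < 0)) stop("rate_sd must be >= 0")
  if (any(groups$rate_mean <= rate_floor & groups$rate_sd > 0) ||
      any(groups$rate_mean < rate_floor)) {
    stop("group rate means must lie above the rate floor")
  }
  if (rate_cap <= rate_floor) stop("rate_cap must exceed rate_floor")
  if (any(groups$rate_mean >= rate_cap)) {
    stop("group rate means must lie below the rate cap")
  }
  if (abs(copula_rho) > 1) stop("copula_rho must be in [-1, 1]")
  if (length(ehr_fraction_range) != 2 ||
      ehr_fraction_range[1] < 0 || ehr_fraction_range[2] > 1 ||
      ehr_fraction_range[1] >= ehr_fraction_range[2]) {
    stop("ehr_fraction_range must satisfy 0 <= low < high <= 1")
  }
  if (assay_noise_cv < 0 || pk_noise_cv < 0 || control_rate_cv < 0) {
    stop("noise CVs must be >= 0")
  }
  if (baseline_contamination_prob < 0 || baseline_contamination_prob > 1) {
    stop("baseline_contamination_prob must be in [0, 1]")
  }
  if (lloq_mg_l <= 0) stop("lloq_mg_l must be > 0")
  if (any(diff(assay_times) <= 0) || assay_times[1] != 0) {
    stop("assay_times must be strictly increasing and start at 0")
  }
  if (pk_shape$tau_recirc < 4 || pk_shape$tau_recirc > 10) {
    stop("tau_recirc must lie in [4, 10] h to yield a 6-10 h secondary peak")
  }
  structure(
    list(groups = groups, rate_floor = rate_floor, rate_cap = rate_cap,
         copula_rho = copula_rho,
         ehr_fraction_range = ehr_fraction_range,
         assay_noise_cv = assay_noise_cv, pk_noise_cv = pk_noise_cv,
         baseline_contamination_prob = baseline_contamination_prob,
         seed = as.integer(seed), assay_times = assay_times,
         n_replicates = as.integer(n_replicates),
         mpag_start_um = mpag_start_um, lloq_mg_l = lloq_mg_l,
         achim_rate = achim_rate, control_rate_cv = control_rate_cv,
         pk_shape = pk_shape, dose_scale_gm = dose_scale_gm,
         dose_scale_cv = dose_scale_cv, pk_times = pk_times,
         pk_time_jitter_h = pk_time_jitter_h),
    class = "cohort_design"
  )
}

#' Rescale a cohort design to a target total size
#'
#' Multiplies every group's `n_subjects` so the design totals approximately
#' `n_total` subjects while keeping the group proportions.
#'
#' @param design A [cohort_design()].
#' @param n_total Target total number of subjects.
#' @return A `cohort_design` with rescaled group sizes.
#' @export
scale_cohort <- function(design, n_total) {
  stopifnot(inherits(design, "cohort_design"), n_total >= nrow(design$groups))
  g <- design$groups
  g$n_subjects <- pmax(1L, as.integer(round(
    g$n_subjects * n_total / sum(g$n_subjects))))
  design$groups <- g
  design
}

# Mean of a normal(m, s) truncated to [lo, hi].
.tnorm_mean <- function(m, s, lo, hi) {
  a <- (lo - m) / s
  b <- (hi - m) / s
  # upper-tail form keeps the normalising mass accurate far from the bounds
  mass <- stats::pnorm(a, lower.tail = FALSE) -
    stats::pnorm(b, lower.tail = FALSE)
  m + s * (stats::dnorm(a) - stats::dnorm(b)) / mass
}

# Location m such that the [lo, hi]-truncated normal(m, s) has mean
# `target`. Moment matching keeps the printed cohort means directly
# interpretable as the means of the generated (truncated) rate
# distributions.
.tnorm_location <- function(target, s, lo, hi) {
  if (s == 0) {
    if (target < lo || target > hi) stop("group mean outside rate bounds")
    return(target)
  }
  if (target <= lo || target >= hi) {
    stop("target mean must lie strictly inside the rate bounds")
  }
  stats::uniroot(function(m) .tnorm_mean(m, s, lo, hi) - target,
                 lower = target - 10 * s, upper = target + 10 * s,
                 tol = 1e-10)$root
}

# CDF of the [lo, hi]-truncated normal(m, s); degenerate step when s == 0.
.tnorm_cdf <- function(r, m, s, lo, hi) {
  if (s == 0) return(as.numeric(r >= m))
  p0 <- stats::pnorm((lo - m) / s)
  p1 <- stats::pnorm((hi - m) / s)
  pmin(1, pmax(0, (stats::pnorm((r - m) / s) - p0) / (p1 - p0)))
}

#' Simulate a cohort of subjects with coupled rates and recycled fractions
#'
#' Draws one latent truth per subject: a reactivation rate from the group's
#' normal truncated to `[rate_floor, rate_cap]` (location moment-matched so
#' the truncated mean equals the group mean; the cap is the fastest rate
#' the linear assay can measure before substrate exhaustion) and a recycled
#' (enterohepatic) fraction coupled to
#' the rate through a Gaussian copula. The copula acts on the subject's
#' pooled-cohort rate quantile, so the configured coupling is the Spearman
#' correlation of the pooled sample; the latent Pearson correlation is set
#' to `2*sin(pi*rho/6)` so the rank coupling equals `copula_rho` without a
#' small-sample bias from the Gaussian rank transform.
#'
#' @param design A [cohort_design()].
#' @return A data frame of class `mpa_cohort` with one row per subject:
#'   `subject_id`, `group`, `true_rate` (uM/h), `true_ehr_fraction`,
#'   `dose_scale`, `ka`, `ke`, `ka2`, `tau_recirc`.
#' @examples
#' cohort <- simulate_cohort(cohort_design(seed = 42))
#' head(cohort)
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  g <- design$groups
  lo <- design$rate_floor
  hi <- design$rate_cap
  loc <- mapply(.tnorm_location, g$rate_mean, g$rate_sd,
                MoreArgs = list(lo = lo, hi = hi))
  rate <- numeric(0)
  group <- character(0)
  sid <- character(0)
  for (i in seq_len(nrow(g))) {
    n <- g$n_subjects[i]
    if (g$rate_sd[i] == 0) {
      r <- rep(g$rate_mean[i], n)
    } else {
      u <- stats::pnorm(stats::rnorm(n))
      p0 <- stats::pnorm((lo - loc[i]) / g$rate_sd[i])
      p1 <- stats::pnorm((hi - loc[i]) / g$rate_sd[i])
      r <- loc[i] + g$rate_sd[i] * stats::qnorm(p0 + u * (p1 - p0))
    }
    rate <- c(rate, r)
    group <- c(group, rep(g$label[i], n))
    sid <- c(sid, sprintf("%s_%03d", g$label[i], seq_len(n)))
  }
  n_all <- length(rate)
  w <- g$n_subjects / sum(g$n_subjects)
  # pooled mixture CDF -> latent normal shared by the copula
  u_pool <- rowSums(vapply(seq_len(nrow(g)), function(i) {
    w[i] * .tnorm_cdf(rate, loc[i], g$rate_sd[i], lo, hi)
  }, numeric(n_all)))
  u_pool <- pmin(pmax(u_pool, 1e-12), 1 - 1e-12)
  z1 <- stats::qnorm(u_pool)
  rho_lat <- 2 * sin(pi * design$copula_rho / 6)
  z2 <- rho_lat * z1 + sqrt(1 - rho_lat^2) * stats::rnorm(n_all)
  lo <- design$ehr_fraction_range[1]
  hi <- design$ehr_fraction_range[2]
  ehr <- lo + (hi - lo) * stats::pnorm(z2)
  sdlog <- sqrt(log(1 + design$dose_scale_cv^2))
  dose_scale <- stats::rlnorm(n_all, meanlog = log(design$dose_scale_gm),
                              sdlog = sdlog)
  out <- data.frame(
    subject_id = sid, group = group, true_rate = rate,
    true_ehr_fraction = ehr, dose_scale = dose_scale,
    ka = design$pk_shape$ka, ke = design$pk_shape$ke,
    ka2 = design$pk_shape$ka2, tau_recirc = design$pk_shape$tau_recirc,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mpa_cohort", "data.frame")
  out
}
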