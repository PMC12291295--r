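# Shared OLS core: baseline subtraction, LLOQ handling, unit conversion,
# then ordinary least squares of all replicate MPA points against time.
.fit_rate <- function(tc) {
  d <- tc$data
  mpa <- d$mpa_mg_l
  baseline_subtracted <- FALSE
  if (!is.na(tc$blank_mpa_mg_l) && tc$blank_mpa_mg_l > tc$lloq_mg_l) {
    mpa <- pmax(mpa - tc$blank_mpa_mg_l, 0)
    baseline_subtracted <- TRUE
  }
  mpag <- d$mpag_mg_l
  if (!is.na(tc$blank_mpag_mg_l) && tc$blank_mpag_mg_l > tc$lloq_mg_l) {
    mpag <- pmax(mpag - tc$blank_mpag_mg_l, 0)
  }
  # strictly positive measurements below the LLOQ are set to LLOQ/2 (common
  # bioanalytical convention); exact zeros denote "not detected" and stay 0
  below <- mpa > 0 & mpa < tc$lloq_mg_l
  mpa[below] <- tc$lloq_mg_l / 2
  if (length(unique(d$time_h)) < 2) {
    stop("need at least 2 distinct time points to fit a rate")
  }
  y <- mg_per_l_to_um(mpa, "MPA")
  fit <- stats::lm(y ~ d$time_h)
  co <- suppressWarnings(summary(fit))$coefficients
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-300) as.numeric(rss < 1e-12) else 1 - rss / tss
  rate <- unname(co[2, 1])
  stderr <- unname(co[2, 2])
  # linearity guard: the initial-rate model assumes limited substrate use
  mpag_um <- mg_per_l_to_um(mpag, "MPAG")
  last <- d$time_h == max(d$time_h)
  depletion_warn <- mean(mpag_um[last]) < 0.5 * max(mpag_um[d$time_h == 0])
  list(rate = rate, intercept = unname(co[1, 1]), stderr = stderr,
       r_squared = r2, n_points = length(y), df = fit$df.residual,
       baseline_subtracted = baseline_subtracted,
       below_lloq_points = sum(below),
       flagged_negative = rate < -2 * stderr,
       depletion_warn = depletion_warn,
       mpa_um = y)
}

#' Estimate the microbiome-derived MPA reactivation rate
#'
#' Fits MPA concentration versus incubation time by ordinary least squares
#' over all replicate points; the slope is the reactivation rate in uM/h.
#' Before fitting, (1) a blank-control MPA baseline exceeding the LLOQ is
#' subtracted from every measurement (floored at 0), (2) strictly positive
#' measurements below the LLOQ are replaced by LLOQ/2 and counted, and
#' (3) concentrations are converted from mg/L to uM.
#'
#' @param tc An [assay_timecourse()] of kind `"sample"` or
#'   `"positive_control"`.
#' @param warn_depletion Emit an R warning (in addition to the
#'   `depletion_warn` flag) when more than half the substrate is consumed
#'   by the last time point; set `FALSE` in cohort-scale loops.
#' @return An object of class `rate_estimate`: `rate` (uM/h), `intercept`
#'   (uM), `stderr`, `r_squared`, `n_points`, `baseline_subtracted`,
#'   `below_lloq_points`, `flagged_negative` (slope below `-2*stderr`,
#'   flagged as an assay failure rather than truncated) and
#'   `depletion_warn` (more than half the substrate consumed by the last
#'   time point, outside the initial-rate regime).
#' @examples
#' tc <- simulate_assay_timecourse(30, design = cohort_design(seed = 1),
#'                                 seed = 1)
#' estimate_reactivation_rate(tc)
#' @export
estimate_reactivation_rate <- function(tc, warn_depletion = TRUE) {
  stopifnot(inherits(tc, "assay_timecourse"))
  if (!tc$kind %in% c("sample", "positive_control")) {
    stop("rate estimation applies to kind 'sample' or 'positive_control'")
  }
  f <- .fit_rate(tc)
  if (f$depletion_warn && warn_depletion) {
    warning("MPAG depletion exceeds 50% of the starting substrate; ",
            "the linear initial-rate assumption may not hold")
  }
  structure(
    list(sample_id = tc$sample_id, rate = f$rate, intercept = f$intercept,
         stderr = f$stderr, r_squared = f$r_squared, n_points = f$n_points,
         baseline_subtracted = f$baseline_subtracted,
         below_lloq_points = f$below_lloq_points,
         flagged_negative = f$flagged_negative,
         depletion_flag = f$depletion_warn),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Reactivation rate estimate for '%s'\n", x$sample_id))
  cat(sprintf("  rate: %.2f uM/h (SE %.3f), intercept %.2f uM, R^2 %.4f\n",
              x$rate, x$stderr, x$intercept, x$r_squared))
  cat(sprintf("  n = %d points; %d below LLOQ; baseline subtracted: %s\n",
              x$n_points, x$below_lloq_points, x$baseline_subtracted))
  if (isTRUE(x$flagged_negative)) {
    cat("  WARNING: significantly negative slope (assay failure flag)\n")
  }
  invisible(x)
}

#' Control quality checks for an assay series
#'
#' The negative control (buffer plus substrate, no lysate) passes when the
#' 95% confidence interval of its fitted slope contains 0 and every MPA
#' measurement lies below the LLOQ, confirming the absence of spontaneous
#' hydrolysis. Each positive control (standardized culture) passes when its
#' estimated rate lies within +/-20% of the reference mean; the
#' between-series precision is summarised as `100 * SD / mean` of the
#' positive-control rates.
#'
#' @param negative An [assay_timecourse()] of kind `"negative_control"`.
#' @param positives List of at least two positive-control time courses.
#' @param reference_mean Reference rate of the control culture, uM/h (> 0).
#' @return An object of class `control_qc` with `cv_percent`,
#'   `reference_mean`, `lower`/`upper` acceptance limits, per-run
#'   `positive_rates` and `positive_pass` flags, and `negative_pass`.
#' @export
qc_controls <- function(negative, positives, reference_mean) {
  stopifnot(inherits(negative, "assay_timecourse"))
  if (negative$kind != "negative_control") {
    stop("'negative' must have kind 'negative_control'")
  }
  if (length(positives) < 2) stop("need at least 2 positive-control runs")
  if (reference_mean <= 0) stop("reference_mean must be > 0")
  nf <- .fit_rate(negative)
  qcrit <- if (nf$df > 0) stats::qt(0.975, nf$df) else 0
  ci_zero <- (nf$rate - qcrit * nf$stderr) <= 0 &&
    (nf$rate + qcrit * nf$stderr) >= 0
  all_blq <- all(negative$data$mpa_mg_l < negative$lloq_mg_l)
  rates <- vapply(positives, function(p) estimate_reactivation_rate(p)$rate,
                  numeric(1))
  lower <- 0.8 * reference_mean
  upper <- 1.2 * reference_mean
  pass <- rates >= lower & rates <= upper
  cv <- 100 * stats::sd(rates) / mean(rates)
  structure(
    list(cv_percent = cv, reference_mean = reference_mean,
         lower = lower, upper = upper,
         positive_rates = rates, positive_pass = pass,
         negative_pass = ci_zero && all_blq,
         negative_ci_contains_zero = ci_zero,
         negative_all_below_lloq = all_blq),
    class = "control_qc"
  )
}

#' @export
print.control_qc <- function(x, ...) {
  cat(sprintf("Control QC: CV %.2f%% across %d positive runs (limits %.1f-%.1f uM/h)\n",
              x$cv_percent, length(x$positive_rates), x$lower, x$upper))
  cat(sprintf("  positives passing: %d/%d; negative control pass: %s\n",
              sum(x$positive_pass), length(x$positive_pass), x$negative_pass))
  invisible(x)
}

#' Inhibitor dose-response profile of the reactivation assay
#'
#' Estimates the reactivation rate at each amoxapine concentration
#' (including 0) and reports whether the rates are monotone non-increasing
#' in inhibitor concentration.
#'
#' @param tcs List of [assay_timecourse()] objects, each with its
#'   `amoxapine_mg_ml` field set; the series must contain concentration 0
#'   and no duplicates.
#' @param tol Relative tolerance for treating rates as equal.
#' @return Data frame `(amoxapine_mg_ml, rate, stderr)` ordered by
#'   concentration, with attribute `diagnostic` equal to `"no inhibition"`,
#'   `"monotone non-increasing"` or `"non-monotone"`.
#' @export
inhibition_profile <- function(tcs, tol = 1e-8) {
  concs <- vapply(tcs, function(tc) tc$amoxapine_mg_ml, numeric(1))
  if (anyNA(concs)) stop("every time course needs amoxapine_mg_ml set")
  if (anyDuplicated(concs)) stop("duplicate amoxapine concentrations")
  if (length(concs) < 2 || !any(concs == 0)) {
    stop("need at least 2 concentrations including 0")
  }
  ord <- order(concs)
  est <- lapply(tcs[ord], estimate_reactivation_rate)
  rates <- vapply(est, `[[`, numeric(1), "rate")
  scale <- max(abs(rates), 1e-12)
  diffs <- diff(rates)
  diagnostic <- if (all(abs(diffs) <= tol * scale)) {
    "no inhibition"
  } else if (all(diffs <= tol * scale)) {
    "monotone non-increasing"
  } else {
    "non-monotone"
  }
  out <- data.frame(
    amoxapine_mg_ml = concs[ord], rate = rates,
    stderr = vapply(est, `[[`, numeric(1), "stderr")
  )
  attr(out, "diagnostic") <- diagnostic
  out
}

#' General beta-glucuronidase activity from a fluorometric kinetic read
#'
#' Converts fluorescence to product amount through a linear
#' 4-methylumbelliferone (4-MU) standard curve (free intercept) and reports
#' the activity as the slope of product amount versus time.
#'
#' @param fluorescence Data frame `(time_min, rfu)` with at least 3 kinetic
#'   points.
#' @param standard Data frame `(nmol, rfu)` with at least 2 points.
#' @return Activity in nmol 4-MU per minute, with the standard-curve slope
#'   and intercept as attributes.
#' @examples
#' std <- data.frame(nmol = c(1, 2), rfu = c(100, 200))
#' kin <- data.frame(time_min = c(0, 10, 20), rfu = c(0, 100, 200))
#' gus_activity_4mu(kin, std) # 0.1 nmol/min
#' @export
gus_activity_4mu <- function(fluorescence, standard) {
  stopifnot(is.data.frame(fluorescence), is.data.frame(standard))
  if (nrow(standard) < 2) stop("need at least 2 standard-curve points")
  if (nrow(fluorescence) < 3) stop("need at least 3 kinetic points")
  sc <- stats::lm(rfu ~ nmol, data = standard)
  slope <- unname(stats::coef(sc)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive standard-curve slope")
  }
  intercept <- unname(stats::coef(sc)[1])
  nmol <- (fluorescence$rfu - intercept) / slope
  kin <- stats::lm(nmol ~ fluorescence$time_min)
  activity <- unname(stats::coef(kin)[2])
  attr(activity, "standard_slope") <- slope
  attr(activity, "standard_intercept") <- intercept
  activity
}

#' Fold spread of a set of reactivation rates
#'
#' Ratio of the largest to the smallest rate, the figure used to summarise
#' interindividual spread within a cohort (e.g. rates spanning 6-86 uM/h
#' correspond to a 14-fold difference).
#'
#' @param rates Numeric vector of positive rates.
#' @return `max(rates) / min(rates)`.
#' @export
fold_range <- function(rates) {
  stopifnot(is.numeric(rates), length(rates) >= 2)
  if (min(rates) <= 0) stop("fold spread requires strictly positive rates")
  max(rates) / min(rates)
}
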