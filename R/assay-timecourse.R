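#' Construct a fecal-lysate assay time course
#'
#' Container for one incubation experiment: triplicate MPA and MPAG
#' concentrations (mg/L) measured at fixed times after exposing a fecal
#' lysate to MPAG, plus optional blank-control baselines and the assay LLOQ.
#'
#' @param sample_id Sample identifier.
#' @param kind One of `"sample"`, `"negative_control"`, `"blank"`,
#'   `"positive_control"`.
#' @param data Data frame with columns `time_h`, `replicate`, `mpa_mg_l`,
#'   `mpag_mg_l`; times must start at 0, be non-negative and cover at least
#'   two distinct values.
#' @param blank_mpa_mg_l,blank_mpag_mg_l Baseline concentrations measured in
#'   a lysate blank (no substrate), or `NA` when no blank was run.
#' @param lloq_mg_l Lower limit of quantification of the concentration
#'   assay, mg/L.
#' @param amoxapine_mg_ml Amoxapine (beta-glucuronidase inhibitor)
#'   concentration added to the incubation, or `NA`.
#' @param truth Optional list with the simulated ground truth (`rate_um_h`,
#'   `baseline_mg_l`); `NULL` for real data.
#' @return An object of class `assay_timecourse`.
#' @export
assay_timecourse <- function(sample_id, kind, data,
                             blank_mpa_mg_l = NA_real_,
                             blank_mpag_mg_l = NA_real_,
                             lloq_mg_l = 0.25,
                             amoxapine_mg_ml = NA_real_,
                             truth = NULL) {
  kind <- match.arg(kind, c("sample", "negative_control", "blank",
                            "positive_control"))
  req <- c("time_h", "replicate", "mpa_mg_l", "mpag_mg_l")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop("'data' must have columns ", paste(req, collapse = ", "))
  }
  tt <- sort(unique(data$time_h))
  if (length(tt) < 2) stop("need at least 2 distinct time points")
  if (tt[1] != 0) stop("time grid must start at 0")
  if (any(data$mpa_mg_l < 0) || any(data$mpag_mg_l < 0)) {
    stop("concentrations must be non-negative")
  }
  if (lloq_mg_l <= 0) stop("lloq_mg_l must be > 0")
  structure(
    list(sample_id = sample_id, kind = kind,
         data = data[order(data$time_h, data$replicate), , drop = FALSE],
         blank_mpa_mg_l = blank_mpa_mg_l,
         blank_mpag_mg_l = blank_mpag_mg_l,
         lloq_mg_l = lloq_mg_l, amoxapine_mg_ml = amoxapine_mg_ml,
         truth = truth),
    class = "assay_timecourse"
  )
}

#' Simulate an assay time course for one lysate
#'
#' The noiseless truth follows the linear (initial-rate) regime of the
#' reactivation reaction: `MPA(t) = rate * t` and
#' `MPAG(t) = mpag_start - rate * t` in uM, converted to mg/L and multiplied
#' by independent lognormal noise (mean 1, CV `assay_noise_cv`) per
#' replicate. With probability `baseline_contamination_prob` a sample lysate
#' carries a constant MPA baseline above the LLOQ, which is added to every
#' MPA measurement and recorded as the blank-control baseline. Negative
#' controls have rate 0 and no baseline; positive controls draw their rate
#' near the fixed reference culture rate.
#'
#' @param subject_or_rate A reactivation rate in uM/h, or a single-row
#'   `mpa_cohort` data frame (its `true_rate` is used).
#' @param kind `"sample"`, `"negative_control"` or `"positive_control"`.
#' @param design A [cohort_design()] providing the sampling grid, noise and
#'   control parameters.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param sample_id Identifier for the returned time course.
#' @return An [assay_timecourse()] with the simulated truth attached.
#' @export
simulate_assay_timecourse <- function(subject_or_rate, kind = "sample",
                                      design = cohort_design(),
                                      seed = NULL, sample_id = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  kind <- match.arg(kind, c("sample", "negative_control", "positive_control"))
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(subject_or_rate)) {
    stopifnot(nrow(subject_or_rate) == 1)
    rate <- subject_or_rate$true_rate
    if (is.null(sample_id)) sample_id <- subject_or_rate$subject_id
  } else {
    rate <- subject_or_rate
  }
  if (kind == "negative_control") {
    rate <- 0
    if (is.null(sample_id)) sample_id <- "negative_control"
  }
  if (kind == "positive_control") {
    sdlog <- sqrt(log(1 + design$control_rate_cv^2))
    rate <- design$achim_rate *
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    if (is.null(sample_id)) sample_id <- "positive_control"
  }
  if (is.null(sample_id)) sample_id <- "sample"
  if (is.na(rate) || rate < 0) stop("rate must be >= 0")
  times <- design$assay_times
  if (rate * max(times) > design$mpag_start_um) {
    stop("substrate exhaustion: MPAG would be depleted within the ",
         "incubation window; the linear-rate model does not apply")
  }
  nrep <- design$n_replicates
  grid <- expand.grid(replicate = seq_len(nrep), time_h = times)
  mpa_um <- rate * grid$time_h
  mpag_um <- design$mpag_start_um - rate * grid$time_h
  mpa <- um_to_mg_per_l(mpa_um, "MPA")
  mpag <- um_to_mg_per_l(mpag_um, "MPAG")
  cv <- design$assay_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  mpa <- mpa * noise(length(mpa))
  mpag <- mpag * noise(length(mpag))
  baseline <- 0
  blank_mpa <- NA_real_
  if (kind == "sample" &&
      stats::runif(1) < design$baseline_contamination_prob) {
    baseline <- stats::runif(1, 1.2 * design$lloq_mg_l,
                             4 * design$lloq_mg_l)
    mpa <- mpa + baseline
    blank_mpa <- baseline
  }
  assay_timecourse(
    sample_id = sample_id, kind = kind,
    data = data.frame(time_h = grid$time_h, replicate = grid$replicate,
                      mpa_mg_l = mpa, mpag_mg_l = mpag),
    blank_mpa_mg_l = blank_mpa, lloq_mg_l = design$lloq_mg_l,
    truth = list(rate_um_h = rate, baseline_mg_l = baseline)
  )
}
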