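#' Trapezoidal partial AUC over observed time points
#'
#' Linear trapezoidal sum between two observed sampling times; no
#' extrapolation or interpolation is performed, so both endpoints must be
#' members of the recorded grid.
#'
#' @param profile A [pk_profile()], or a numeric vector of times when
#'   `conc` is supplied.
#' @param t_start,t_end Interval endpoints; must match observed times.
#' @param conc Concentrations, required when `profile` is a time vector.
#' @return AUC in mg*h/L.
#' @examples
#' p <- pk_profile("p1", times = c(0, 1, 2, 3, 4, 6, 8, 10, 12),
#'                 conc = rep(2, 9))
#' auc_trapezoid(p, 0, 12) # 24
#' @export
auc_trapezoid <- function(profile, t_start, t_end, conc = NULL) {
  if (inherits(profile, "pk_profile")) {
    times <- profile$times
    conc <- profile$conc
  } else {
    times <- profile
    stopifnot(!is.null(conc), length(times) == length(conc))
  }
  i1 <- which(abs(times - t_start) < 1e-9)
  i2 <- which(abs(times - t_end) < 1e-9)
  if (length(i1) != 1 || length(i2) != 1) {
    stop("t_start and t_end must be observed time points")
  }
  if (i1 >= i2) stop("t_start must precede t_end")
  idx <- i1:i2
  sum(diff(times[idx]) * (utils::head(conc[idx], -1) +
                            utils::tail(conc[idx], -1)) / 2)
}

#' Detect the onset of enterohepatic recirculation
#'
#' Scans the profile for interior local minima inside the search window
#' that are followed by a later concentration exceeding the minimum by at
#' least `rise_threshold` (relative). The latest qualifying minimum is
#' reported as the onset time `n` — the last sampling time before
#' recirculated drug re-enters the circulation. When no minimum qualifies
#' the onset is absent and the diagnostic says so.
#'
#' @param profile A [pk_profile()] or a numeric time vector (with `conc`).
#' @param window Length-2 search window in hours.
#' @param rise_threshold Minimum relative rise after the candidate minimum.
#' @param conc Concentrations when `profile` is a time vector.
#' @return List with `onset` (time in h, or `NA`) and `diagnostic`.
#' @export
detect_ehr_onset <- function(profile, window = c(3, 11),
                             rise_threshold = 0.1, conc = NULL) {
  if (inherits(profile, "pk_profile")) {
    times <- profile$times
    conc <- profile$conc
  } else {
    times <- profile
    stopifnot(!is.null(conc), length(times) == length(conc))
  }
  if (window[1] >= max(times) || window[2] <= min(times)) {
    stop("search window lies outside the observed time range")
  }
  n <- length(times)
  onset <- NA_real_
  for (i in 2:(n - 1)) {
    if (times[i] < window[1] || times[i] > window[2]) next
    if (conc[i] > conc[i - 1] || conc[i] > conc[i + 1]) next
    later <- conc[(i + 1):n]
    rises <- if (conc[i] > 0) {
      any(later >= conc[i] * (1 + rise_threshold))
    } else {
      any(later > 0)
    }
    if (rises) onset <- times[i]
  }
  if (is.na(onset)) {
    list(onset = NA_real_, diagnostic = "no recirculation detected")
  } else {
    list(onset = onset, diagnostic = "onset detected")
  }
}

#' Non-compartmental analysis with the degree-of-recirculation statistic
#'
#' Computes the trapezoidal `AUC(0-12)`, detects the recirculation onset
#' `n`, and reports the degree of enterohepatic recirculation as
#' `100 * AUC(n-12) / AUC(0-12)`. Profiles without a detectable onset score
#' 0% with an explicit diagnostic so cohort summaries stay computable. The
#' trough `c12` is the last observed concentration.
#'
#' @param profile A [pk_profile()].
#' @param window,rise_threshold Passed to [detect_ehr_onset()].
#' @param onset_n Optional forced onset time (must be an observed time);
#'   overrides detection.
#' @return An object of class `nca_result` with `auc_0_12`, `onset_n`,
#'   `auc_n_12`, `ehr_percent`, `c12`, `cmax`, `tmax` and
#'   `onset_diagnostic`.
#' @export
degree_ehr <- function(profile, window = c(3, 11), rise_threshold = 0.1,
                       onset_n = NULL) {
  stopifnot(inherits(profile, "pk_profile"))
  if (all(profile$conc == 0)) stop("all-zero concentration profile")
  times <- profile$times
  conc <- profile$conc
  t0 <- times[1]
  t_last <- times[length(times)]
  auc_total <- auc_trapezoid(profile, t0, t_last)
  if (auc_total <= 0) stop("AUC(0-12) must be positive")
  if (is.null(onset_n)) {
    det <- detect_ehr_onset(profile, window = window,
                            rise_threshold = rise_threshold)
  } else {
    if (!any(abs(times - onset_n) < 1e-9)) {
      stop("forced onset_n must be an observed time point")
    }
    det <- list(onset = onset_n, diagnostic = "onset forced")
  }
  if (is.na(det$onset)) {
    auc_n <- 0
    ehr <- 0
  } else {
    auc_n <- auc_trapezoid(profile, det$onset, t_last)
    ehr <- 100 * auc_n / auc_total
  }
  imax <- which.max(conc)
  structure(
    list(patient_id = profile$patient_id, visit = profile$visit,
         auc_0_12 = auc_total, onset_n = det$onset, auc_n_12 = auc_n,
         ehr_percent = ehr, c12 = conc[length(conc)],
         cmax = conc[imax], tmax = times[imax],
         onset_diagnostic = det$diagnostic),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA for '%s' (%s)\n", x$patient_id, x$visit))
  cat(sprintf("  AUC(0-12) %.2f mg*h/L; Cmax %.2f mg/L at %.2f h; C12 %.2f mg/L\n",
              x$auc_0_12, x$cmax, x$tmax, x$c12))
  if (is.na(x$onset_n)) {
    cat(sprintf("  %s; degree of EHR 0%%\n", x$onset_diagnostic))
  } else {
    cat(sprintf("  onset n = %.2f h; AUC(n-12) %.2f; degree of EHR %.1f%%\n",
                x$onset_n, x$auc_n_12, x$ehr_percent))
  }
  invisible(x)
}

#' Summarise a cohort of concentration-time profiles
#'
#' Bins each recorded sample to the nearest nominal grid time, reports the
#' per-time mean and standard error of the mean, and runs the
#' non-compartmental analysis on every profile.
#'
#' @param profiles List of [pk_profile()] objects (at least 2).
#' @param nominal_times Nominal sampling grid used for binning.
#' @param ... Passed to [degree_ehr()].
#' @return List with `profile_summary` (data frame `time_h`, `n`, `mean`,
#'   `sem`) and `nca` (one row per profile).
#' @export
summarize_pk_cohort <- function(profiles,
                                nominal_times = c(0, 0.25, 0.5, 1, 1.5, 2,
                                                  3, 4, 5, 6, 7, 8, 9, 10,
                                                  11, 12),
                                ...) {
  stopifnot(length(profiles) >= 2)
  tt <- unlist(lapply(profiles, `[[`, "times"))
  cc <- unlist(lapply(profiles, `[[`, "conc"))
  bin <- nominal_times[vapply(tt, function(t) {
    which.min(abs(nominal_times - t))
  }, integer(1))]
  agg <- lapply(split(cc, bin), function(v) {
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  })
  tms <- as.numeric(names(agg))
  ord <- order(tms)
  profile_summary <- data.frame(
    time_h = tms[ord],
    n = vapply(agg, `[`, numeric(1), "n")[ord],
    mean = vapply(agg, `[`, numeric(1), "mean")[ord],
    sem = vapply(agg, `[`, numeric(1), "sem")[ord],
    row.names = NULL
  )
  nca <- do.call(rbind, lapply(profiles, function(p) {
    r <- degree_ehr(p, ...)
    data.frame(patient_id = r$patient_id, visit = r$visit,
               auc_0_12 = r$auc_0_12, onset_n = r$onset_n,
               auc_n_12 = r$auc_n_12, ehr_percent = r$ehr_percent,
               c12 = r$c12, cmax = r$cmax, tmax = r$tmax,
               onset_diagnostic = r$onset_diagnostic,
               stringsAsFactors = FALSE)
  }))
  list(profile_summary = profile_summary, nca = nca)
}
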