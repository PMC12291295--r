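#' Bateman absorption-elimination curve
#'
#' `bateman(t, ka, ke)` is `ka/(ka-ke) * (exp(-ke*t) - exp(-ka*t))` for
#' `t > 0` and 0 otherwise: the unit-amplitude concentration profile of a
#' first-order absorbed, first-order eliminated oral dose.
#'
#' @param t Time vector, h.
#' @param ka,ke Absorption and elimination rate constants, 1/h (`ka != ke`).
#' @return Curve values (dimensionless amplitude).
#' @export
bateman <- function(t, ka, ke) {
  if (abs(ka - ke) < 1e-8) stop("ka and ke must differ")
  ifelse(t <= 0, 0, ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t)))
}

# Closed-form integral of the unit Bateman curve over [0, T].
.bateman_integral <- function(T, ka, ke) {
  if (T <= 0) return(0)
  ka / (ka - ke) * ((1 - exp(-ke * T)) / ke - (1 - exp(-ka * T)) / ka)
}

#' Construct a plasma concentration-time profile
#'
#' @param patient_id Patient identifier.
#' @param times Recorded sampling times in hours, strictly increasing,
#'   starting at 0, with the last sample in `[11.5, 12.5]` h; at least 8
#'   points.
#' @param conc MPA plasma concentrations in mg/L, non-negative.
#' @param visit Visit label.
#' @param dose_mg Administered dose (informational).
#' @param truth Optional simulation ground truth.
#' @return An object of class `pk_profile`.
#' @export
pk_profile <- function(patient_id, times, conc, visit = "week_3_6",
                       dose_mg = 750, truth = NULL) {
  stopifnot(length(times) == length(conc))
  if (length(times) < 8) stop("need at least 8 sampling times")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] != 0) stop("first sampling time must be 0")
  last <- times[length(times)]
  if (last < 11.5 || last > 12.5) {
    stop("last sampling time must lie in [11.5, 12.5] h")
  }
  if (any(conc < 0)) stop("concentrations must be non-negative")
  structure(
    list(patient_id = patient_id, visit = visit, times = times,
         conc = conc, dose_mg = dose_mg, truth = truth),
    class = "pk_profile"
  )
}

#' Simulate a 12-h MPA concentration-time profile
#'
#' The noiseless truth is a sum of two Bateman components: a primary
#' absorption component and a delayed secondary component representing
#' enterohepatically recirculated drug reabsorbed after a lag
#' `tau_recirc`. The secondary amplitude is chosen in closed form so that
#' the secondary component contributes exactly the subject's
#' `true_ehr_fraction` of the total 0-12 h integral. The curve is sampled at
#' the nominal blood-draw grid with small uniform jitter on the recorded
#' times (the pre-dose sample stays at 0) and multiplied by lognormal noise
#' with CV `pk_noise_cv`.
#'
#' @param subject Single-row `mpa_cohort` data frame.
#' @param design A [cohort_design()].
#' @param seed Optional integer seed.
#' @return A [pk_profile()] whose `truth` stores the component integrals
#'   (`primary_auc`, `secondary_auc`), the recycled fraction and the
#'   noiseless concentration function.
#' @export
simulate_pk_profile <- function(subject, design = cohort_design(),
                                seed = NULL) {
  stopifnot(inherits(design, "cohort_design"), is.data.frame(subject),
            nrow(subject) == 1)
  if (!is.null(seed)) set.seed(seed)
  ka <- subject$ka; ke <- subject$ke; ka2 <- subject$ka2
  tau <- subject$tau_recirc
  if (tau < 4 || tau > 10) stop("tau_recirc must lie in [4, 10] h")
  f <- subject$true_ehr_fraction
  if (f < 0 || f >= 1) stop("true_ehr_fraction must lie in [0, 1)")
  t_end <- max(design$pk_times)
  A1 <- subject$dose_scale
  I1 <- A1 * .bateman_integral(t_end, ka, ke)
  I2_unit <- .bateman_integral(t_end - tau, ka2, ke)
  A2 <- if (f > 0) f / (1 - f) * I1 / I2_unit else 0
  I2 <- A2 * I2_unit
  ctruth <- function(t) A1 * bateman(t, ka, ke) + A2 * bateman(t - tau, ka2, ke)
  times <- design$pk_times
  jit <- design$pk_time_jitter_h
  rec <- times + stats::runif(length(times), -jit, jit)
  rec[1] <- 0
  rec <- pmax(rec, 0)
  cv <- design$pk_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  conc <- ctruth(rec) *
    stats::rlnorm(length(rec), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  pk_profile(
    patient_id = subject$subject_id, times = rec, conc = conc,
    visit = subject$group, truth = list(
      primary_auc = I1, secondary_auc = I2,
      ehr_fraction = if (I1 + I2 > 0) I2 / (I1 + I2) else 0,
      conc_fun = ctruth
    )
  )
}
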