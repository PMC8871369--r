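#' Rapamycin-induced translocation kinetics parameters
#'
#' Phenomenological parameters of rapamycin-driven PKA-R accumulation at
#' the plasma membrane. Both the plateau and the accumulation rate scale
#' with the same fractional FKBP-FRB occupancy
#' `E(d) = d^h / (d^h + EC50^h)`:
#' \deqn{R_x(t) = R_{max} E(d) (1 - e^{-k_{max} E(d) t}).}
#'
#' Defaults make 2 nM a sub-EC50 dose (slow, partial translocation), 20 nM
#' supra-EC50 (fast, supra-optimal for the prozone model) and 100 nM
#' near-saturating, with the 100 nM curve reaching over 90 percent of its
#' plateau within 3 minutes.
#'
#' @param R_max Maximal translocatable PKA-R at saturating dose (uM).
#' @param EC50 Dose of half-maximal plateau (nM).
#' @param h Hill coefficient (dimensionless).
#' @param k_max Maximal accumulation rate (1/min).
#' @return A one-row tibble of class `pka_transloc_params`.
#' @export
translocation_params <- function(R_max = 1, EC50 = 10, h = 1, k_max = 1.0) {
  for (nm in c("R_max", "EC50", "h", "k_max")) {
    check_scalar(get(nm), nm, positive = TRUE)
  }
  out <- tibble(R_max = R_max, EC50 = EC50, h = h, k_max = k_max)
  class(out) <- c("pka_transloc_params", class(out))
  out
}

#' Emission-ratio calibration of the membrane FRET biosensor
#'
#' Maps kinase activity to the fractional change of the biosensor emission
#' ratio. `DR` is the full-scale fractional ratio increase at kinase
#' saturation (the probe's dynamic range, measured by saturating cAMP with
#' forskolin/IBMX); `K_act` is the activity at which the saturating
#' response map reaches half scale.
#'
#' @param DR Full-scale fractional emission-ratio increase, in (0, 1).
#'   Default 0.209 (a 20.9 percent dynamic range).
#' @param K_act Activity (uM free PKA-C) at half-scale response.
#' @return A one-row tibble of class `pka_ratio_cal`.
#' @export
ratio_calibration <- function(DR = 0.209, K_act = 0.1) {
  check_scalar(DR, "DR", positive = TRUE)
  if (DR >= 1) abort("`DR` must be in (0, 1).")
  check_scalar(K_act, "K_act", positive = TRUE)
  out <- tibble(DR = DR, K_act = K_act)
  class(out) <- c("pka_ratio_cal", class(out))
  out
}

#' Membrane PKA-R accumulation time course
#'
#' Single-exponential approach to the dose-dependent plateau,
#' `R_x(t) = R_max E(d) (1 - exp(-k_max E(d) t))`, collapsing the
#' FKBP-rapamycin-FRB ternary-complex kinetics into one compartmental
#' rate. Rapamycin is not depleted.
#'
#' @param dose Rapamycin dose (nM), >= 0.
#' @param t_grid Time grid (min), strictly increasing from 0.
#' @param params A [translocation_params()] object.
#' @return A tibble of class `pka_timecourse` with columns `t_min`,
#'   `value` (translocated PKA-R, uM) and attribute `quantity = "R_x"`.
#' @examples
#' membrane_R_timecourse(100, seq(0, 10, by = 0.5))
#' @export
membrane_R_timecourse <- function(dose, t_grid, params = translocation_params()) {
  check_scalar(dose, "dose", nonneg = TRUE)
  check_t_grid(t_grid)
  E <- dose_occupancy(dose, params)
  k <- params$k_max * E
  value <- params$R_max * E * (1 - exp(-k * t_grid))
  new_timecourse(t_grid, value, "R_x")
}

dose_occupancy <- function(dose, params) {
  if (dose == 0) return(0)
  dose^params$h / (dose^params$h + params$EC50^params$h)
}

check_t_grid <- function(t_grid) {
  if (length(t_grid) == 0 || any(!is.finite(t_grid)) ||
      t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE)) {
    abort("`t_grid` must be strictly increasing and start at 0.")
  }
  invisible(t_grid)
}

new_timecourse <- function(t_min, value, quantity) {
  out <- tibble(t_min = t_min, value = value)
  attr(out, "quantity") <- quantity
  class(out) <- c("pka_timecourse", class(out))
  out
}

#' Membrane PKA activity time course after a rapamycin dose
#'
#' Composes [membrane_R_timecourse()] with the binding equilibrium of
#' [solve_equilibrium()] point by point (quasi-steady-state assumption:
#' binding equilibrates much faster than translocation). With default
#' parameters a 20 nM dose overshoots the activity optimum, giving a
#' transient rise-then-decline trace, while 2 nM rises slowly and
#' monotonically to a higher late value.
#'
#' @inheritParams membrane_R_timecourse
#' @param basal Basal [compartment_totals()] of the membrane compartment.
#' @param rho Catalytic subunits co-recruited per translocated protomer.
#' @param binding A [prozone_params()] object.
#' @return A `pka_timecourse` tibble (`value` = free PKA-C, uM) with
#'   attribute `baseline` (activity at `t = 0`).
#' @examples
#' activity_timecourse(20, seq(0, 60, by = 2))
#' @export
activity_timecourse <- function(dose, t_grid,
                                params = translocation_params(),
                                basal = compartment_totals(),
                                rho = 0.5,
                                binding = prozone_params()) {
  rx <- membrane_R_timecourse(dose, t_grid, params)
  totals <- compartment_totals(
    R_tot = basal$R_tot + rx$value,
    C_tot = basal$C_tot + rho * rx$value,
    A_tot = basal$A_tot
  )
  eq <- solve_equilibrium(totals, binding)
  out <- new_timecourse(t_grid, eq$C_free, "activity")
  attr(out, "baseline") <- eq$C_free[1]
  out
}

#' Fractional emission-ratio change from an activity time course
#'
#' Converts kinase activity to the biosensor's fractional emission-ratio
#' change using a saturating response map `S(x) = x / (x + K_act)`:
#' \deqn{r(t) = DR \, (S(Act(t)) - S(Act_0)).}
#' The result is bounded in `(-DR, DR)`; a saturating activity input
#' approaches `DR * (1 - S(Act_0))`, i.e. the full calibrated dynamic
#' range when basal activity is far below `K_act`.
#'
#' @param activity A `pka_timecourse` of activity (from
#'   [activity_timecourse()]) or any tibble with `t_min` and `value`.
#' @param baseline Baseline activity `Act_0` (uM). Defaults to the
#'   `baseline` attribute of `activity`, else its first value.
#' @param cal A [ratio_calibration()] object.
#' @return A `pka_timecourse` tibble of fractional ratio change
#'   (dimensionless).
#' @export
ratio_proxy <- function(activity, baseline = NULL, cal = ratio_calibration()) {
  stopifnot(is.data.frame(activity), all(c("t_min", "value") %in% names(activity)))
  baseline <- baseline %||% attr(activity, "baseline") %||% activity$value[1]
  S <- function(x) x / (x + cal$K_act)
  new_timecourse(activity$t_min, cal$DR * (S(activity$value) - S(baseline)),
                 "ratio_change")
}

#' Fit an exponential-plateau model to a cytoplasmic depletion curve
#'
#' Recovers the accumulation rate `k` and plateau of the translocation
#' model from a measured cytoplasmic intensity drop series
#' (`drop(t) = plateau * (1 - exp(-k t))`), e.g. the output of
#' [cytoplasmic_intensity_series()]. Uses Levenberg-Marquardt least
#' squares.
#'
#' @param drop A data frame with columns `t_min` and `drop` (fractional
#'   cytoplasmic intensity drop, 0 at `t = 0`).
#' @return An object of class `pka_depletion_fit` wrapping the `nls` fit;
#'   use [tidy()] for coefficients.
#' @export
fit_depletion <- function(drop) {
  stopifnot(is.data.frame(drop), all(c("t_min", "drop") %in% names(drop)))
  plateau0 <- max(drop$drop, na.rm = TRUE)
  if (plateau0 <= 0) abort("depletion series shows no drop; nothing to fit.")
  half <- drop$t_min[which(drop$drop >= plateau0 / 2)[1]]
  k0 <- log(2) / max(half, diff(range(drop$t_min)) / 20)
  fit <- minpack.lm::nlsLM(
    drop ~ plateau * (1 - exp(-k * t_min)),
    data = drop,
    start = list(plateau = plateau0, k = k0),
    lower = c(0, 0)
  )
  structure(list(fit = fit, data = drop), class = "pka_depletion_fit")
}

#' @export
#' @method tidy pka_depletion_fit
tidy.pka_depletion_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"]
  )
}

#' @export
#' @method glance pka_depletion_fit
glance.pka_depletion_fit <- function(x, ...) {
  co <- coef(x$fit)
  tibble(
    plateau = unname(co["plateau"]),
    k = unname(co["k"]),
    half_time_min = log(2) / unname(co["k"]),
    sigma = summary(x$fit)$sigma,
    n = nrow(x$data)
  )
}

#' @export
#' @method autoplot pka_timecourse
autoplot.pka_timecourse <- function(object, ...) {
  lab <- switch(attr(object, "quantity") %||% "value",
    R_x = expression("Translocated PKA-R (µM)"),
    activity = expression("PM PKA activity, free PKA-C (µM)"),
    ratio_change = "Fractional emission-ratio change",
    "value"
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = lab) +
    ggplot2::theme_minimal()
}
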