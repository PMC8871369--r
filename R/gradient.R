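#' Microfluidic gradient-device geometry
#'
#' Geometry of the diffusion-based gradient generator: parallel
#' cross-channels of span `L` connect a continuously replenished sink
#' (y = 0) to a source (y = L); cells sit inside the cross-channels, where
#' high hydraulic resistance suppresses flow so transport is purely
#' diffusive.
#'
#' The default span of 250 um reproduces both printed operating points of
#' the device: a 0-20 nM boundary pair gives 0.08 nM/um and a 10-20 nM
#' pair gives 0.04 nM/um.
#'
#' @param L Cross-channel span between sink and source boundaries (um).
#' @param n_channels Number of parallel cross-channels (device capacity up
#'   to 304).
#' @param D_rap Rapamycin diffusivity (um^2/s); only affects the transient
#'   solution, not the steady state.
#' @return A one-row tibble of class `pka_device_geometry`.
#' @export
device_geometry <- function(L = 250, n_channels = 304, D_rap = 300) {
  check_scalar(L, "L", positive = TRUE)
  check_scalar(D_rap, "D_rap", positive = TRUE)
  if (!is.numeric(n_channels) || n_channels < 1) {
    abort("`n_channels` must be >= 1.")
  }
  out <- tibble(L = L, n_channels = as.integer(n_channels), D_rap = D_rap)
  class(out) <- c("pka_device_geometry", class(out))
  out
}

#' Steady-state concentration profile across a cross-channel
#'
#' The steady state of 1D diffusion with Dirichlet boundaries is affine:
#' `c(y) = c_sink + (c_source - c_sink) * y / L`, with slope
#' `(c_source - c_sink) / L` (positive = increasing toward the source).
#'
#' @param c_source,c_sink Boundary concentrations (nM), >= 0.
#' @param geom A [device_geometry()] object.
#' @param n_grid Number of grid points across the span.
#' @return A tibble of class `pka_gradient_profile` with columns `y_um`
#'   and `c_nM`, plus attributes `slope` (nM/um), `c_source`, `c_sink`.
#' @examples
#' prof <- steady_state_profile(20, 0)
#' attr(prof, "slope") # 0.08 nM/um
#' @export
steady_state_profile <- function(c_source, c_sink, geom = device_geometry(),
                                 n_grid = 101L) {
  check_scalar(c_source, "c_source", nonneg = TRUE)
  check_scalar(c_sink, "c_sink", nonneg = TRUE)
  y <- seq(0, geom$L, length.out = n_grid)
  new_gradient_profile(y, c_sink + (c_source - c_sink) * y / geom$L,
                       c_source, c_sink, geom$L)
}

new_gradient_profile <- function(y, c, c_source, c_sink, L) {
  out <- tibble(y_um = y, c_nM = c)
  attr(out, "slope") <- (c_source - c_sink) / L
  attr(out, "c_source") <- c_source
  attr(out, "c_sink") <- c_sink
  attr(out, "L") <- L
  class(out) <- c("pka_gradient_profile", class(out))
  out
}

#' Transient concentration profile across a cross-channel
#'
#' Fourier-series solution of the 1D diffusion equation with fixed
#' boundary concentrations and zero initial interior concentration:
#' \deqn{c(y,t) = c_{ss}(y) + \sum_n b_n \sin(n\pi y/L)
#'   e^{-D (n\pi/L)^2 t}, \quad
#'   b_n = -\frac{2}{n\pi}\,(c_{sink} - (-1)^n c_{source}).}
#' The series is truncated once the decay envelope of the next term falls
#' below `1e-9` times the concentration scale (capped at 50,000 terms,
#' which matters only at `t = 0` where convergence is slow near the
#' boundaries).
#'
#' @inheritParams steady_state_profile
#' @param t Elapsed time since the boundaries were switched on (s), >= 0.
#' @return A `pka_gradient_profile` tibble (same shape as
#'   [steady_state_profile()]).
#' @export
transient_profile <- function(c_source, c_sink, geom = device_geometry(),
                              t, n_grid = 101L) {
  check_scalar(c_source, "c_source", nonneg = TRUE)
  check_scalar(c_sink, "c_sink", nonneg = TRUE)
  check_scalar(t, "t", nonneg = TRUE)
  L <- geom$L
  y <- seq(0, L, length.out = n_grid)
  c_ss <- c_sink + (c_source - c_sink) * y / L
  scale <- max(c_source, c_sink, 1)
  conc <- c_ss
  n <- 1L
  repeat {
    lam <- geom$D_rap * (n * pi / L)^2
    b_n <- -(2 / (n * pi)) * (c_sink - (-1)^n * c_source)
    env <- abs(b_n) * exp(-lam * t)
    if (env < 1e-9 * scale || n > 50000L) break
    conc <- conc + b_n * sin(n * pi * y / L) * exp(-lam * t)
    n <- n + 1L
  }
  # interior concentrations are physically bounded by the boundary values
  conc <- pmin(pmax(conc, min(c_source, c_sink, 0)), max(c_source, c_sink))
  conc[1] <- c_sink
  conc[n_grid] <- c_source
  new_gradient_profile(y, conc, c_source, c_sink, L)
}

#' Named gradient scenario presets
#'
#' Boundary-concentration pairs for the device operating points studied:
#' a steep 0-20 nM gradient (0.08 nM/um), a shallow 10-20 nM gradient
#' (0.04 nM/um), the reverse steep gradient, spatially uniform 20 and
#' 100 nM inputs, and a DMSO (zero rapamycin) control.
#'
#' @param preset One of `"steep"`, `"shallow"`, `"reverse"`,
#'   `"uniform-20"`, `"uniform-100"`, `"dmso"`.
#' @param geom A [device_geometry()] object.
#' @return A `pka_gradient_profile` tibble.
#' @export
gradient_preset <- function(preset = c("steep", "shallow", "reverse",
                                       "uniform-20", "uniform-100", "dmso"),
                            geom = device_geometry()) {
  preset <- match.arg(preset)
  bc <- switch(preset,
    "steep" = c(20, 0),
    "shallow" = c(20, 10),
    "reverse" = c(0, 20),
    "uniform-20" = c(20, 20),
    "uniform-100" = c(100, 100),
    "dmso" = c(0, 0)
  )
  steady_state_profile(bc[1], bc[2], geom)
}

#' A cell's span along a cross-channel
#'
#' @param y_rear,y_front Sink-facing and source-facing end positions (um);
#'   `0 <= y_rear < y_front <= L`.
#' @param geom A [device_geometry()] object (for bounds checking).
#' @return A one-row tibble of class `pka_cell_span` with `y_rear`,
#'   `y_front`, `L_cell`.
#' @export
cell_span <- function(y_rear = 100, y_front = 150, geom = device_geometry()) {
  check_scalar(y_rear, "y_rear", nonneg = TRUE)
  check_scalar(y_front, "y_front", positive = TRUE)
  if (y_rear >= y_front || y_front > geom$L) {
    abort("cell span must satisfy 0 <= y_rear < y_front <= L.")
  }
  out <- tibble(y_rear = y_rear, y_front = y_front, L_cell = y_front - y_rear)
  class(out) <- c("pka_cell_span", class(out))
  out
}

#' Predicted intracellular activity profile of a cell in a gradient
#'
#' Samples the local rapamycin dose at 20 positions along a cell's axis
#' and runs the composed translocation + binding-equilibrium model at each
#' position. Positions are normalised so that 0 is the source-facing
#' (high-rapamycin) end and 1 the sink-facing (low) end, matching the
#' convention used for binned intracellular FRET profiles.
#'
#' At early times the high-rapamycin end transiently leads (faster
#' translocation while still on the activating limb); at late times,
#' supra-optimal local doses suppress activity most where rapamycin is
#' highest, flipping the internal activity gradient relative to the
#' external one.
#'
#' @param span A [cell_span()] object.
#' @param profile A `pka_gradient_profile` (steady-state or transient).
#' @param t_grid Time grid (min), strictly increasing from 0.
#' @param n_positions Number of sampling positions along the cell.
#' @param params,basal,rho,binding Model parameter objects as in
#'   [activity_timecourse()].
#' @return A tibble of class `pka_cell_profile` with columns `position`
#'   (normalised, 0 = high-rapamycin end), `y_um`, `dose_nM`, `t_min`,
#'   `activity`.
#' @export
predicted_cell_profile <- function(span, profile, t_grid,
                                   n_positions = 20L,
                                   params = translocation_params(),
                                   basal = compartment_totals(),
                                   rho = 0.5,
                                   binding = prozone_params()) {
  stopifnot(inherits(span, "pka_cell_span"),
            inherits(profile, "pka_gradient_profile"))
  check_t_grid(t_grid)
  L <- attr(profile, "L")
  if (span$y_front > L) abort("cell span lies outside the device.")
  pos <- (seq_len(n_positions) - 0.5) / n_positions
  # position 0 = source-facing end (y_front); 1 = sink-facing end (y_rear)
  y <- span$y_front - pos * span$L_cell
  dose <- stats::approx(profile$y_um, profile$c_nM, xout = y, rule = 2)$y
  dose <- pmax(dose, 0)
  out <- purrr::map2_dfr(pos, seq_along(pos), function(p, i) {
    tc <- activity_timecourse(dose[i], t_grid, params, basal, rho, binding)
    tibble(position = p, y_um = y[i], dose_nM = dose[i],
           t_min = tc$t_min, activity = tc$value)
  })
  class(out) <- c("pka_cell_profile", class(out))
  out
}

#' Front-minus-rear polarity score of an intracellular profile
#'
#' Mean activity (or ratio) over the source-facing half of the cell minus
#' the mean over the sink-facing half. Under the premise that high PKA
#' activity marks the cell front, the sign predicts the preferred
#' migration direction: positive = toward the source.
#'
#' @param profile A data frame with columns `position` (normalised, 0 =
#'   source-facing end) and a value column.
#' @param value Name of the value column (default `"activity"`).
#' @param at_time Optional time (min) at which to evaluate when the
#'   profile carries a `t_min` column; default: the latest time present.
#' @return A single signed numeric score.
#' @export
polarity_score <- function(profile, value = "activity", at_time = NULL) {
  stopifnot(is.data.frame(profile), "position" %in% names(profile),
            value %in% names(profile))
  if ("t_min" %in% names(profile)) {
    at_time <- at_time %||% max(profile$t_min)
    profile <- profile[profile$t_min == at_time, , drop = FALSE]
  }
  if (nrow(profile) < 2) abort("profile needs at least 2 positions.")
  v <- profile[[value]]
  front <- v[profile$position < 0.5]
  rear <- v[profile$position >= 0.5]
  mean(front) - mean(rear)
}

#' @export
#' @method autoplot pka_gradient_profile
autoplot.pka_gradient_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$y_um, y = .data$c_nM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position, sink → source (µm)",
                  y = "Rapamycin (nM)") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot pka_cell_profile
autoplot.pka_cell_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$activity,
                               colour = factor(.data$t_min))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Normalised position (0 = high-rapamycin end)",
                  y = "PM PKA activity (µM)", colour = "t (min)") +
    ggplot2::theme_minimal()
}

#' Export a gradient profile as CSV
#'
#' @param profile A `pka_gradient_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gradient_csv <- function(profile, path) {
  df <- data.frame(y_um = profile$y_um, c_nM = profile$c_nM,
                   slope_nM_per_um = attr(profile, "slope"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
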