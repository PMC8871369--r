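#' Synthetic imaging scenario
#'
#' Describes one synthetic experiment for the movie generator. Scenario
#' kinds mirror the experimental conditions the analysis pipeline must
#' handle:
#'
#' * `dish_uniform` -- dish culture, spatially uniform rapamycin `dose`;
#'   translocation assay (mCherry cytoplasmic depletion).
#' * `fsk_ibmx_saturating` -- dish culture, forskolin/IBMX saturation of
#'   cAMP; every cell's emission ratio rises by the full calibrated
#'   dynamic range.
#' * `chip_gradient` -- microfluidic cross-channels under a source-sink
#'   rapamycin gradient (`c_source`, `c_sink` in nM); FRET readout driven
#'   by the composed translocation + equilibrium model.
#' * `chip_uniform` -- cross-channels under a uniform `dose`.
#' * `chip_ramp` -- validation scenario: cross-channel cells with a
#'   directly imposed linear emission-ratio ramp of fractional contrast
#'   `ramp_contrast` (default half the biosensor dynamic range), with
#'   per-cell alternating sign.
#' * `dmso_control`, `no_membrane_anchor_control` -- migration controls
#'   with no translocation (vehicle gradient / missing membrane anchor);
#'   cells keep their initial polarity.
#'
#' Default frame intervals follow the imaging protocol: 1 min for
#' translocation (single-channel) movies and 2 min for FRET movies.
#'
#' @param name Scenario kind (see above).
#' @param n_cells Number of cells (>= 1).
#' @param duration_min Movie duration (min), > 0.
#' @param frame_interval_min Frame interval (min).
#' @param dose Rapamycin dose (nM) for uniform scenarios.
#' @param c_source,c_sink Gradient boundary concentrations (nM).
#' @param ramp_contrast Fractional ratio contrast across the cell for
#'   `chip_ramp`.
#' @param noise Noise model: list with `dark` (camera offset, counts),
#'   `read_sd` (Gaussian read noise SD) and `poisson` (logical shot
#'   noise); or the string `"off"`.
#' @param seed Integer seed; recorded in the ground truth.
#' @param pixel_size Pixel pitch (um/px).
#' @return A list of class `pka_scenario`.
#' @export
scenario <- function(name = c("dish_uniform", "fsk_ibmx_saturating",
                              "chip_gradient", "chip_uniform", "chip_ramp",
                              "dmso_control", "no_membrane_anchor_control"),
                     n_cells = NULL, duration_min = NULL,
                     frame_interval_min = NULL,
                     dose = 100, c_source = 20, c_sink = 0,
                     ramp_contrast = 0.209 / 2,
                     noise = list(dark = 100, read_sd = 3, poisson = TRUE),
                     seed = 1L, pixel_size = 0.389) {
  name <- match.arg(name)
  defaults <- switch(name,
    dish_uniform = list(n = 6L, dur = 12, dt = 1),
    fsk_ibmx_saturating = list(n = 12L, dur = 20, dt = 2),
    chip_gradient = list(n = 9L, dur = 30, dt = 2),
    chip_uniform = list(n = 9L, dur = 30, dt = 2),
    chip_ramp = list(n = 12L, dur = 2, dt = 2),
    dmso_control = list(n = 48L, dur = 180, dt = 5),
    no_membrane_anchor_control = list(n = 48L, dur = 180, dt = 5)
  )
  n_cells <- as.integer(n_cells %||% defaults$n)
  duration_min <- duration_min %||% defaults$dur
  frame_interval_min <- frame_interval_min %||% defaults$dt
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (duration_min <= 0) abort("`duration_min` must be > 0.")
  if (identical(noise, "off")) {
    noise <- list(dark = 100, read_sd = 0, poisson = FALSE)
  }
  structure(list(
    name = name, n_cells = n_cells, duration_min = duration_min,
    frame_interval_min = frame_interval_min, dose = dose,
    c_source = c_source, c_sink = c_sink, ramp_contrast = ramp_contrast,
    noise = noise, seed = as.integer(seed), pixel_size = pixel_size
  ), class = "pka_scenario")
}

scenario_times <- function(sc) seq(0, sc$duration_min, by = sc$frame_interval_min)

new_movie <- function(channels, t_min, pixel_size, dark, regions = NULL) {
  structure(list(channels = channels, t_min = t_min,
                 pixel_size = pixel_size, dark = dark, regions = regions),
            class = "pka_movie")
}

# camera model: counts = dark + Poisson(signal) + Normal(0, read_sd)
apply_noise_ <- function(signal, noise) {
  n <- length(signal)
  out <- if (isTRUE(noise$poisson)) {
    rpois(n, lambda = as.vector(signal))
  } else {
    as.vector(signal)
  }
  if (noise$read_sd > 0) out <- out + rnorm(n, 0, noise$read_sd)
  matrix(pmax(out + noise$dark, 0), nrow(signal), ncol(signal))
}

# disk / ellipse footprints ---------------------------------------------------
disk_mask_ <- function(nr, nc, r0, c0, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}

ellipse_mask_ <- function(nr, nc, r0, c0, a_row, b_col) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rr - r0) / a_row)^2 + ((cc - c0) / b_col)^2 <= 1
}

# channel-filling cell body with rounded caps, within lane columns
chip_cell_mask_ <- function(nr, nc, lane_cols, r_center, half_len = 64L,
                            cap = 10L) {
  m <- matrix(FALSE, nr, nc)
  c_mid <- mean(range(lane_cols))
  for (dr in -half_len:half_len) {
    r <- r_center + dr
    if (r < 1 || r > nr) next
    if (abs(dr) <= half_len - cap) {
      m[r, lane_cols] <- TRUE
    } else {
      w <- sqrt(cap^2 - (abs(dr) - (half_len - cap))^2)
      cols <- lane_cols[abs(lane_cols - c_mid) <= w]
      if (length(cols)) m[r, cols] <- TRUE
    }
  }
  m
}

rim_of_ <- function(mask, width = 3L) mask & !erode_mask(mask, width)

# truncated lognormal per-cell expression scalar
draw_expression_ <- function(n, sdlog = 0.5, lo = 0.4, hi = 3) {
  pmin(pmax(rlnorm(n, 0, sdlog), lo), hi)
}

#' Render a synthetic multi-channel movie with ground truth
#'
#' Generates per-channel image stacks with the statistical structure the
#' analysis pipeline assumes: cells with a bright membrane rim, cytoplasm
#' and nucleus; a PKA-R channel whose rim brightens while the cytoplasm
#' dims as translocation proceeds; CFP and FRET-emission channels
#' consistent with the imposed emission-ratio field; a dye channel
#' visualising the gradient; and camera noise (dark offset + Poisson shot
#' noise + Gaussian read noise). Identical `(scenario, seed)` gives
#' bit-identical output.
#'
#' The imposed ratio field comes from the composed translocation +
#' equilibrium model for `chip_gradient`/`chip_uniform`, from the
#' calibrated full-scale dynamic range for `fsk_ibmx_saturating`, and from
#' an explicit linear ramp for `chip_ramp`.
#'
#' @param sc A [scenario()] object.
#' @param cal A [ratio_calibration()]; its `DR` is the generator's
#'   full-scale constant.
#' @param tparams,basal,rho,binding Model parameters as in
#'   [activity_timecourse()].
#' @param geom A [device_geometry()] for chip scenarios.
#' @return A list of class `pka_synthetic` with `movie` (a `pka_movie`)
#'   and `truth` (ground-truth record: per-cell geometry, expression,
#'   imposed series, seed).
#' @export
render_movie <- function(sc, cal = ratio_calibration(),
                         tparams = translocation_params(),
                         basal = compartment_totals(), rho = 0.5,
                         binding = prozone_params(),
                         geom = device_geometry()) {
  stopifnot(inherits(sc, "pka_scenario"))
  set.seed(sc$seed)
  switch(sc$name,
    dish_uniform = render_dish_translocation_(sc, tparams),
    fsk_ibmx_saturating = render_fsk_ibmx_(sc, cal),
    chip_gradient = ,
    chip_uniform = render_chip_fret_(sc, cal, tparams, basal, rho, binding, geom),
    chip_ramp = render_chip_ramp_(sc),
    abort(sprintf(
      "scenario '%s' is a migration scenario; use make_migration_tracks() (optionally with render_migration_movie()).",
      sc$name))
  )
}

dish_layout_ <- function(n_cells) {
  if (n_cells > 12) abort("dish scenarios support at most 12 cells.")
  centers <- expand.grid(row = c(44, 132, 220), col = c(44, 132, 220, 308))
  centers <- centers[order(centers$row, centers$col), ][seq_len(n_cells), ]
  centers$row <- centers$row + sample(-4:4, n_cells, replace = TRUE)
  centers$col <- centers$col + sample(-4:4, n_cells, replace = TRUE)
  list(nr = 264L, nc = 352L, centers = centers, radius = 32L,
       rim_w = 3L, nucleus_r = 10L)
}

render_dish_translocation_ <- function(sc, tparams) {
  ly <- dish_layout_(sc$n_cells)
  t_min <- scenario_times(sc)
  expr <- draw_expression_(sc$n_cells)
  rx <- membrane_R_timecourse(sc$dose, t_min, tparams)
  R_cyto_total <- 2 # uM; bulk cytoplasmic PKA-R pool feeding translocation
  drop <- rx$value / R_cyto_total
  I_cyto <- 1200; I_yfp <- 800; I_nuc <- 1500; rim_gain <- 2

  body <- core <- rim <- nuc <- vector("list", sc$n_cells)
  for (i in seq_len(sc$n_cells)) {
    body[[i]] <- disk_mask_(ly$nr, ly$nc, ly$centers$row[i], ly$centers$col[i],
                            ly$radius)
    rim[[i]] <- rim_of_(body[[i]], ly$rim_w)
    core[[i]] <- body[[i]] & !rim[[i]]
    nuc[[i]] <- disk_mask_(ly$nr, ly$nc, ly$centers$row[i], ly$centers$col[i],
                           ly$nucleus_r)
  }
  mch <- yfp <- cfp <- vector("list", length(t_min))
  for (fi in seq_along(t_min)) {
    sig_m <- matrix(0, ly$nr, ly$nc)
    sig_y <- matrix(0, ly$nr, ly$nc)
    sig_c <- matrix(0, ly$nr, ly$nc)
    for (i in seq_len(sc$n_cells)) {
      sig_m[core[[i]]] <- I_cyto * expr[i] * (1 - drop[fi])
      sig_m[rim[[i]]] <- I_cyto * expr[i] * (1 + rim_gain * rx$value[fi])
      sig_y[body[[i]]] <- I_yfp * expr[i]
      sig_c[nuc[[i]]] <- I_nuc
    }
    mch[[fi]] <- apply_noise_(sig_m, sc$noise)
    yfp[[fi]] <- apply_noise_(sig_y, sc$noise)
    cfp[[fi]] <- apply_noise_(sig_c, sc$noise)
  }
  movie <- new_movie(list(YFP = yfp, mCherry = mch, CFP = cfp), t_min,
                     sc$pixel_size,
                     dark = list(YFP = sc$noise$dark, mCherry = sc$noise$dark,
                                 CFP = sc$noise$dark))
  truth <- list(
    scenario = sc$name, seed = sc$seed, dose = sc$dose,
    expression = expr, t_min = t_min,
    R_x = rx$value, drop = drop, R_cyto_total = R_cyto_total,
    plateau_drop = (tparams$R_max * dose_occupancy(sc$dose, tparams)) /
      R_cyto_total,
    k = tparams$k_max * dose_occupancy(sc$dose, tparams),
    centers = ly$centers, radius = ly$radius
  )
  structure(list(movie = movie, truth = truth), class = "pka_synthetic")
}

render_fsk_ibmx_ <- function(sc, cal) {
  ly <- dish_layout_(sc$n_cells)
  t_min <- scenario_times(sc)
  expr <- draw_expression_(sc$n_cells)
  ratio0 <- 1.2; t_rise <- 10
  ratio_t <- ratio0 * (1 + cal$DR * pmin(t_min / t_rise, 1))
  I_cfp <- 900; I_yfp <- 900

  body <- vector("list", sc$n_cells)
  for (i in seq_len(sc$n_cells)) {
    body[[i]] <- disk_mask_(ly$nr, ly$nc, ly$centers$row[i], ly$centers$col[i],
                            ly$radius)
  }
  yfp <- cfp <- fret <- vector("list", length(t_min))
  for (fi in seq_along(t_min)) {
    sig_y <- sig_c <- sig_f <- matrix(0, ly$nr, ly$nc)
    for (i in seq_len(sc$n_cells)) {
      sig_y[body[[i]]] <- I_yfp * expr[i]
      sig_c[body[[i]]] <- I_cfp * expr[i]
      sig_f[body[[i]]] <- I_cfp * expr[i] * ratio_t[fi]
    }
    yfp[[fi]] <- apply_noise_(sig_y, sc$noise)
    cfp[[fi]] <- apply_noise_(sig_c, sc$noise)
    fret[[fi]] <- apply_noise_(sig_f, sc$noise)
  }
  movie <- new_movie(list(YFP = yfp, CFP = cfp, FRET_em = fret), t_min,
                     sc$pixel_size,
                     dark = list(YFP = sc$noise$dark, CFP = sc$noise$dark,
                                 FRET_em = sc$noise$dark))
  truth <- list(
    scenario = sc$name, seed = sc$seed, expression = expr, t_min = t_min,
    ratio0 = ratio0, ratio = ratio_t,
    max_ratio_increase_pct = 100 * cal$DR,
    centers = ly$centers, radius = ly$radius
  )
  structure(list(movie = movie, truth = truth), class = "pka_synthetic")
}

chip_layout_ <- function(sc, geom) {
  nr <- as.integer(round(geom$L / sc$pixel_size))
  lane_w <- 20L; wall <- 8L
  lanes <- lapply(seq_len(sc$n_cells), function(k) {
    wall + (k - 1L) * (lane_w + wall) + seq_len(lane_w)
  })
  nc <- wall + sc$n_cells * (lane_w + wall)
  list(nr = nr, nc = nc, lanes = lanes, half_len = 64L, cap = 10L)
}

# place cell centres mid-channel with jitter, regenerating positions that
# would clip the channel ends (bounded retries)
chip_cell_centers_ <- function(ly, n_cells) {
  centers <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (try in 1:20) {
      r0 <- as.integer(round(ly$nr / 2 + sample(-40:40, 1)))
      if (r0 - ly$half_len >= 1 && r0 + ly$half_len <= ly$nr) { ok <- TRUE; break }
    }
    if (!ok) abort("could not place cell inside the channel after 20 tries.")
    centers[i] <- r0
  }
  centers
}

render_chip_fret_ <- function(sc, cal, tparams, basal, rho, binding, geom) {
  ly <- chip_layout_(sc, geom)
  t_min <- scenario_times(sc)
  expr <- draw_expression_(sc$n_cells)
  centers <- chip_cell_centers_(ly, sc$n_cells)
  ratio0 <- 1.2; I_cfp <- 900; I_yfp <- 800
  if (sc$name == "chip_uniform") {
    profile <- steady_state_profile(sc$dose, sc$dose, geom)
  } else {
    profile <- steady_state_profile(sc$c_source, sc$c_sink, geom)
  }

  # imposed per-cell ratio fields from the composed model
  bodies <- nucs <- vector("list", sc$n_cells)
  ratio_field <- vector("list", sc$n_cells) # matrix [position bin, frame]
  pos_centers <- (seq_len(20L) - 0.5) / 20
  for (i in seq_len(sc$n_cells)) {
    bodies[[i]] <- chip_cell_mask_(ly$nr, ly$nc, ly$lanes[[i]], centers[i],
                                   ly$half_len, ly$cap)
    nucs[[i]] <- ellipse_mask_(ly$nr, ly$nc, centers[i],
                               mean(range(ly$lanes[[i]])), 14, 7)
    y_front <- (ly$nr - (centers[i] - ly$half_len)) * sc$pixel_size
    y_rear <- (ly$nr - (centers[i] + ly$half_len)) * sc$pixel_size
    span <- cell_span(max(y_rear, 0), min(y_front, geom$L), geom)
    prof <- predicted_cell_profile(span, profile, t_min, 20L,
                                   tparams, basal, rho, binding)
    base_act <- prof$activity[prof$t_min == 0]
    rmat <- matrix(NA_real_, 20L, length(t_min))
    for (p in seq_len(20L)) {
      sel <- prof$position == pos_centers[p]
      act <- prof$activity[sel]
      S <- function(x) x / (x + cal$K_act)
      rmat[p, ] <- ratio0 * (1 + cal$DR * (S(act) - S(act[1])))
    }
    ratio_field[[i]] <- rmat
  }

  dye_sig <- matrix(0, ly$nr, ly$nc)
  y_of_row <- (ly$nr - seq_len(ly$nr)) * sc$pixel_size
  c_of_row <- stats::approx(profile$y_um, profile$c_nM, xout = y_of_row,
                            rule = 2)$y
  for (k in seq_len(sc$n_cells)) {
    dye_sig[, ly$lanes[[k]]] <- matrix(200 + 40 * c_of_row, ly$nr,
                                       length(ly$lanes[[k]]))
  }

  yfp <- cfp <- fret <- dye <- vector("list", length(t_min))
  for (fi in seq_along(t_min)) {
    sig_y <- sig_c <- sig_f <- matrix(0, ly$nr, ly$nc)
    for (i in seq_len(sc$n_cells)) {
      b <- bodies[[i]]
      rows_in <- which(apply(b, 1, any))
      top <- min(rows_in); extent <- max(rows_in) - top + 1L
      # pixel row -> normalised position (0 = top = high/source end)
      w <- which(b, arr.ind = TRUE)
      pos_px <- (w[, 1] - top + 0.5) / extent
      rvals <- stats::approx(pos_centers, ratio_field[[i]][, fi], xout = pos_px,
                             rule = 2)$y
      sig_y[b] <- I_yfp * expr[i]
      sig_c[b] <- I_cfp * expr[i]
      sig_f[b] <- I_cfp * expr[i] * rvals
      sig_c[nucs[[i]]] <- sig_c[nucs[[i]]] + 800 # nuclear marker
    }
    yfp[[fi]] <- apply_noise_(sig_y, sc$noise)
    cfp[[fi]] <- apply_noise_(sig_c, sc$noise)
    fret[[fi]] <- apply_noise_(sig_f, sc$noise)
    dye[[fi]] <- apply_noise_(dye_sig, sc$noise)
  }
  movie <- new_movie(list(YFP = yfp, CFP = cfp, FRET_em = fret, dye = dye),
                     t_min, sc$pixel_size,
                     dark = list(YFP = sc$noise$dark, CFP = sc$noise$dark,
                                 FRET_em = sc$noise$dark, dye = sc$noise$dark),
                     regions = ly$lanes)
  truth <- list(
    scenario = sc$name, seed = sc$seed, expression = expr, t_min = t_min,
    ratio0 = ratio0, ratio_field = ratio_field, centers = centers,
    c_source = attr(profile, "c_source"), c_sink = attr(profile, "c_sink"),
    slope_nM_per_um = attr(profile, "slope"),
    dye_gain_per_nM = 40, dye_offset = 200
  )
  structure(list(movie = movie, truth = truth), class = "pka_synthetic")
}

render_chip_ramp_ <- function(sc) {
  ly <- chip_layout_(sc, device_geometry())
  t_min <- scenario_times(sc)
  expr <- draw_expression_(sc$n_cells)
  centers <- chip_cell_centers_(ly, sc$n_cells)
  signs <- rep(c(1, -1), length.out = sc$n_cells)
  ratio0 <- 1.2; I_cfp <- 900; I_yfp <- 800
  yfp <- cfp <- fret <- vector("list", length(t_min))
  bodies <- vector("list", sc$n_cells)
  for (i in seq_len(sc$n_cells)) {
    bodies[[i]] <- chip_cell_mask_(ly$nr, ly$nc, ly$lanes[[i]], centers[i],
                                   ly$half_len, ly$cap)
  }
  for (fi in seq_along(t_min)) {
    sig_y <- sig_c <- sig_f <- matrix(0, ly$nr, ly$nc)
    for (i in seq_len(sc$n_cells)) {
      b <- bodies[[i]]
      rows_in <- which(apply(b, 1, any))
      top <- min(rows_in); extent <- max(rows_in) - top + 1L
      w <- which(b, arr.ind = TRUE)
      pos_px <- (w[, 1] - top + 0.5) / extent
      # positive sign: higher ratio at the top (position 0) end
      rvals <- ratio0 * (1 + signs[i] * sc$ramp_contrast * (0.5 - pos_px))
      sig_y[b] <- I_yfp * expr[i]
      sig_c[b] <- I_cfp * expr[i]
      sig_f[b] <- I_cfp * expr[i] * rvals
    }
    yfp[[fi]] <- apply_noise_(sig_y, sc$noise)
    cfp[[fi]] <- apply_noise_(sig_c, sc$noise)
    fret[[fi]] <- apply_noise_(sig_f, sc$noise)
  }
  movie <- new_movie(list(YFP = yfp, CFP = cfp, FRET_em = fret), t_min,
                     sc$pixel_size,
                     dark = list(YFP = sc$noise$dark, CFP = sc$noise$dark,
                                 FRET_em = sc$noise$dark),
                     regions = ly$lanes)
  truth <- list(scenario = sc$name, seed = sc$seed, expression = expr,
                t_min = t_min, ratio0 = ratio0, signs = signs,
                ramp_contrast = sc$ramp_contrast, centers = centers)
  structure(list(movie = movie, truth = truth), class = "pka_synthetic")
}

#' Migration model parameters
#'
#' Parameters of the 1D biased-random-walk nuclear migration model:
#' `y(t + dt) = y(t) + s(t) v0 dt + Normal(0, sigma_step^2)`, with
#' polarity `s(t)` in \{+1, -1\} evolving by the scenario's reversal rule
#' and reflecting boundaries at the channel ends.
#'
#' The defaults are generator choices, not estimates of any measured cell
#' population: reversal times are drawn uniformly over `tau_range`
#' (anchored to the ~15 min onset of the intracellular response), and
#' `p_up_init` reflects the seeding-induced initial "upward" bias.
#'
#' @param v0 Mean migration speed (um/min).
#' @param sigma_step Per-step positional noise SD (um).
#' @param p_up_init Initial fraction of upward-polarised cells.
#' @param tau_range Range (min) of per-cell reversal times for gradient
#'   scenarios.
#' @param tau_r Repolarisation interval (min) for the uniform-100
#'   randomisation rule.
#' @return A list of class `pka_migration_params`.
#' @export
migration_params <- function(v0 = 0.3, sigma_step = 1.0, p_up_init = 0.8,
                             tau_range = c(15, 60), tau_r = 15) {
  check_scalar(v0, "v0", nonneg = TRUE)
  check_scalar(sigma_step, "sigma_step", nonneg = TRUE)
  check_scalar(p_up_init, "p_up_init", nonneg = TRUE)
  if (p_up_init > 1) abort("`p_up_init` must be in [0, 1].")
  structure(list(v0 = v0, sigma_step = sigma_step, p_up_init = p_up_init,
                 tau_range = tau_range, tau_r = tau_r),
            class = "pka_migration_params")
}

#' Simulate nuclear migration tracks
#'
#' 1D biased random walk per cell with scenario-dependent polarity
#' dynamics:
#'
#' * `chip_gradient` -- each cell reverses its polarity at a per-cell time
#'   `tau ~ U(tau_range)` toward the direction opposite the external
#'   gradient (down the gradient for an upward source);
#' * `chip_uniform` with `dose >= 100` -- polarity is resampled with equal
#'   probability every `tau_r` minutes (directional randomisation);
#' * `chip_uniform` with lower dose, `dmso_control`,
#'   `no_membrane_anchor_control` -- polarity never changes.
#'
#' Boundaries at the channel ends reflect.
#'
#' @param sc A [scenario()] object of a chip/migration kind.
#' @param mp A [migration_params()] object.
#' @param geom A [device_geometry()].
#' @return A list of class `pka_synthetic_tracks` with `tracks` (tibble:
#'   `cell`, `t_min`, `y_um`, `displacement_um`, `s`) and `truth`
#'   (per-cell initial polarity, reversal times, rule, seed).
#' @export
make_migration_tracks <- function(sc, mp = migration_params(),
                                  geom = device_geometry()) {
  stopifnot(inherits(sc, "pka_scenario"), inherits(mp, "pka_migration_params"))
  set.seed(sc$seed + 1L) # separate stream from movie rendering
  t_min <- scenario_times(sc)
  dt <- sc$frame_interval_min
  n <- sc$n_cells
  rule <- migration_rule_(sc)
  s0 <- ifelse(runif(n) < mp$p_up_init, 1, -1)
  tau <- runif(n, mp$tau_range[1], mp$tau_range[2])
  flip_dir <- if (rule == "flip") {
    if (sc$c_source >= sc$c_sink) -1 else 1
  } else NA_real_
  y0 <- runif(n, 0.3 * geom$L, 0.7 * geom$L)
  lo <- 10; hi <- geom$L - 10

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    y <- numeric(length(t_min)); s <- numeric(length(t_min))
    y[1] <- y0[i]; s_cur <- s0[i]
    s[1] <- s_cur
    for (k in seq_along(t_min)[-1]) {
      tk <- t_min[k]
      if (rule == "flip" && tk > tau[i]) s_cur <- flip_dir
      if (rule == "randomize" && tk >= mp$tau_r &&
          (tk %% mp$tau_r) < dt) {
        s_cur <- ifelse(runif(1) < 0.5, 1, -1)
      }
      step <- s_cur * mp$v0 * dt + rnorm(1, 0, mp$sigma_step)
      yn <- y[k - 1] + step
      if (yn > hi) yn <- 2 * hi - yn
      if (yn < lo) yn <- 2 * lo - yn
      y[k] <- yn; s[k] <- s_cur
    }
    rows[[i]] <- tibble(cell = i, t_min = t_min, y_um = y,
                        displacement_um = y - y[1], s = s)
  }
  tracks <- dplyr::bind_rows(rows)
  truth <- list(scenario = sc$name, seed = sc$seed, rule = rule,
                s0 = s0, tau = if (rule == "flip") tau else NULL,
                flip_dir = flip_dir, y0 = y0,
                params = unclass(mp))
  structure(list(tracks = tracks, truth = truth),
            class = "pka_synthetic_tracks")
}

migration_rule_ <- function(sc) {
  switch(sc$name,
    chip_gradient = "flip",
    chip_uniform = if (sc$dose >= 100) "randomize" else "none",
    dmso_control = ,
    no_membrane_anchor_control = "none",
    abort(sprintf("scenario '%s' has no migration rule.", sc$name))
  )
}

#' Render a nuclear-marker movie from migration tracks
#'
#' Renders the CFP (nuclear marker) channel of a chip movie in which each
#' lane's nucleus follows its simulated track, rounded to integer pixel
#' rows so that centroid tracking can be validated against exact ground
#' truth.
#'
#' @param sc A [scenario()] object (chip/migration kind).
#' @param tracks Output of [make_migration_tracks()].
#' @param geom A [device_geometry()].
#' @return A list of class `pka_synthetic` with `movie` and `truth`
#'   (including the pixel-rounded track used for rendering).
#' @export
render_migration_movie <- function(sc, tracks, geom = device_geometry()) {
  stopifnot(inherits(tracks, "pka_synthetic_tracks"))
  set.seed(sc$seed + 2L)
  ly <- chip_layout_(sc, geom)
  t_min <- scenario_times(sc)
  tr <- tracks$tracks
  cfp <- vector("list", length(t_min))
  y_px_truth <- matrix(NA_real_, sc$n_cells, length(t_min))
  for (fi in seq_along(t_min)) {
    sig <- matrix(0, ly$nr, ly$nc)
    for (i in seq_len(sc$n_cells)) {
      y_um <- tr$y_um[tr$cell == i & tr$t_min == t_min[fi]]
      r0 <- as.integer(round(ly$nr - y_um / sc$pixel_size))
      r0 <- min(max(r0, 16L), ly$nr - 16L)
      y_px_truth[i, fi] <- ly$nr - r0
      nuc <- ellipse_mask_(ly$nr, ly$nc, r0, mean(range(ly$lanes[[i]])), 14, 7)
      sig[nuc] <- 1500
    }
    cfp[[fi]] <- apply_noise_(sig, sc$noise)
  }
  movie <- new_movie(list(CFP = cfp), t_min, sc$pixel_size,
                     dark = list(CFP = sc$noise$dark), regions = ly$lanes)
  truth <- c(tracks$truth, list(y_px = y_px_truth, t_min = t_min))
  structure(list(movie = movie, truth = truth), class = "pka_synthetic")
}

#' Canonical deterministic test fixtures
#'
#' Emits the fixed set of tiny noise-free images used in unit tests,
#' together with a manifest of their expected analysis outputs: a single
#' disk (known area and centroid), two disjoint disks, a rectangular cell
#' with a linear ratio ramp (known bin means), a disk with a bright rim
#' (known post-erosion mean), and a nucleus translated by a fixed number
#' of pixels per frame (known displacement).
#'
#' @param seed Seed recorded in the manifest (the fixtures themselves are
#'   deterministic).
#' @return A named list of fixtures, each with the image data and an
#'   `expected` record; plus a `manifest` tibble.
#' @export
fixture_suite <- function(seed = 1L) {
  fx <- list()

  disk <- matrix(0, 64, 64)
  dm <- disk_mask_(64, 64, 32, 32, 10)
  disk[dm] <- 500
  fx$disk <- list(frame = disk, expected = list(area = sum(dm),
                                                centroid = c(32, 32)))

  two <- matrix(0, 64, 64)
  d1 <- disk_mask_(64, 64, 16, 20, 6); d2 <- disk_mask_(64, 64, 46, 44, 8)
  two[d1 | d2] <- 500
  fx$two_disks <- list(frame = two,
                       expected = list(areas = c(sum(d1), sum(d2)),
                                       order = "top disk first"))

  # 40-row x 24-col rectangular cell, ratio ramps linearly down the rows
  ramp_mask <- matrix(FALSE, 60, 40); ramp_mask[11:50, 9:32] <- TRUE
  ramp_vals <- matrix(NA_real_, 60, 40)
  for (r in 11:50) ramp_vals[r, 9:32] <- 1 + (r - 11) / 39 # 1 at top -> 2 at bottom
  bins <- vapply(split(11:50, rep(1:20, each = 2)), function(rr) {
    mean(ramp_vals[rr, 9:32])
  }, numeric(1))
  fx$ramp <- list(mask = ramp_mask, ratio = ramp_vals,
                  expected = list(bin_means = unname(bins)))

  core <- disk_mask_(128, 128, 64, 64, 50)
  rimr <- core & !disk_mask_(128, 128, 64, 64, 40)
  rimmed <- matrix(0, 128, 128)
  rimmed[core] <- 100; rimmed[rimr] <- 200
  fx$rimmed_disk <- list(frame = rimmed, mask = core,
                         expected = list(post_erosion_mean = 100))

  nuc_frames <- lapply(0:5, function(k) {
    f <- matrix(0, 96, 32)
    f[disk_mask_(96, 32, 70 - 3 * k, 16, 6)] <- 1000
    f
  })
  fx$translated_nucleus <- list(
    frames = nuc_frames,
    expected = list(px_per_frame = 3, pixel_size = 0.389,
                    displacement_um_frame5 = 15 * 0.389)
  )

  fx$manifest <- tibble(
    fixture = c("disk", "two_disks", "ramp", "rimmed_disk",
                "translated_nucleus"),
    expectation = c("area and centroid", "two masks ordered by centroid row",
                    "20 known bin means", "post-erosion mean 100",
                    "displacement 5.835 um at frame 5"),
    seed = seed
  )
  fx
}
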