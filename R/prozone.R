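#' Microstate weights of a single PKA-R protomer
#'
#' Enumerates the six microstates of one PKA-R protomer -- PKA-C bound or
#' not (`c` in 0/1) crossed with 0, 1 or 2 bound cAMP (`a`) -- at given free
#' ligand concentrations. The statistical weight of state `(c, a)` relative
#' to the empty protomer is
#' \deqn{w(c, a) = (C_f/K_C)^c \binom{2}{a} (A_f/K_A)^a \alpha^{-ca},}
#' so the empty state always has weight 1 and the partition function is
#' `Z = sum(w)`.
#'
#' @param C_free Free catalytic subunit concentration (uM).
#' @param A_free Free cAMP concentration (uM).
#' @param params A [prozone_params()] object.
#'
#' @return A list with `weights` (tibble with columns `c_bound`, `a_bound`,
#'   `weight`), the partition function `Z`, and the mean occupancies
#'   `c_mean` (bound PKA-C per protomer, in \[0, 1\]) and `a_mean`
#'   (bound cAMP per protomer, in \[0, 2\]).
#' @examples
#' p <- prozone_params()
#' protomer_weights(C_free = p$K_C, A_free = 0, params = p)$c_mean # 0.5
#' @export
protomer_weights <- function(C_free, A_free, params = prozone_params()) {
  check_scalar(C_free, "C_free", nonneg = TRUE)
  check_scalar(A_free, "A_free", nonneg = TRUE)
  stopifnot(inherits(params, "pka_binding_params"))
  cb <- rep(0:1, times = 3L)
  ab <- rep(0:2, each = 2L)
  w <- (C_free / params$K_C)^cb *
    choose(2L, ab) * (A_free / params$K_A)^ab *
    params$alpha^(-cb * ab)
  Z <- sum(w)
  list(
    weights = tibble(c_bound = cb, a_bound = ab, weight = w),
    Z = Z,
    c_mean = sum(cb * w) / Z,
    a_mean = sum(ab * w) / Z
  )
}

# Vectorised occupancies <c>, <a> at free concentrations (internal fast path).
# Closed forms: with B_a = (1 + A/(alpha^c K_A))^2,
#   Z = B_0 + (C/K_C) B_1,  <c> = (C/K_C) B_1 / Z,
#   <a> = [2(A/K_A)(1 + A/K_A) + (C/K_C) 2(A/(alpha K_A))(1 + A/(alpha K_A))] / Z
occupancy_ <- function(C, A, K_C, K_A, alpha) {
  aK <- A / K_A
  aKa <- A / (alpha * K_A)
  cK <- C / K_C
  B0 <- (1 + aK)^2
  B1 <- (1 + aKa)^2
  Z <- B0 + cK * B1
  list(
    c_mean = cK * B1 / Z,
    a_mean = (2 * aK * (1 + aK) + cK * 2 * aKa * (1 + aKa)) / Z
  )
}

# Bracketing bisection for the inner (C) conservation equation at fixed A_free.
# residual(C) = C + R_tot <c>(C, A) - C_tot is strictly increasing in C.
solve_C_ <- function(A_free, R_tot, C_tot, K_C, K_A, alpha, iter = 90L) {
  if (C_tot <= 0) return(0)
  lo <- 0
  hi <- C_tot
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    r <- mid + R_tot * occupancy_(mid, A_free, K_C, K_A, alpha)$c_mean - C_tot
    if (r > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Solve the membrane-compartment binding equilibrium
#'
#' Given conserved totals of PKA-R protomers, catalytic subunit and cAMP,
#' finds the unique free concentrations `(C_free, A_free)` satisfying both
#' conservation equations
#' \deqn{C_f + R_{tot}\langle c\rangle = C_{tot}, \qquad
#'       A_f + R_{tot}\langle a\rangle = A_{tot},}
#' where the mean occupancies come from the protomer partition function of
#' [protomer_weights()]. Each conservation equation is strictly monotone in
#' its own free variable, so a nested bracketing bisection (outer loop on
#' `A_free`, inner on `C_free`) converges to the unique physical root
#' without randomness.
#'
#' The free catalytic subunit `C_free` is the model's kinase-activity
#' readout: dissociation from PKA-R is the canonical activation event.
#'
#' @param totals A [compartment_totals()] tibble; each row is solved
#'   independently.
#' @param params A [prozone_params()] object.
#' @param camp_mode `"conserved"` (default) treats cAMP as a conserved
#'   total; `"buffered"` clamps `A_free = A_tot` (cAMP held by an external
#'   reservoir) and solves only the PKA-C conservation.
#'
#' @return A tibble of class `pka_equilibrium`, one row per input row, with
#'   columns `R_tot`, `C_tot`, `A_tot`, `C_free`, `A_free`, `c_occ`,
#'   `a_occ`, `Z`, and the conservation residuals `resid_C`, `resid_A`
#'   (absolute, uM).
#' @examples
#' solve_equilibrium(compartment_totals(1, 1, 0),
#'                   prozone_params(K_C = 1, K_A = 1, alpha = 1))
#' @export
solve_equilibrium <- function(totals, params = prozone_params(),
                              camp_mode = c("conserved", "buffered")) {
  stopifnot(inherits(totals, "pka_totals") || is.data.frame(totals))
  stopifnot(inherits(params, "pka_binding_params"))
  camp_mode <- match.arg(camp_mode)
  K_C <- params$K_C; K_A <- params$K_A; alpha <- params$alpha

  solve_one <- function(R_tot, C_tot, A_tot) {
    if (R_tot == 0) {
      C_free <- C_tot
      A_free <- A_tot
    } else if (camp_mode == "buffered") {
      A_free <- A_tot
      C_free <- solve_C_(A_free, R_tot, C_tot, K_C, K_A, alpha)
    } else if (A_tot <= 0) {
      A_free <- 0
      C_free <- solve_C_(0, R_tot, C_tot, K_C, K_A, alpha)
    } else {
      # outer bisection on A_free in [0, A_tot]; residual increasing in A_free
      lo <- 0
      hi <- A_tot
      r_lo <- 0 + R_tot * occupancy_(
        solve_C_(0, R_tot, C_tot, K_C, K_A, alpha), 0, K_C, K_A, alpha
      )$a_mean - A_tot
      r_hi <- A_tot + R_tot * occupancy_(
        solve_C_(A_tot, R_tot, C_tot, K_C, K_A, alpha), A_tot, K_C, K_A, alpha
      )$a_mean - A_tot
      if (r_lo > 0 || r_hi < 0) {
        abort(sprintf(
          "failed to bracket the cAMP conservation root (R_tot=%g, C_tot=%g, A_tot=%g)",
          R_tot, C_tot, A_tot
        ))
      }
      for (i in seq_len(90L)) {
        mid <- (lo + hi) / 2
        Cm <- solve_C_(mid, R_tot, C_tot, K_C, K_A, alpha)
        r <- mid + R_tot * occupancy_(Cm, mid, K_C, K_A, alpha)$a_mean - A_tot
        if (r > 0) hi <- mid else lo <- mid
      }
      A_free <- (lo + hi) / 2
      C_free <- solve_C_(A_free, R_tot, C_tot, K_C, K_A, alpha)
    }
    occ <- occupancy_(C_free, A_free, K_C, K_A, alpha)
    pw <- protomer_weights(C_free, A_free, params)
    tibble(
      R_tot = R_tot, C_tot = C_tot, A_tot = A_tot,
      C_free = C_free, A_free = A_free,
      c_occ = occ$c_mean, a_occ = occ$a_mean, Z = pw$Z,
      resid_C = abs(C_free + R_tot * occ$c_mean - C_tot),
      resid_A = if (camp_mode == "buffered") NA_real_ else
        abs(A_free + R_tot * occ$a_mean - A_tot)
    )
  }

  out <- purrr::pmap_dfr(
    list(totals$R_tot, totals$C_tot, totals$A_tot), solve_one
  )
  class(out) <- c("pka_equilibrium", class(out))
  out
}

#' Membrane PKA activity as a function of translocated PKA-R
#'
#' Sweeps the amount of translocated PKA-R (`R_x`) added on top of the
#' basal membrane pool, solving the binding equilibrium at each point.
#' Translocation adds `R_x` protomers and co-recruits `rho * R_x`
#' catalytic subunits (holoenzyme-bound fraction), while the local cAMP
#' total stays fixed. Activity is read out as free catalytic subunit.
#'
#' With the default parameters the curve is biphasic: activity rises with
#' moderate translocation (cAMP loading of incoming protomers releases
#' co-recruited PKA-C) and falls below the pre-translocation baseline at
#' high `R_x`, where excess cAMP-free protomers titrate the catalytic
#' subunit away -- the prozone / combinatorial-inhibition regime.
#'
#' @param R_x_grid Sorted, non-negative grid of translocated PKA-R values
#'   (uM), starting at 0.
#' @param basal [compartment_totals()] of the unstimulated membrane
#'   compartment.
#' @param rho Catalytic subunits co-recruited per translocated protomer,
#'   in \[0, 1\].
#' @param params A [prozone_params()] object.
#'
#' @return A tibble of class `pka_activity_curve` with columns `R_x`,
#'   `activity` (uM free PKA-C) and `baseline` (activity at `R_x = 0`,
#'   repeated).
#' @examples
#' curve <- activity_vs_R(seq(0, 5, length.out = 50))
#' find_optimum(curve)
#' @export
activity_vs_R <- function(R_x_grid, basal = compartment_totals(),
                          rho = 0.5, params = prozone_params()) {
  if (length(R_x_grid) == 0) {
    out <- tibble(R_x = numeric(), activity = numeric(), baseline = numeric())
    class(out) <- c("pka_activity_curve", class(out))
    return(out)
  }
  if (any(!is.finite(R_x_grid)) || any(R_x_grid < 0)) {
    abort("`R_x_grid` must be finite and non-negative.")
  }
  if (is.unsorted(R_x_grid, strictly = FALSE)) {
    abort("`R_x_grid` must be sorted ascending.")
  }
  check_scalar(rho, "rho", nonneg = TRUE)
  if (rho > 1) abort("`rho` must be in [0, 1].")
  stopifnot(nrow(basal) == 1L)

  totals <- compartment_totals(
    R_tot = basal$R_tot + R_x_grid,
    C_tot = basal$C_tot + rho * R_x_grid,
    A_tot = basal$A_tot
  )
  eq <- solve_equilibrium(totals, params)
  base_eq <- if (R_x_grid[1] == 0) eq$C_free[1] else
    solve_equilibrium(basal, params)$C_free
  out <- tibble(R_x = R_x_grid, activity = eq$C_free, baseline = base_eq)
  class(out) <- c("pka_activity_curve", class(out))
  out
}

#' Locate the activity optimum and below-baseline crossing
#'
#' Finds the grid argmax of an activity curve and, if the high-`R_x` tail
#' dips below the `R_x = 0` baseline, the first grid point where it does.
#' Ties are broken toward the smaller `R_x`.
#'
#' @param curve A tibble from [activity_vs_R()].
#' @return A one-row tibble with `R_x_opt`, `activity_opt`, `baseline`,
#'   `R_x_below_baseline` (NA when the tail never drops below baseline)
#'   and `interior_max` (logical: argmax strictly inside the grid).
#' @export
find_optimum <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("R_x", "activity") %in% names(curve)))
  if (nrow(curve) == 0) abort("`curve` must be non-empty.")
  i <- which.max(curve$activity) # which.max takes the first maximum: small-R_x tie-break
  base <- curve$baseline[1]
  after <- which(curve$activity < base & seq_len(nrow(curve)) > i)
  tibble(
    R_x_opt = curve$R_x[i],
    activity_opt = curve$activity[i],
    baseline = base,
    R_x_below_baseline = if (length(after)) curve$R_x[after[1]] else NA_real_,
    interior_max = i > 1L && i < nrow(curve)
  )
}

#' @export
#' @method glance pka_activity_curve
glance.pka_activity_curve <- function(x, ...) {
  find_optimum(x)
}

#' @export
#' @method autoplot pka_activity_curve
autoplot.pka_activity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$R_x, y = .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      yintercept = object$baseline[1], linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = expression("Translocated PKA-R," ~ R[x] ~ "(µM)"),
      y = expression("PM PKA activity, free PKA-C (µM)")
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @method tidy pka_equilibrium
tidy.pka_equilibrium <- function(x, ...) {
  as_tibble(x)
}
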