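test_that("protomer microstate weights reproduce closed-form occupancies", {
  p <- prozone_params()

  empty <- protomer_weights(0, 0, p)
  expect_equal(empty$Z, 1)
  expect_equal(empty$c_mean, 0)
  expect_equal(empty$a_mean, 0)
  expect_equal(empty$weights$weight[empty$weights$c_bound == 0 &
                                      empty$weights$a_bound == 0], 1)
  expect_true(all(empty$weights$weight >= 0))

  half <- protomer_weights(p$K_C, 0, p)
  expect_equal(half$c_mean, 0.5)
  expect_equal(half$a_mean, 0)

  # independent sites (alpha = 1): <c> = 1/2 at C = K_C, <a> = 1 at A = K_A,
  # cross-checked against an explicit 6-state enumeration
  p1 <- prozone_params(K_C = 0.2, K_A = 0.4, alpha = 1)
  w <- protomer_weights(p1$K_C, p1$K_A, p1)
  states <- expand.grid(c = 0:1, a = 0:2)
  wt <- with(states, (p1$K_C / p1$K_C)^c * choose(2, a) * (p1$K_A / p1$K_A)^a)
  expect_equal(w$c_mean, sum(states$c * wt) / sum(wt))
  expect_equal(w$a_mean, sum(states$a * wt) / sum(wt))
  expect_equal(w$c_mean, 0.5)
  expect_equal(w$a_mean, 1.0)
})

test_that("invalid protomer inputs are rejected with a diagnostic", {
  p <- prozone_params()
  expect_error(protomer_weights(-1, 0, p), "C_free")
  expect_error(protomer_weights(0, NaN, p), "A_free")
  expect_error(prozone_params(K_C = 0), "K_C")
  expect_error(prozone_params(alpha = 0.5), "alpha")
  expect_error(compartment_totals(R_tot = -1), "R_tot")
})

test_that("equilibrium solver handles degenerate totals exactly", {
  p <- prozone_params()

  no_linker <- solve_equilibrium(compartment_totals(0, 0.7, 1.3), p)
  expect_equal(no_linker$C_free, 0.7)
  expect_equal(no_linker$A_free, 1.3)

  no_C <- solve_equilibrium(compartment_totals(0.5, 0, 1), p)
  expect_equal(no_C$C_free, 0)
  # A_free then solves the cAMP-only conservation
  resid <- no_C$A_free +
    0.5 * protomer_weights(0, no_C$A_free, p)$a_mean - 1
  expect_lt(abs(resid), 1e-9)

  zero <- solve_equilibrium(compartment_totals(0, 0, 0), p)
  expect_equal(zero$C_free, 0)
  expect_equal(zero$A_free, 0)
})

test_that("single-ligand equilibrium matches the closed-form quadratic", {
  p <- prozone_params(K_C = 1, K_A = 1, alpha = 1)
  eq <- solve_equilibrium(compartment_totals(1, 1, 0), p)
  expect_equal(eq$C_free, (sqrt(5) - 1) / 2, tolerance = 1e-10)

  # alpha = 1 with cAMP present: C binding decouples from cAMP loading,
  # so the same quadratic applies at any A_tot
  for (A in c(0, 0.5, 3)) {
    eq <- solve_equilibrium(compartment_totals(0.8, 1.2, A),
                            prozone_params(K_C = 0.3, K_A = 0.7, alpha = 1))
    expect_equal(eq$C_free, quadratic_C_free(0.8, 1.2, 0.3),
                 tolerance = 1e-9)
  }
})

test_that("solved states conserve mass and match the ODE relaxation oracle", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  p_draw <- function() {
    prozone_params(K_C = 10^runif(1, -2, 0), K_A = 10^runif(1, -2, 0),
                   alpha = 10^runif(1, 0, 2))
  }
  for (i in 1:25) {
    p <- p_draw()
    tot <- compartment_totals(runif(1, 0.05, 2), runif(1, 0.05, 2),
                              runif(1, 0.05, 2))
    eq <- solve_equilibrium(tot, p)
    expect_lt(eq$resid_C / max(tot$C_tot, 1e-12), 1e-9)
    expect_lt(eq$resid_A / max(tot$A_tot, 1e-12), 1e-9)
    oracle <- ode_relax_oracle(tot$R_tot, tot$C_tot, tot$A_tot,
                               p$K_C, p$K_A, p$alpha)
    expect_lt(abs(eq$C_free - oracle$C_free) / max(oracle$C_free, 1e-12),
              1e-6)
  }
})

test_that("limiting regimes behave physically", {
  p <- prozone_params()
  # saturating cAMP releases the catalytic subunit up to the residual
  # affinity of the doubly-loaded protomer (K_C * alpha^2)
  eq <- solve_equilibrium(compartment_totals(1, 0.5, 1e5), p)
  expect_equal(eq$C_free, 0.5, tolerance = 0.02)
  eq_hi <- solve_equilibrium(compartment_totals(1, 0.5, 1e5),
                             prozone_params(alpha = 1e4))
  expect_equal(eq_hi$C_free, 0.5, tolerance = 1e-5)
  # excess linker titrates the catalytic subunit away
  eq <- solve_equilibrium(compartment_totals(1e4, 0.5, 1), p)
  expect_lt(eq$C_free, 1e-4)
  # monotonicity: C_free non-decreasing in A_tot
  A_grid <- seq(0, 3, length.out = 12)
  cf <- solve_equilibrium(
    compartment_totals(R_tot = 1, C_tot = 0.5, A_tot = A_grid), p
  )$C_free
  expect_true(all(diff(cf) >= -1e-12))
})

test_that("buffered cAMP mode clamps the free concentration", {
  p <- prozone_params()
  eq <- solve_equilibrium(compartment_totals(1, 0.5, 0.2), p,
                          camp_mode = "buffered")
  expect_equal(eq$A_free, 0.2)
  expect_lt(eq$resid_C, 1e-9)
})

test_that("default activity curve is biphasic with a below-baseline tail", {
  curve <- activity_vs_R(seq(0, 10, length.out = 200))
  opt <- find_optimum(curve)
  expect_true(opt$interior_max)
  expect_gt(opt$activity_opt, opt$baseline)
  expect_lt(curve$activity[nrow(curve)], opt$baseline)
  expect_false(is.na(opt$R_x_below_baseline))
  expect_true(all(curve$activity >= 0))
  expect_identical(glance(curve), opt)
})

test_that("activity curve edge cases and validation", {
  expect_equal(nrow(activity_vs_R(numeric())), 0)
  expect_error(activity_vs_R(c(1, 0.5)), "sorted")
  expect_error(activity_vs_R(c(0, -1)), "non-negative")
  expect_error(activity_vs_R(c(0, 1), rho = 2), "rho")

  # pure sequestration limit: no co-recruited C, no cAMP -> monotone
  # non-increasing activity (brute force over the grid)
  curve <- activity_vs_R(seq(0, 5, length.out = 60),
                         basal = compartment_totals(0.1, 0.1, 0), rho = 0)
  expect_true(all(diff(curve$activity) <= 1e-12))
})

test_that("find_optimum ties break toward smaller R_x", {
  dec <- tibble::tibble(R_x = 0:5, activity = 6:1, baseline = 6)
  expect_equal(find_optimum(dec)$R_x_opt, 0)
  flat <- tibble::tibble(R_x = 0:5, activity = rep(1, 6), baseline = 1)
  expect_equal(find_optimum(flat)$R_x_opt, 0)
  expect_error(find_optimum(flat[0, ]), "non-empty")
})
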