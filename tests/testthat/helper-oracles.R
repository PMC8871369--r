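# Independent oracles used across tests.

# Mass-action ODE relaxation oracle for the membrane binding equilibrium.
# All six protomer microstates are explicit species; rate constants are
# chosen so that every reaction's equilibrium constant matches the
# partition-function weights (detailed balance on the thermodynamic cycle):
#   R[0,a] + C <-> R[1,a]    Kd = K_C * alpha^a
#   R[c,a] + A <-> R[c,a+1]  on ~ (2-a), off ~ (a+1), per-site Kd = K_A * alpha^c
ode_relax_oracle <- function(R_tot, C_tot, A_tot, K_C, K_A, alpha,
                             t_end = 2e4, kon = 100) {
  rhs <- function(t, x, p) {
    R <- matrix(x[1:6], nrow = 2) # rows c = 0,1; cols a = 0,1,2
    Cf <- x[7]; Af <- x[8]
    dR <- matrix(0, 2, 3); dC <- 0; dA <- 0
    for (a in 0:2) { # C binding/unbinding
      f <- kon * (R[1, a + 1] * Cf - K_C * alpha^a * R[2, a + 1])
      dR[1, a + 1] <- dR[1, a + 1] - f
      dR[2, a + 1] <- dR[2, a + 1] + f
      dC <- dC - f
    }
    for (c in 0:1) for (a in 0:1) { # cAMP site binding/unbinding
      f <- kon * ((2 - a) * R[c + 1, a + 1] * Af -
                    (a + 1) * K_A * alpha^c * R[c + 1, a + 2])
      dR[c + 1, a + 1] <- dR[c + 1, a + 1] - f
      dR[c + 1, a + 2] <- dR[c + 1, a + 2] + f
      dA <- dA - f
    }
    list(c(as.vector(dR), dC, dA))
  }
  x0 <- c(R_tot, 0, 0, 0, 0, 0, C_tot, A_tot)
  sol <- deSolve::lsoda(x0, times = c(0, t_end), func = rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  xf <- sol[nrow(sol), -1]
  list(C_free = unname(xf[7]), A_free = unname(xf[8]))
}

# closed-form positive root of C + R*C/(K_C + C) = C_tot (alpha = 1, no cAMP
# coupling of C binding)
quadratic_C_free <- function(R_tot, C_tot, K_C) {
  b <- K_C + R_tot - C_tot
  (-b + sqrt(b^2 + 4 * K_C * C_tot)) / 2
}
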