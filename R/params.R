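#' Binding parameters of the membrane PKA protomer model
#'
#' The membrane compartment is modelled as a pool of independent PKA-R
#' protomers, each carrying one catalytic-subunit (PKA-C) site and two cAMP
#' sites. `prozone_params()` collects the equilibrium constants of that
#' protomer together with the thermodynamic coupling between the two ligands.
#'
#' Each bound cAMP multiplies the affinity of the protomer for PKA-C by
#' `1/alpha` (and, by the thermodynamic cycle, bound PKA-C weakens cAMP
#' binding by the same factor). `alpha = 1` decouples the two ligands;
#' large `alpha` reproduces the physiological antagonism in which cAMP
#' loading releases the catalytic subunit.
#'
#' @param K_C Dissociation constant of PKA-C from a cAMP-free protomer (uM).
#' @param K_A Per-site cAMP dissociation constant on a PKA-C-free protomer
#'   (uM).
#' @param alpha Dimensionless allosteric coupling factor per bound cAMP;
#'   must be >= 1.
#'
#' @return A one-row tibble of class `pka_binding_params` with columns
#'   `K_C`, `K_A`, `alpha` and `n_A` (number of cAMP sites, fixed at 2).
#' @examples
#' prozone_params()
#' prozone_params(K_C = 0.05, alpha = 50)
#' @export
prozone_params <- function(K_C = 0.01, K_A = 0.1, alpha = 100) {
  check_scalar(K_C, "K_C", positive = TRUE)
  check_scalar(K_A, "K_A", positive = TRUE)
  check_scalar(alpha, "alpha")
  if (alpha < 1) {
    abort("`alpha` must be >= 1 (cAMP binding cannot strengthen C binding).")
  }
  out <- tibble(K_C = K_C, K_A = K_A, alpha = alpha, n_A = 2L)
  class(out) <- c("pka_binding_params", class(out))
  out
}

#' Conserved totals of the membrane compartment
#'
#' Total concentrations of PKA-R protomers, catalytic subunit and cAMP in
#' the membrane compartment. These are the conserved quantities of
#' [solve_equilibrium()]; free and bound species are derived from them.
#'
#' @param R_tot Total PKA-R protomer concentration (uM).
#' @param C_tot Total catalytic subunit concentration (uM).
#' @param A_tot Total cAMP concentration (uM).
#'
#' @return A one-row tibble of class `pka_totals`. Vectors of equal length
#'   (or length 1, recycled) give a multi-row tibble; [solve_equilibrium()]
#'   solves each row independently.
#' @examples
#' compartment_totals(R_tot = 0.1, C_tot = 0.1, A_tot = 1)
#' @export
compartment_totals <- function(R_tot = 0.1, C_tot = 0.1, A_tot = 1) {
  for (nm in c("R_tot", "C_tot", "A_tot")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      abort(sprintf("`%s` must be finite, non-negative numeric.", nm))
    }
  }
  out <- tibble(R_tot = R_tot, C_tot = C_tot, A_tot = A_tot)
  class(out) <- c("pka_totals", class(out))
  out
}

# shared scalar validator
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}
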