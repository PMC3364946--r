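#' Calibrated concentration-offset parameter g
#'
#' The per-pair free energy assigns one value to Watson-Crick pairs (`g`) and
#' another to mismatches (`g + delta_eps`), in thermal units. At equilibrium
#' the pairing distribution must be the Boltzmann distribution of a two-level
#' system with a ground state and `z - 1` degenerate mismatch states with gap
#' `delta_eps`; because g absorbs the normalizing partition function, the
#' calibrated value is `g = log(1 + (z-1) exp(-delta_eps))`. The two factors
#' are the energetic cost of a mismatch and the entropic gain of having
#' `z - 1` of them.
#'
#' @param delta_eps Mismatch free-energy penalty in units of kT (>= 0).
#' @param ntp_types Number of competing monomer species `z` (default 4).
#' @return Calibrated `g` (thermal units).
#' @export
calibrate_g <- function(delta_eps, ntp_types = 4L) {
  stopifnot(delta_eps >= 0)
  log(1 + (ntp_types - 1) * exp(-delta_eps))
}

#' Thermodynamic condition of the monomer-addition step
#'
#' Bundles the chemical driving of templated polymerization: the dimensionless
#' control `gamma` (relative reaction quotient of the NTP -> chain + PPi step;
#' `gamma = 1` at equilibrium, `gamma -> Inf` far from equilibrium), the
#' equilibrium constant `K_eq` used by closed-system (starvation) bookkeeping,
#' the mismatch free-energy penalty `delta_eps`, and the concentration-offset
#' parameter `g` of the per-pair free energy. `g` is stored, not recomputed,
#' so off-calibration values can be probed; by default it is calibrated via
#' [calibrate_g()] so that the stationary velocity vanishes exactly at
#' `gamma = 1`.
#'
#' The nominal driving force of the condition is `A = log(gamma)` (zero at
#' equilibrium, strictly increasing, `-Inf` as `gamma -> 0+`): the force an
#' ideal reservoir at that composition exerts. The force reported with
#' mean-field solutions and curves is the realized entropy production per
#' monomer, which reduces to zero at `gamma = 1` and is obtained from the
#' stationary pairing distribution.
#'
#' @param gamma Driving-force control, > 0. Alternatively supply `A_nominal`.
#' @param A_nominal Nominal force `log(gamma)`; used if `gamma` missing.
#' @param K_eq Equilibrium constant of the monomer-addition step (dimensionless
#'   in the concentration units of the rate tables); default 10.
#' @param delta_eps Mismatch penalty in kT; default 0.5, a terminal-mismatch
#'   duplex destabilization of ~0.3 kcal/mol at 310 K, the scale measured for
#'   DNA and RNA terminal mismatches.
#' @param g Concentration-offset parameter; default [calibrate_g()].
#' @param ntp_types Number of monomer species (4).
#' @return Object of class `thermo_condition`.
#' @examples
#' cond <- thermo_condition(gamma = 100)
#' nominal_force(cond)
#' @export
thermo_condition <- function(gamma = NULL, A_nominal = NULL, K_eq = 10,
                             delta_eps = 0.5, g = NULL, ntp_types = 4L) {
  if (is.null(gamma)) {
    if (is.null(A_nominal)) stop("supply gamma or A_nominal")
    gamma <- exp(A_nominal)
  }
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive and finite")
  stopifnot(delta_eps >= 0, K_eq > 0)
  if (is.null(g)) g <- calibrate_g(delta_eps, ntp_types)
  structure(list(gamma = gamma, K_eq = K_eq, delta_eps = delta_eps, g = g,
                 ntp_types = as.integer(ntp_types)),
            class = "thermo_condition")
}

#' @export
print.thermo_condition <- function(x, ...) {
  cat(sprintf(
    "<thermo_condition> gamma = %.6g (A_nominal = %.4g), K_eq = %.3g, delta_eps = %.3g kT, g = %.4g\n",
    x$gamma, log(x$gamma), x$K_eq, x$delta_eps, x$g))
  invisible(x)
}

#' Nominal driving force of a condition
#'
#' `A = log(gamma)`: zero at equilibrium, strictly increasing in `gamma`,
#' `-Inf` as `gamma -> 0+`.
#'
#' @param cond A [thermo_condition()].
#' @return Numeric force in kT per monomer.
#' @export
nominal_force <- function(cond) log(cond$gamma)

#' Per-pair free energy of nucleotide addition
#'
#' Free energy change (thermal units, at `gamma = 1`) for adding incoming base
#' `n_in` against template base `n_tmpl`: `g` for the Watson-Crick pair,
#' `g + delta_eps` for any of the three mismatches. Only the correct/mismatch
#' classification matters, so Watson-Crick pairs share one value and
#' mismatches another, differing by `delta_eps`.
#'
#' @param cond A [thermo_condition()].
#' @param n_in,n_tmpl Base letters, or both missing to get the full 4x4
#'   matrix via `free_energy_matrix()`.
#' @param alphabet Alphabet preset or list; default RNA.
#' @return Numeric free energy (kT).
#' @export
per_pair_free_energy <- function(cond, n_in, n_tmpl, alphabet = "rna") {
  if (is.character(alphabet)) alphabet <- .alphabets[[alphabet]]
  if (!(n_in %in% alphabet$bases) || !(n_tmpl %in% alphabet$bases))
    stop(sprintf("unknown base: alphabet is {%s}", paste(alphabet$bases, collapse = ",")))
  is_wc <- alphabet$complement[[n_tmpl]] == n_in
  cond$g + if (is_wc) 0 else cond$delta_eps
}

#' @rdname per_pair_free_energy
#' @param rates A [rate_table()] supplying the alphabet/complement map.
#' @export
free_energy_matrix <- function(cond, rates) {
  dg <- matrix(cond$g + cond$delta_eps, 4, 4, dimnames = dimnames(rates$k_f))
  dg[cbind(.wc_index(rates), 1:4)] <- cond$g
  dg
}

#' Backward (excision) rates from forward rates and the driving force
#'
#' Local detailed balance ties each backward rate to its forward rate through
#' the per-pair free energy and the driving control:
#' `k_b(n'|n) = k_f(n'|n) * exp(dG(n'|n)) / gamma`. At `gamma = 1` with the
#' calibrated `g` this is exactly the detailed-balance point (stationary
#' velocity zero, Boltzmann pairing distribution); as `gamma -> Inf` all
#' backward rates vanish.
#'
#' @param rates A [rate_table()] of forward rates.
#' @param cond A [thermo_condition()].
#' @return 4x4 matrix of backward rates with the same dimnames as `k_f`.
#' @export
backward_rates <- function(rates, cond) {
  if (cond$gamma <= 0) stop("gamma must be positive")
  rates$k_f * exp(free_energy_matrix(cond, rates)) / cond$gamma
}

#' Invert the detailed-balance relation
#'
#' Recovers the forward table from a backward-rate matrix produced by
#' [backward_rates()]; a round-trip identity used to validate the relation.
#'
#' @param k_b 4x4 backward-rate matrix.
#' @inheritParams backward_rates
#' @export
forward_from_backward <- function(k_b, rates, cond) {
  k_b * cond$gamma / exp(free_energy_matrix(cond, rates))
}
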