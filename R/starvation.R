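## Starvation process: population growth in a closed system. Each monomer
## addition consumes one NTP and releases one PPi, so growth lowers the
## driving force from its initial value A0 until equilibrium (A = 0), where
## growth stops. With the fractional population size n (relative to the
## asymptotic population at equilibrium) the force follows in closed form
## from the reaction quotient of the depleted medium.

#' Driving force along an idealized starvation process
#'
#' With initial force `A0 = log(K_eq [NTP]0 / [PPi]0)` and rapid mixing, the
#' force at fractional population size `n` (0 = start, 1 = equilibrium
#' endpoint) is `A(n) = log(K (1 - n u) / (K e^{-A0} + n u))` with
#' `u = K (1 - e^{-A0}) / (1 + K)` the fraction of the initial NTP pool
#' consumed at equilibrium. `A` decreases strictly from `A0` to 0.
#'
#' @param n Fractional population size(s) in [0, 1].
#' @param A0 Initial force (kT per monomer, > 0).
#' @param K_eq Equilibrium constant of the monomer-addition step.
#' @return Force A(n) (kT).
#' @export
starvation_force <- function(n, A0, K_eq) {
  stopifnot(A0 > 0, K_eq > 0, all(n >= -1e-12), all(n <= 1 + 1e-12))
  u <- K_eq * (1 - exp(-A0)) / (1 + K_eq)
  log(K_eq * (1 - n * u) / (K_eq * exp(-A0) + n * u))
}

#' @rdname starvation_force
#' @details `starvation_force_deriv` gives dA/dn, the right-hand side of the
#'   depletion balance that `starvation_force` solves in closed form; an
#'   independent numerical integration of it must reproduce the closed form.
#' @export
starvation_force_deriv <- function(n, A0, K_eq) {
  u <- K_eq * (1 - exp(-A0)) / (1 + K_eq)
  -u * (1 / (1 - n * u) + 1 / (K_eq * exp(-A0) + n * u))
}

#' Simulate an idealized (quasistatic) starvation process
#'
#' Follows the realized stationary state of a population at fixed inverse
#' fidelity while the force decays from `A0` to 0 through monomer depletion:
#' at each fractional size `n` the state is the higher-velocity branch at
#' `A(n)` and the mean fitness is the infinite-population quasispecies value.
#' Phase-boundary crossings (C-L, L-G) along the process are recorded.
#'
#' @param rates A [rate_table()] already rescaled to the Q of interest.
#' @param cond A [thermo_condition()] supplying `K_eq`, `delta_eps`, `g`.
#' @param A0 Initial force (kT, > 0).
#' @param landscape A [fitness_landscape()].
#' @param n_grid Grid over the fractional population size (default 101
#'   points, endpoint n = 1 included; A(1) = 0 means w_bar(1) = 0).
#' @param template_dist Template base distribution.
#' @param n_gamma Gamma-grid size for the underlying curves.
#' @return Object of class `starvation_trajectory`: data.frame `n, A, v,
#'   eps2, w_bar, phase` with attributes `transitions` (data.frame `n, type`)
#'   and `A0`.
#' @export
starvation_run <- function(rates, cond, A0, landscape, n_grid = NULL,
                           template_dist = NULL, n_gamma = 301) {
  if (is.null(n_grid)) n_grid <- seq(0, 1, length.out = 101)
  stopifnot(all(diff(n_grid) > 0), abs(n_grid[1]) < 1e-12,
            abs(n_grid[length(n_grid)] - 1) < 1e-12)
  A_n <- starvation_force(n_grid, A0, cond$K_eq)
  A_n[length(A_n)] <- 0
  cv <- elongation_curves(rates, cond, template_dist,
                          A_max = A0 + 0.5, n_grid = n_gamma)
  st <- realize_at_force(cv, pmax(A_n, 0), refine = FALSE)
  ## at A -> 0 the curves start at gamma = 1 (v = 0): fill the endpoint
  st$v[!is.finite(st$v) & A_n <= min(cv$A) + 1e-9] <- 0
  e2s <- error_threshold(landscape$sigma, landscape$L)$eps2_star
  bist_A <- attr(cv, "bistable_A")
  A_spin <- if (!is.null(bist_A)) bist_A[1] else -Inf
  ## fitness scale: landscape rate constant x relative velocity (the Q-table
  ## sets fidelity and the velocity response, not the genotypes' rate scale)
  k_bar <- reduced_kinetics(rates, template_dist)$k_bar
  w <- landscape$k0 * (st$v / k_bar) / (2 * landscape$L) *
    mean_fitness(st$eps2, landscape)
  w[A_n <= 0] <- 0
  phase <- ifelse(is.finite(st$eps2) & st$eps2 < e2s, "C",
                  ifelse(A_n < A_spin, "G", "L"))
  phase[A_n <= 0] <- "G" # equilibrium endpoint: no moving state
  tr <- data.frame(n = n_grid, A = A_n, v = st$v, eps2 = st$eps2,
                   w_bar = w, phase = phase)
  ch <- which(phase[-1] != phase[-length(phase)])
  transitions <- data.frame(
    n = (n_grid[ch] + n_grid[ch + 1]) / 2,
    type = paste(phase[ch], phase[ch + 1], sep = "-"))
  structure(tr, class = c("starvation_trajectory", "data.frame"),
            transitions = transitions, A0 = A0, landscape = landscape)
}

#' Process-averaged mean fitness
#'
#' Trapezoidal average of the mean fitness over the fractional population
#' size of a starvation trajectory.
#'
#' @param traj A [starvation_run()] result (or any data.frame with `n` and
#'   `w_bar`).
#' @return Scalar `<w_bar>`.
#' @export
starvation_mean_fitness <- function(traj) {
  n <- traj$n; w <- traj$w_bar
  ok <- is.finite(w)
  n <- n[ok]; w <- w[ok]
  sum(diff(n) * (w[-1] + w[-length(w)]) / 2) / (max(n) - min(n))
}

#' Starvation fidelity-threshold map
#'
#' For each initial force `A0` and equilibrium constant, the threshold
#' inverse fidelity below which the process-averaged mean fitness increases
#' with decreasing Q (`d<w_bar>/dQ < 0`), i.e. below which repeated
#' starvation cycles bias evolution toward higher fidelity. The threshold is
#' the zero crossing of the centered-difference slope over the Q grid.
#'
#' @param base_rates A [rate_table()] to rescale over `Q_grid`.
#' @param A0_grid Initial forces (kT).
#' @param Q_grid Inverse-fidelity grid (log-spaced recommended).
#' @param landscape A [fitness_landscape()].
#' @param cond Template [thermo_condition()]; its `K_eq` is overridden by
#'   each value of `K_eq_values`.
#' @param K_eq_values Equilibrium constants to scan.
#' @param template_dist Template base distribution.
#' @param n_gamma,n_points Resolution knobs (gamma grid; starvation n grid).
#' @return data.frame `K_eq, A0, Q_star` (NA when the slope never changes
#'   sign) with attribute `w_avg` (array Q x A0 x K_eq).
#' @export
starvation_threshold_map <- function(base_rates, A0_grid, Q_grid, landscape,
                                     cond, K_eq_values = cond$K_eq,
                                     template_dist = NULL, n_gamma = 201,
                                     n_points = 61) {
  n_grid <- seq(0, 1, length.out = n_points)
  w_avg <- array(NA_real_, c(length(Q_grid), length(A0_grid), length(K_eq_values)),
                 dimnames = list(NULL, NULL, NULL))
  for (iq in seq_along(Q_grid)) {
    rt <- rescale_fidelity(base_rates, Q_grid[iq], template_dist)
    for (ik in seq_along(K_eq_values)) {
      ci <- cond; ci$K_eq <- K_eq_values[ik]
      for (ia in seq_along(A0_grid)) {
        tr <- starvation_run(rt, ci, A0_grid[ia], landscape, n_grid,
                             template_dist, n_gamma)
        w_avg[iq, ia, ik] <- starvation_mean_fitness(tr)
      }
    }
  }
  lq <- log(Q_grid)
  out <- expand.grid(A0 = A0_grid, K_eq = K_eq_values)
  out$Q_star <- NA_real_
  for (r in seq_len(nrow(out))) {
    ia <- match(out$A0[r], A0_grid); ik <- match(out$K_eq[r], K_eq_values)
    w <- w_avg[, ia, ik]
    nq <- length(lq)
    slope <- rep(NA_real_, nq)
    slope[2:(nq - 1)] <- (w[3:nq] - w[1:(nq - 2)]) / (lq[3:nq] - lq[1:(nq - 2)])
    ok <- is.finite(slope)
    if (sum(ok) >= 3) {
      qs <- .first_crossing(lq[ok], slope[ok])
      if (is.finite(qs)) out$Q_star[r] <- exp(qs)
    }
  }
  out <- out[, c("K_eq", "A0", "Q_star")]
  attr(out, "w_avg") <- w_avg
  attr(out, "Q_grid") <- Q_grid
  out
}
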