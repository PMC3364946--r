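#' Single-peak fitness (and fidelity) landscape
#'
#' The Eigen single-peak landscape: one master genotype replicates at
#' `sigma >= 1` times the background rate constant `k0`; all other genotypes
#' are equivalent. Optionally the inverse fidelity follows the same
#' single-peak form: `Q_master` for reactions catalyzed by the master (the
#' better replicase) and `Q_background` for everyone else.
#'
#' @param L Genome length in bases (>= 1).
#' @param sigma Relative fitness of the master sequence (>= 1).
#' @param k0 Base rate-scale constant (units of the rate tables; default 1,
#'   i.e. time measured in units of 1/k_bar).
#' @param master Master genotype as a character vector of bases, or NULL for
#'   an unspecified master index.
#' @param fidelity_peak Optional list `list(Q_master=, Q_background=)` with
#'   `Q_master <= Q_background`.
#' @return Object of class `fitness_landscape`.
#' @export
fitness_landscape <- function(L, sigma, k0 = 1, master = NULL,
                              fidelity_peak = NULL) {
  stopifnot(L >= 1, sigma >= 1, k0 > 0)
  if (!is.null(fidelity_peak)) {
    stopifnot(all(c("Q_master", "Q_background") %in% names(fidelity_peak)))
    if (fidelity_peak$Q_master > fidelity_peak$Q_background)
      stop("Q_master must not exceed Q_background (the master is the better replicase)")
  }
  if (!is.null(master)) stopifnot(length(master) == L)
  structure(list(L = as.integer(L), sigma = sigma, k0 = k0, master = master,
                 fidelity_peak = fidelity_peak),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("<fitness_landscape> L = %d, sigma = %g, k0 = %g%s\n",
              x$L, x$sigma, x$k0,
              if (!is.null(x$fidelity_peak))
                sprintf(", fidelity peak Q: %g (master) / %g (background)",
                        x$fidelity_peak$Q_master, x$fidelity_peak$Q_background)
              else ""))
  invisible(x)
}

#' Replication rate of a genotype
#'
#' Completing a replication cycle requires a pair of template-directed
#' syntheses (only one polarity is catalytic), i.e. the addition of 2L
#' nucleotides, so the rate is fitness x base rate x relative elongation
#' velocity / (2L).
#'
#' @param genotype_fitness Relative fitness (sigma for the master, 1 else).
#' @param k_bar Mean base incorporation rate of the genotype's kinetics.
#' @param v_rel Relative elongation velocity at the ambient force (v / k_bar,
#'   in (0, 1]).
#' @param L Genome length.
#' @return Replication rate (same units as `k_bar`).
#' @export
replication_rate <- function(genotype_fitness, k_bar, v_rel, L) {
  genotype_fitness * k_bar * v_rel / (2 * L)
}

#' Two-replication genome survival probability
#'
#' Probability of replicating L sites over two consecutive cycles without
#' error, under per-site independence: `(1 - eps2)^L`.
#'
#' @param eps2 Two-replication per-site error rate.
#' @param L Genome length.
#' @export
pair_survival <- function(eps2, L) (1 - eps2)^L

#' Error threshold of the single-peak quasispecies
#'
#' The master and mutant branches of the mean fitness cross where
#' `sigma * (1 - eps2)^L = 1`, giving the threshold two-replication error rate
#' `eps2_star = 1 - sigma^(-1/L)`. The per-replication threshold `eps_star`
#' follows by inverting the per-site pair-composition
#' `eps2 = 1 - (1-eps)^2 - eps^2/3` (an error in the first copy can be
#' compensated in the copy-back).
#'
#' @param sigma Master relative fitness (>= 1).
#' @param L Genome length.
#' @return List `eps2_star`, `eps_star`.
#' @export
error_threshold <- function(sigma, L) {
  stopifnot(sigma >= 1, L >= 1)
  e2 <- 1 - sigma^(-1 / L)
  e1 <- 0.75 * (1 - sqrt(pmax(1 - 4 * e2 / 3, 0)))
  list(eps2_star = e2, eps_star = e1)
}

#' Mean fitness of the infinite-population quasispecies
#'
#' Below the error threshold the population is dominated by the master
#' species, with mean fitness `sigma * (1 - eps2)^L` in units of the base
#' replication rate `k0 * v_rel / (2L)`; above it, by the mutant cloud with
#' relative mean fitness 1. The two branches meet continuously at the
#' threshold of [error_threshold()].
#'
#' @param eps2 Two-replication per-site error rate(s), in [0, 1].
#' @param landscape A [fitness_landscape()].
#' @param v_rel Relative elongation velocity multiplying the rate scale
#'   (default 1).
#' @param relative If TRUE (default) return the fitness in units of the
#'   background replication rate `k0 v_rel / (2L)`; otherwise multiply it in.
#' @return Mean fitness w_bar.
#' @export
mean_fitness <- function(eps2, landscape, v_rel = 1, relative = TRUE) {
  w_rel <- pmax(landscape$sigma * pair_survival(eps2, landscape$L), 1)
  if (relative) w_rel
  else w_rel * landscape$k0 * v_rel / (2 * landscape$L)
}

#' Time course of the master-sequence frequency (no back-mutation)
#'
#' Closed-form solution of the two-type linear quasispecies dynamics
#' (master replicating at `sigma*k*Q2` into itself and `sigma*k*(1-Q2)` into
#' the mutant cloud; mutants at `k`; back-mutation neglected), by
#' eigen-decomposition of the 2x2 growth matrix.
#'
#' @param sigma Master relative fitness.
#' @param Q2 Probability of an error-free replication pair of the whole
#'   genome (`(1-eps2)^L`).
#' @param k Mutant replication rate (sets the time unit; default 1).
#' @param t_grid Times at which to evaluate.
#' @param x0 Initial master frequency.
#' @return Numeric vector x_m(t) on `t_grid`.
#' @export
master_frequency_timecourse <- function(sigma, Q2, k = 1, t_grid, x0) {
  stopifnot(Q2 >= 0, Q2 <= 1, x0 >= 0, x0 <= 1)
  l1 <- sigma * k * Q2
  l2 <- k
  nm <- x0 * exp(l1 * t_grid)
  if (abs(l1 - l2) > 1e-12 * max(l1, l2)) {
    nu <- (1 - x0) * exp(l2 * t_grid) +
      x0 * sigma * (1 - Q2) * k * (exp(l1 * t_grid) - exp(l2 * t_grid)) / (l1 - l2)
  } else {
    nu <- (1 - x0) * exp(l2 * t_grid) +
      x0 * sigma * (1 - Q2) * k * t_grid * exp(l2 * t_grid)
  }
  nm / (nm + nu)
}

#' Stationary master-sequence frequency
#'
#' The t -> Inf limit of [master_frequency_timecourse()]:
#' `max(0, (sigma*Q2 - 1)/(sigma - 1))`; zero at or below the error threshold
#' (`sigma*Q2 <= 1`), one for perfect fidelity.
#'
#' @inheritParams master_frequency_timecourse
#' @export
stationary_master_frequency <- function(sigma, Q2) {
  if (sigma == 1) return(ifelse(Q2 >= 1, 1, 0))
  pmin(pmax((sigma * Q2 - 1) / (sigma - 1), 0), 1)
}

#' Expected sequence drift under Jukes-Cantor substitution
#'
#' Cumulative expected fractional Hamming distance from an ancestral sequence
#' after `generations` replication pairs with per-site error rate `eps2`
#' (uniform over the 3 alternative bases):
#' `d = (3/4) * (1 - (1 - 4*eps2/3)^generations)`, saturating at 3/4.
#'
#' @param eps2 Per-site two-replication error rate.
#' @param generations Number of replication pairs (nonnegative).
#' @param L Genome length (the expectation per site does not depend on it;
#'   kept so callers can convert to absolute distances `d * L`).
#' @return Expected fractional Hamming distance in [0, 3/4].
#' @export
hamming_drift <- function(eps2, generations, L = NULL) {
  0.75 * (1 - (1 - 4 * eps2 / 3)^generations)
}

#' Generations to reach a target sequence divergence
#'
#' Inverse of [hamming_drift()] in `generations`.
#'
#' @param eps2 Per-site error rate per generation.
#' @param d_target Target fractional Hamming distance (< 3/4).
#' @export
generations_to_drift <- function(eps2, d_target) {
  stopifnot(d_target < 0.75)
  log(1 - d_target / 0.75) / log(1 - 4 * eps2 / 3)
}

#' Exact quasispecies stationary state on Hamming classes
#'
#' Full-matrix eigen solve of the single-peak Eigen model lumped onto Hamming
#' distance classes (exact for permutation-symmetric landscapes), including
#' back-mutation. Used as the independent oracle for the closed forms that
#' neglect back-mutation.
#'
#' @param sigma Master relative fitness.
#' @param eps_site Per-site error rate per replication event.
#' @param L Genome length (small; the matrix is (L+1) x (L+1)).
#' @return List `x_master` (stationary master frequency), `w_bar`
#'   (mean fitness in units of the background rate), `freq` (class
#'   frequencies).
#' @export
quasispecies_eigen <- function(sigma, eps_site, L) {
  e <- eps_site
  ## per-site transition probabilities relative to the master base:
  ## match -> match 1-e, match -> mismatch e;
  ## mismatch -> match e/3, mismatch -> mismatch 1 - e/3
  P <- matrix(0, L + 1, L + 1) # P[d' + 1, d + 1] = P(child class d' | parent d)
  for (d in 0:L) {
    m <- L - d # matched sites of the parent
    pm <- stats::dbinom(0:m, m, e)        # new mismatches among matched sites
    pb <- stats::dbinom(0:d, d, e / 3)    # back-corrections among mismatched
    for (i in 0:m) for (j in 0:d) {
      dp <- d + i - j
      P[dp + 1, d + 1] <- P[dp + 1, d + 1] + pm[i + 1] * pb[j + 1]
    }
  }
  r <- c(sigma, rep(1, L))
  W <- P %*% diag(r)
  eg <- eigen(W)
  i <- which.max(Re(eg$values))
  v <- abs(Re(eg$vectors[, i]))
  v <- v / sum(v)
  list(x_master = v[1], w_bar = Re(eg$values[i]), freq = v)
}
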