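## Stationary mean-field theory of reversible templated elongation.
##
## For each template base n the pairing distribution obeys
##   q(n'|n) = k_f(n'|n) / (v_n + k_b(n'|n))            (generalized Boltzmann)
## with v_n fixed by the normalization sum(q(.|n)) = 1, a quartic in v_n with a
## unique root on the physically admissible branch v_n > -min(k_b). The theory
## is exact when the rate set is independent of the template base identity
## ("symmetric template models").

## unique admissible root of sum(kf/(v+kb)) = 1, bracketed then Newton-polished
.solve_column <- function(kf, kb, rel_tol = 1e-12) {
  stopifnot(all(kf > 0), all(kb >= 0))
  K <- sum(kf)
  lo <- -min(kb)
  f <- function(v) sum(kf / (v + kb)) - 1
  ## move off the pole; f is strictly decreasing on (lo, Inf)
  span <- max(K, min(kb[kb > 0], K))
  eps <- max(1e-14 * span, lo * -1e-14, .Machine$double.xmin)
  lower <- lo + eps
  while (f(lower) < 0) { # pole extremely sharp: tighten toward it
    eps <- eps / 8
    lower <- lo + eps
    if (eps < .Machine$double.xmin * 4) break
  }
  upper <- K
  if (f(upper) > 0) upper <- K + sum(kb) # only when some kb huge; f(K+sum kb)<0 always
  v <- uniroot(f, c(lower, upper), tol = 1e-10 * span)$root
  for (i in 1:4) { # Newton polish to machine precision
    fv <- sum(kf / (v + kb)) - 1
    dv <- -sum(kf / (v + kb)^2)
    step <- fv / dv
    if (!is.finite(step)) break
    v_new <- v - step
    if (v_new <= lo) v_new <- (v + lo) / 2
    v <- v_new
    if (abs(step) <= rel_tol * max(abs(v), span * 1e-6)) break
  }
  resid <- sum(kf / (v + kb)) - 1
  if (!is.finite(resid) || abs(resid) > 1e-6)
    stop(sprintf("no admissible stationary root found (residual %.3g)", resid))
  v
}

#' Stationary solution for one template-base subproblem
#'
#' Solves the self-consistent pairing/velocity system for a single set of 4
#' forward and 4 backward rates (the exact solution for symmetric template
#' models, where the rates do not depend on the template base).
#'
#' @param k_f,k_b Length-4 positive forward rates and nonnegative backward
#'   rates for the 4 incoming bases.
#' @return List with `v` (nucleotide-addition velocity) and `q` (length-4
#'   pairing probabilities of the incoming bases, summing to 1).
#' @export
solve_symmetric <- function(k_f, k_b) {
  v <- .solve_column(k_f, k_b)
  q <- k_f / (v + k_b)
  q <- q / sum(q) # remove residual rounding; solver already makes sum(q)=1
  list(v = v, q = q)
}

#' Solve the mean-field elongation theory
#'
#' Computes the stationary pairing distribution, per-template-base and mean
#' velocities, single- and double-replication error rates, and the entropy
#' production per monomer (the thermodynamic force realized by the state) for
#' a rate table under a thermodynamic condition. Velocities and error rates
#' are template-averaged with the harmonic convention (summation over incoming
#' bases before the harmonic average); the entropy production uses the
#' arithmetic template average, since it is not a rate.
#'
#' @param rates A [rate_table()].
#' @param cond A [thermo_condition()].
#' @param template_dist Template base distribution (default uniform).
#' @return Object of class `meanfield_solution`: list with `q` (4x4, columns
#'   sum to 1), `v_n`, `v`, `eps_n`, `eps`, `eps2`, `A` (entropy production
#'   per monomer, kT), `gamma`, `rates`, `cond`, `template_dist`.
#' @examples
#' rt <- random_rate_table("jc", c(1, 0.02))
#' meanfield_solve(rt, thermo_condition(gamma = 1e6))
#' @export
meanfield_solve <- function(rates, cond, template_dist = NULL) {
  p <- .check_dist(template_dist)
  kf <- rates$k_f
  kb <- backward_rates(rates, cond)
  dg <- free_energy_matrix(cond, rates)
  wc <- .wc_index(rates)
  q <- matrix(NA_real_, 4, 4, dimnames = dimnames(kf))
  v_n <- numeric(4)
  for (j in 1:4) {
    s <- solve_symmetric(kf[, j], kb[, j])
    v_n[j] <- s$v
    q[, j] <- s$q
  }
  names(v_n) <- colnames(kf)
  eps_n <- 1 - q[cbind(wc, 1:4)]
  ## treat velocities within solver noise of 0 as the equilibrium point
  vscale <- max(colSums(kf))
  v0 <- abs(v_n) < 1e-11 * vscale
  if (all(v0[p > 0])) v <- 0
  else if (any(v_n[p > 0] > 0) && any(v_n[p > 0] < 0))
    stop("mixed-sign per-base velocities: no stationary moving state")
  else v <- .harmonic_mean(v_n, p)
  eps <- .harmonic_mean(eps_n, p)
  ## two-replication net error per site: copy then copy the copy back
  ret_n <- vapply(1:4, function(j) sum(q[, j] * q[j, ]), numeric(1))
  eps2_n <- 1 - ret_n
  eps2 <- .harmonic_mean(eps2_n, p)
  ## entropy production per monomer: monomer consumption + sequence disorder
  lg <- log(cond$gamma)
  term <- q * (lg - dg - ifelse(q > 0, log(q), 0))
  A <- sum(p * colSums(term))
  structure(list(q = q, v_n = v_n, v = v, eps_n = setNames(eps_n, colnames(kf)),
                 eps = eps, eps2 = eps2, A = A, gamma = cond$gamma,
                 rates = rates, cond = cond, template_dist = p),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf("<meanfield_solution> gamma = %.5g\n", x$gamma))
  cat(sprintf("  v = %.6g   eps = %.6g   eps2 = %.6g   A = %.6g kT\n",
              x$v, x$eps, x$eps2, x$A))
  invisible(x)
}

#' Closed-form limits of the elongation error rates
#'
#' At equilibrium the pairing distribution is Boltzmann, so the maximum error
#' rate depends only on the mismatch penalty and degeneracy:
#' `eps_max = (z-1) exp(-delta_eps) / (1 + (z-1) exp(-delta_eps))` (equal to
#' 3/4 when `delta_eps = 0` with the symmetric offset). Far from equilibrium
#' the backward rates vanish and the error rate reaches its lower bound
#' `eps_min = Q/(1+Q)`, which depends only on the forward rates. The
#' two-replication analogues follow from composing the limiting pairing
#' distributions over a copy and a copy-back.
#'
#' @inheritParams meanfield_solve
#' @return List `eps_min`, `eps_max`, `eps2_min`, `eps2_max`.
#' @export
meanfield_limits <- function(rates, cond, template_dist = NULL) {
  p <- .check_dist(template_dist)
  z <- cond$ntp_types
  em <- (z - 1) * exp(-cond$delta_eps) / (1 + (z - 1) * exp(-cond$delta_eps))
  rk <- reduced_kinetics(rates, template_dist)
  eps_min <- rk$Q / (1 + rk$Q)
  ## far-from-equilibrium pairing distribution is forward-rate proportional
  q_inf <- sweep(rates$k_f, 2, colSums(rates$k_f), "/")
  eps2_min_n <- vapply(1:4, function(j) 1 - sum(q_inf[, j] * q_inf[j, ]), numeric(1))
  eps2_min <- .harmonic_mean(eps2_min_n, p)
  eps2_max <- 1 - (1 - em)^2 - em^2 / (z - 1)
  list(eps_min = eps_min, eps_max = em, eps2_min = eps2_min, eps2_max = eps2_max)
}

#' Velocity and error-rate curves against the thermodynamic force
#'
#' Sweeps the control `gamma`, solves the mean-field theory at each value, and
#' re-indexes the results by the realized force `A` (entropy production per
#' monomer). Because `A(gamma)` need not be monotone, one force value can be
#' attained by several stationary states; monotone-in-A segments are grouped
#' into branches and branch multiplicity >= 2 flags bistability (the
#' liquid/gas dichotomy of the phase diagram).
#'
#' @inheritParams meanfield_solve
#' @param gamma_grid Increasing vector of gamma values; default a log grid
#'   from 1 to `exp(A_max + 2)`.
#' @param A_max Largest force of interest when `gamma_grid` is NULL
#'   (default 12 kT).
#' @param n_grid Grid size for the default gamma grid (default 301).
#' @return Object of class `elongation_curves`: a data.frame with columns
#'   `gamma, A, v, eps, eps2, branch_id` plus attributes `bistable` (logical)
#'   and `bistable_A` (force interval with branch multiplicity >= 2, or NULL).
#' @export
velocity_error_curves <- function(rates, cond, template_dist = NULL,
                                  gamma_grid = NULL, A_max = 12, n_grid = 301) {
  if (is.null(gamma_grid))
    gamma_grid <- exp(seq(0, A_max + 2, length.out = n_grid))
  sols <- lapply(gamma_grid, function(g) {
    ci <- cond; ci$gamma <- g
    meanfield_solve(rates, ci, template_dist)
  })
  df <- data.frame(gamma = gamma_grid,
                   A = vapply(sols, `[[`, numeric(1), "A"),
                   v = vapply(sols, `[[`, numeric(1), "v"),
                   eps = vapply(sols, `[[`, numeric(1), "eps"),
                   eps2 = vapply(sols, `[[`, numeric(1), "eps2"))
  ## branches = maximal runs where A is monotone in the gamma parameterization;
  ## steps below numerical noise inherit the previous direction
  dA <- diff(df$A)
  tol <- 1e-9 * max(abs(df$A), 1e-12)
  s <- sign(dA)
  s[abs(dA) < tol] <- NA
  if (is.na(s[1])) s[1] <- 1
  for (i in seq_along(s)[-1]) if (is.na(s[i])) s[i] <- s[i - 1]
  br <- integer(nrow(df)); br[1] <- 1L
  for (i in seq_along(s)) br[i + 1L] <- br[i] + as.integer(i > 1 && s[i] != s[i - 1])
  df$branch_id <- br
  bist_A <- NULL
  nb <- max(br)
  if (nb >= 2) {
    rng <- do.call(rbind, lapply(split(df$A, br), range))
    ## overlap between any two branches flags force values with multiple states
    for (i in seq_len(nb - 1)) for (j in seq(i + 1, nb)) {
      lo <- max(rng[i, 1], rng[j, 1]); hi <- min(rng[i, 2], rng[j, 2])
      if (hi > lo + 10 * tol) bist_A <- range(c(bist_A, lo, hi))
    }
  }
  structure(df, class = c("elongation_curves", "data.frame"),
            bistable = !is.null(bist_A), bistable_A = bist_A)
}

## interpolate (v, eps, eps2, gamma) on one monotone-in-A branch
.branch_interp <- function(bdf, A) {
  o <- order(bdf$A)
  b <- bdf[o, ]
  out <- lapply(c("v", "eps", "eps2", "gamma"),
                function(col) approx(b$A, b[[col]], xout = A, ties = "ordered")$y)
  names(out) <- c("v", "eps", "eps2", "gamma")
  out
}

#' Realized stationary state at a prescribed external force
#'
#' When several stationary branches coexist at one force, the state with the
#' higher velocity (larger entropy production rate) is the realized one. This
#' looks up, on precomputed curves, every branch covering the force `A` and
#' returns the higher-velocity state; the matching condition between the
#' state's entropy production and the imposed force is what selects `gamma`.
#'
#' @param curves An [velocity_error_curves()] result.
#' @param A Force value(s), kT per monomer.
#' @param refine If TRUE (default) the interpolated `gamma` is polished by a
#'   local root solve of `A(gamma) = A` and the state recomputed exactly.
#' @return data.frame with `A, v, eps, eps2, gamma, branch_id, n_branches`.
#' @export
realize_at_force <- function(curves, A, refine = TRUE) {
  stopifnot(inherits(curves, "elongation_curves"))
  rates <- attr(curves, "rates"); cond <- attr(curves, "cond")
  sp <- split(seq_len(nrow(curves)), curves$branch_id)
  out <- lapply(A, function(a) {
    best <- NULL; nb <- 0L
    for (idx in sp) {
      b <- curves[idx, , drop = FALSE]
      if (a < min(b$A) - 1e-12 || a > max(b$A) + 1e-12) next
      st <- .branch_interp(b, a)
      nb <- nb + 1L
      if (is.null(best) || (is.finite(st$v) && st$v > best$v))
        best <- c(st, branch_id = b$branch_id[1])
    }
    if (is.null(best))
      return(data.frame(A = a, v = NA, eps = NA, eps2 = NA, gamma = NA,
                        branch_id = NA, n_branches = 0L))
    data.frame(A = a, v = best$v, eps = best$eps, eps2 = best$eps2,
               gamma = best$gamma, branch_id = best$branch_id, n_branches = nb)
  })
  res <- do.call(rbind, out)
  if (refine && !is.null(rates) && !is.null(cond)) {
    for (i in seq_len(nrow(res))) {
      if (!is.finite(res$gamma[i])) next
      g <- .refine_gamma(rates, cond, attr(curves, "template_dist"),
                         res$A[i], res$gamma[i])
      if (is.finite(g)) {
        ci <- cond; ci$gamma <- g
        s <- meanfield_solve(rates, ci, attr(curves, "template_dist"))
        res$v[i] <- s$v; res$eps[i] <- s$eps; res$eps2[i] <- s$eps2
        res$gamma[i] <- g
      }
    }
  }
  res
}

## local solve of A(gamma) = A_target around a starting guess (log-gamma secant)
.refine_gamma <- function(rates, cond, template_dist, A_target, gamma0) {
  f <- function(lg) {
    ci <- cond; ci$gamma <- exp(lg)
    meanfield_solve(rates, ci, template_dist)$A - A_target
  }
  lg <- log(gamma0)
  h <- 1e-4
  for (i in 1:30) {
    f0 <- f(lg)
    if (abs(f0) < 1e-10) break
    d <- (f(lg + h) - f0) / h
    if (!is.finite(d) || d == 0) return(NA_real_)
    step <- f0 / d
    step <- max(min(step, 0.5), -0.5) # stay on the local branch
    lg <- lg - step
    if (abs(step) < 1e-13) break
  }
  if (abs(f(lg)) > 1e-6) return(NA_real_)
  exp(lg)
}

#' Curves with solver context attached
#'
#' Convenience wrapper around [velocity_error_curves()] that stores the rate
#' table, condition and template distribution as attributes so that
#' [realize_at_force()] can polish interpolated states by exact solves.
#'
#' @inheritParams velocity_error_curves
#' @export
elongation_curves <- function(rates, cond, template_dist = NULL, ...) {
  cv <- velocity_error_curves(rates, cond, template_dist, ...)
  attr(cv, "rates") <- rates
  attr(cv, "cond") <- cond
  attr(cv, "template_dist") <- .check_dist(template_dist)
  cv
}

#' Fidelity response at a fixed external force
#'
#' For a family of tables obtained from `base_rates` by uniformly rescaling
#' the mismatch rates to a grid of inverse fidelities Q, computes the realized
#' single-molecule observables at one external force and returns spline
#' interpolators in log10(Q). Used to look up genotype-dependent per-site
#' error rates cheaply during population simulations.
#'
#' @param base_rates A [rate_table()] to rescale.
#' @param cond A [thermo_condition()] (its gamma is ignored; the force matters).
#' @param A External force (kT per monomer).
#' @param Q_grid Grid of inverse fidelities (default 80 log-spaced points
#'   between 1e-4 and 1).
#' @param template_dist Template base distribution.
#' @return List with the grid data.frame `grid` and functions `eps(Q)`,
#'   `eps2(Q)`, `v_rel(Q)` (velocity in units of the table's k_bar).
#' @export
fidelity_response <- function(base_rates, cond, A, Q_grid = NULL,
                              template_dist = NULL) {
  if (is.null(Q_grid)) Q_grid <- 10^seq(-4, 0, length.out = 80)
  rows <- lapply(Q_grid, function(Q) {
    rt <- rescale_fidelity(base_rates, Q, template_dist)
    cv <- elongation_curves(rt, cond, template_dist, A_max = A + 2, n_grid = 201)
    st <- realize_at_force(cv, A)
    k_bar <- reduced_kinetics(rt, template_dist)$k_bar
    data.frame(Q = Q, v = st$v, v_rel = st$v / k_bar, eps = st$eps, eps2 = st$eps2)
  })
  grid <- do.call(rbind, rows)
  ok <- stats::complete.cases(grid)
  g <- grid[ok, ]
  mk <- function(col) {
    f <- splinefun(log10(g$Q), g[[col]], method = "natural")
    function(Q) f(log10(Q))
  }
  list(grid = grid, eps = mk("eps"), eps2 = mk("eps2"), v_rel = mk("v_rel"))
}
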