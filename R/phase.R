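## Phase behaviour in the (Q, A) plane. Q (inverse fidelity) plays the role
## of temperature, A (thermodynamic force per monomer) of pressure, and the
## elongation velocity of volume. Phases:
##   G  "gas":        low velocity, high error (realized below the spinodal)
##   L  "liquid":     high velocity, low error, no stable genome
##   C  "crystalline": master-sequence-dominated quasispecies (eps2 below the
##                     error threshold of the single-peak landscape)

## per-Q summary: curves, realized states on the A grid, L-branch spinodal
.phase_column <- function(base_rates, Q, A_grid, cond, template_dist, n_grid) {
  rt <- rescale_fidelity(base_rates, Q, template_dist)
  cv <- elongation_curves(rt, cond, template_dist,
                          A_max = max(A_grid) + 0.5, n_grid = n_grid)
  st <- realize_at_force(cv, A_grid, refine = FALSE)
  bist <- isTRUE(attr(cv, "bistable"))
  A_spin <- eps2_L_end <- NA_real_
  if (bist) {
    ## spinodal = terminus of the branch that continues to gamma -> Inf (the
    ## high-velocity L branch); its error rate there decides whether the C
    ## phase melts through L or sublimates straight into G
    lb <- cv[cv$branch_id == max(cv$branch_id), ]
    i <- which.min(lb$A)
    A_spin <- lb$A[i]
    eps2_L_end <- lb$eps2[i]
  }
  jump <- if (bist) attr(cv, "bistable_A")[2] - attr(cv, "bistable_A")[1] else 0
  list(states = st, bistable = bist, A_spin = A_spin, jump = jump,
       eps2_L_end = eps2_L_end,
       k_bar = reduced_kinetics(rt, template_dist)$k_bar)
}

#' Build the (Q, A) phase diagram
#'
#' For each inverse fidelity Q the mismatch rates of `base_rates` are
#' uniformly rescaled, the stationary branches computed by sweeping gamma,
#' and the realized state at each force taken as the higher-velocity branch.
#' Cells are labelled C where the realized two-replication error rate is
#' below the error threshold of the landscape, G below the spinodal (the
#' force at which the high-velocity branch ceases to exist, defined for
#' subcritical Q), and L otherwise. The mean fitness on the grid is the
#' infinite-population value `w_bar = k0 k_bar v_rel/(2L) * max(sigma
#' (1-eps2)^L, 1)`, with `v_rel = v/k_bar(Q)` the relative elongation
#' velocity: the genotypes' rate scale `k_bar` belongs to the landscape (the
#' base table), while the Q axis rescales only the relative fidelity.
#'
#' @param base_rates A [rate_table()] (the nonenzymatic-like reference whose
#'   mismatch rescaling generates the Q axis).
#' @param Q_grid Increasing inverse-fidelity grid (log-spaced recommended).
#' @param A_grid Increasing force grid (kT per monomer), strictly positive.
#' @param landscape A [fitness_landscape()] providing sigma and L.
#' @param cond Template [thermo_condition()] (delta_eps, g, K_eq).
#' @param template_dist Template base distribution.
#' @param n_gamma Gamma-grid size per Q column.
#' @return Object of class `phase_diagram`: matrices `v`, `eps`, `eps2`,
#'   `w_bar`, `n_branches`, `phase` (Q x A), per-Q `A_spin`/`bistable`, and
#'   `features` (spinodal, melting, critical point, triple point) from
#'   [phase_features()].
#' @export
build_phase_diagram <- function(base_rates, Q_grid, A_grid, landscape, cond,
                                template_dist = NULL, n_gamma = 201) {
  stopifnot(all(diff(Q_grid) > 0), all(diff(A_grid) > 0), min(A_grid) > 0)
  nQ <- length(Q_grid); nA <- length(A_grid)
  k_bar_base <- reduced_kinetics(base_rates, template_dist)$k_bar
  v <- eps <- eps2 <- w_bar <- nb <- matrix(NA_real_, nQ, nA)
  A_spin <- jump <- eps2_L_end <- rep(NA_real_, nQ)
  bist <- logical(nQ)
  for (i in seq_len(nQ)) {
    col <- .phase_column(base_rates, Q_grid[i], A_grid, cond, template_dist, n_gamma)
    eps2_L_end[i] <- col$eps2_L_end
    v[i, ] <- col$states$v
    eps[i, ] <- col$states$eps
    eps2[i, ] <- col$states$eps2
    nb[i, ] <- col$states$n_branches
    bist[i] <- col$bistable
    A_spin[i] <- col$A_spin
    jump[i] <- col$jump
    w_bar[i, ] <- landscape$k0 * k_bar_base * (col$states$v / col$k_bar) /
      (2 * landscape$L) * mean_fitness(col$states$eps2, landscape)
  }
  e2s <- error_threshold(landscape$sigma, landscape$L)$eps2_star
  phase <- matrix("L", nQ, nA)
  for (i in seq_len(nQ)) for (j in seq_len(nA)) {
    if (!is.finite(eps2[i, j])) { phase[i, j] <- NA_character_; next }
    if (eps2[i, j] < e2s) phase[i, j] <- "C"
    else if (bist[i] && A_grid[j] < A_spin[i]) phase[i, j] <- "G"
  }
  pd <- structure(list(Q = Q_grid, A = A_grid, v = v, eps = eps, eps2 = eps2,
                       w_bar = w_bar, n_branches = nb, phase = phase,
                       bistable = bist, A_spin = A_spin, jump = jump,
                       eps2_L_end = eps2_L_end,
                       eps2_star = e2s, landscape = landscape, cond = cond,
                       base_rates = base_rates),
                  class = "phase_diagram")
  pd$features <- phase_features(pd)
  pd
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d x %d (Q in [%.3g, %.3g], A in [%.3g, %.3g])\n",
              length(x$Q), length(x$A), min(x$Q), max(x$Q), min(x$A), max(x$A)))
  tab <- table(factor(x$phase, levels = c("G", "L", "C")))
  cat("  cells:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  f <- x$features
  if (!is.null(f$critical_point))
    cat(sprintf("  critical point: Q ~ %.4g, A ~ %.4g\n",
                f$critical_point["Q"], f$critical_point["A"]))
  if (!is.null(f$triple_point) && all(is.finite(f$triple_point)))
    cat(sprintf("  triple point:   Q ~ %.4g, A ~ %.4g\n",
                f$triple_point["Q"], f$triple_point["A"]))
  invisible(x)
}

## linear interpolation of a sign change of y over x; NA if none
.first_crossing <- function(x, y) {
  s <- sign(y)
  i <- which(s[-1] * s[-length(s)] < 0)
  if (!length(i)) {
    j <- which(y == 0)
    return(if (length(j)) x[j[1]] else NA_real_)
  }
  i <- i[1]
  x[i] + (x[i + 1] - x[i]) * (0 - y[i]) / (y[i + 1] - y[i])
}

#' Extract phase-diagram features
#'
#' Spinodal polyline (the locus where the high-velocity branch loses
#' stability, present only for subcritical Q and terminated by the critical
#' point), melting polyline (the error-threshold contour separating C from
#' the fluid phases), their intersection (triple point), and the critical
#' point (largest Q with a resolved bistable window).
#'
#' @param pd A [build_phase_diagram()] result.
#' @return List `spinodal` (data.frame Q, A), `melting` (data.frame Q, A),
#'   `critical_point` (named vector Q, A or NULL), `triple_point` (named
#'   vector Q, A or NULL).
#' @export
phase_features <- function(pd) {
  sp <- data.frame(Q = pd$Q[pd$bistable], A = pd$A_spin[pd$bistable])
  ## melting: per Q, force at which eps2 crosses the threshold (eps2 falls
  ## with A, so C lies on the high-A side)
  melt_A <- vapply(seq_along(pd$Q), function(i)
    .first_crossing(pd$A, pd$eps2[i, ] - pd$eps2_star), numeric(1))
  melting <- data.frame(Q = pd$Q, A = melt_A)
  melting <- melting[is.finite(melting$A), ]
  crit <- NULL
  if (any(pd$bistable)) {
    i <- max(which(pd$bistable))
    crit <- c(Q = pd$Q[i], A = pd$A_spin[i])
  }
  ## triple point: where the error rate at the L-branch terminus equals the
  ## threshold. Below it the C phase loses stability discontinuously at the
  ## spinodal (sublimation, C meets G directly); above it, the threshold is
  ## crossed smoothly on the L branch (true melting, C-L-G sequence).
  triple <- NULL
  ib <- which(pd$bistable & is.finite(pd$eps2_L_end))
  if (length(ib) > 1) {
    dd <- pd$eps2_L_end[ib] - pd$eps2_star
    qt <- .first_crossing(log(pd$Q[ib]), dd)
    if (is.finite(qt)) {
      qt <- exp(qt)
      triple <- c(Q = qt,
                  A = approx(pd$Q[ib], pd$A_spin[ib], xout = qt, ties = "ordered")$y)
    }
  }
  list(spinodal = sp, melting = melting, critical_point = crit,
       triple_point = triple)
}

#' Fitness-gradient boundary
#'
#' Locus where the slope of the realized mean fitness with respect to Q at
#' fixed force changes sign (centered differences in log Q). To the low-Q
#' side of the boundary random drifts in sequence space are biased toward
#' higher fidelity; inside the C phase the slope is always negative.
#'
#' @param pd A [build_phase_diagram()] result.
#' @param step Use every `step`-th grid point for the finite difference
#'   (halve the resolution to check convergence); default 1.
#' @return data.frame with one row per force value: `A`, `Q_star` (boundary,
#'   NA when the slope does not change sign), and attribute `slope`
#'   (the slope matrix).
#' @export
fitness_gradient_boundary <- function(pd, step = 1) {
  idx <- seq(1, length(pd$Q), by = step)
  lq <- log(pd$Q[idx])
  w <- pd$w_bar[idx, , drop = FALSE]
  n <- length(lq)
  slope <- matrix(NA_real_, n, length(pd$A))
  for (j in seq_along(pd$A)) {
    slope[2:(n - 1), j] <- (w[3:n, j] - w[1:(n - 2), j]) / (lq[3:n] - lq[1:(n - 2)])
  }
  Q_star <- vapply(seq_along(pd$A), function(j) {
    y <- slope[, j]
    ok <- is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    exp(.first_crossing(lq[ok], y[ok]))
  }, numeric(1))
  out <- data.frame(A = pd$A, Q_star = Q_star)
  attr(out, "slope") <- slope
  attr(out, "Q") <- pd$Q[idx]
  out
}

#' Critical inverse fidelity by bisection on the bistable window
#'
#' Locates the largest Q for which the velocity-force relation is multivalued
#' (the jump size vanishes at the critical point), by bisection on the
#' presence of a bistable window.
#'
#' @inheritParams build_phase_diagram
#' @param Q_lo,Q_hi Bracket; `Q_lo` must be bistable and `Q_hi` not.
#' @param tol Relative bisection tolerance on Q.
#' @param n_gamma Gamma-grid size per probe.
#' @return Critical Q estimate.
#' @export
critical_Q <- function(base_rates, cond, Q_lo, Q_hi, tol = 0.02,
                       template_dist = NULL, n_gamma = 401, A_max = 10) {
  is_bist <- function(Q) {
    rt <- rescale_fidelity(base_rates, Q, template_dist)
    cv <- velocity_error_curves(rt, cond, template_dist,
                                A_max = A_max, n_grid = n_gamma)
    isTRUE(attr(cv, "bistable"))
  }
  if (!is_bist(Q_lo)) stop("Q_lo is not bistable: bracket invalid")
  if (is_bist(Q_hi)) stop("Q_hi is bistable: bracket invalid")
  while (Q_hi / Q_lo > 1 + tol) {
    Q_mid <- sqrt(Q_lo * Q_hi)
    if (is_bist(Q_mid)) Q_lo <- Q_mid else Q_hi <- Q_mid
  }
  sqrt(Q_lo * Q_hi)
}
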