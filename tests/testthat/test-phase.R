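## shared modest-resolution diagram used by several tests
pd_cache <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      rt <- jc_table(1, 0.1)
      cond <- thermo_condition(gamma = 1)
      land <- fitness_landscape(20, 20)
      val <<- build_phase_diagram(rt, 10^seq(-4, log10(0.3), length.out = 23),
                                  seq(0.05, 2.5, length.out = 26), land, cond,
                                  n_gamma = 151)
    }
    val
  }
})

test_that("the phase diagram has the fluid-crystal topology", {
  pd <- pd_cache()
  ## C phase exists and sits strictly on the low-eps2 side of the threshold
  expect_true(any(pd$phase == "C", na.rm = TRUE))
  expect_true(all(pd$eps2[pd$phase == "C"] < pd$eps2_star))
  expect_true(all(pd$eps2[pd$phase != "C" & is.finite(pd$eps2)] >= pd$eps2_star - 1e-9))
  ## spinodal only below the critical Q
  expect_true(any(pd$bistable))
  expect_true(any(!pd$bistable))
  ib <- which(pd$bistable)
  expect_true(max(ib) < length(pd$Q)) # high-Q side is supercritical
  expect_true(all(diff(ib) == 1))     # bistable Q form one contiguous block
  ## spinodal force grows with Q up to the critical point
  expect_true(all(diff(pd$A_spin[ib]) > 0))
  ## jump size shrinks to zero at the critical point
  expect_lt(pd$jump[max(ib)], pd$jump[min(ib)])
})

test_that("melting line terminates on the spinodal at the triple point", {
  pd <- pd_cache()
  f <- pd$features
  expect_false(is.null(f$critical_point))
  expect_false(is.null(f$triple_point))
  qt <- f$triple_point["Q"]; qc <- f$critical_point["Q"]
  expect_lt(qt, qc)
  ## above the triple point (true melting) the contour lies above the
  ## spinodal; approaching it from above the two merge
  sp <- f$spinodal
  above <- sp$Q > qt * 1.3 & sp$Q < qc
  mA <- approx(f$melting$Q, f$melting$A, xout = sp$Q, ties = "ordered")$y
  expect_true(all(mA[above] >= sp$A[above] - 1e-9))
  cell <- max(diff(pd$A))
  i_tp <- which.min(abs(sp$Q - qt))
  expect_lt(abs(mA[i_tp] - sp$A[i_tp]), 2 * cell)
  ## below the triple point C loses stability at the spinodal itself
  below <- which(sp$Q < qt / 1.3)
  expect_true(all(abs(mA[below] - sp$A[below]) < 2 * cell))
})

test_that("two independent detectors agree on the critical fidelity", {
  pd <- pd_cache()
  rt <- jc_table(1, 0.1)
  cond <- thermo_condition(gamma = 1)
  ## detector 1: grid scan (largest bistable Q, one grid cell resolution)
  ib <- which(pd$bistable)
  q_lo <- pd$Q[max(ib)]; q_hi <- pd$Q[max(ib) + 1]
  ## detector 2: bisection on the bistable window
  qc <- critical_Q(rt, cond, Q_lo = 0.005, Q_hi = 0.1, tol = 0.02)
  expect_gte(qc, q_lo / 1.02)
  expect_lte(qc, q_hi * 1.02)
})

test_that("sigma -> 1 empties the crystalline region", {
  rt <- jc_table(1, 0.1)
  cond <- thermo_condition(gamma = 1)
  land1 <- fitness_landscape(20, 1)
  pd1 <- build_phase_diagram(rt, 10^seq(-3, -1, length.out = 6),
                             seq(0.2, 2, length.out = 8), land1, cond,
                             n_gamma = 101)
  expect_false(any(pd1$phase == "C", na.rm = TRUE))
})

test_that("the fitness slope in Q is negative inside the crystal phase", {
  pd <- pd_cache()
  fb <- fitness_gradient_boundary(pd)
  slope <- attr(fb, "slope")
  ## sample deep-C cells (interior in Q so the centered difference exists)
  deep <- which(pd$phase == "C" & pd$eps2 < 0.5 * pd$eps2_star, arr.ind = TRUE)
  deep <- deep[deep[, 1] > 2 & deep[, 1] < length(pd$Q) - 1, , drop = FALSE]
  expect_gt(nrow(deep), 5)
  expect_true(all(slope[deep] < 0))
  ## a boundary exists for at least some forces, and is Richardson-stable:
  ## halving the resolution moves it by less than two grid cells in log Q
  fb2 <- fitness_gradient_boundary(pd, step = 2)
  ok <- is.finite(fb$Q_star) & is.finite(fb2$Q_star)
  expect_gt(sum(ok), 3)
  dlq <- abs(log(fb$Q_star[ok]) - log(fb2$Q_star[ok]))
  cell <- mean(diff(log(pd$Q)))
  expect_true(all(dlq <= 4 * cell))
})

test_that("sequence memory differs by orders of magnitude across the spinodal", {
  ## generations to reach 10% divergence on the two branches at the same
  ## force, just inside the bistable window of a subcritical slice
  rt0 <- jc_table(1, 0.1)
  cond <- thermo_condition(gamma = 1)
  rt <- rescale_fidelity(rt0, 0.002)
  cv <- velocity_error_curves(rt, cond, A_max = 3, n_grid = 301)
  w <- attr(cv, "bistable_A")
  expect_false(is.null(w))
  A_mid <- mean(w)
  branches <- split(as.data.frame(cv), cv$branch_id)
  covering <- Filter(function(b) min(b$A) <= A_mid && max(b$A) >= A_mid, branches)
  e2 <- vapply(covering, function(b) {
    b <- b[order(b$A), ]
    approx(b$A, b$eps2, xout = A_mid, ties = "ordered")$y
  }, numeric(1))
  gens <- generations_to_drift(e2, 0.1)
  expect_gt(max(gens) / min(gens), 10)
})
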