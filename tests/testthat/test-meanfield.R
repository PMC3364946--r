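test_that("solve_symmetric closes the far-from-equilibrium limit", {
  kf <- c(1, 0.2, 0.1, 0.05)
  s <- solve_symmetric(kf, rep(0, 4))
  expect_equal(s$v, sum(kf), tolerance = 1e-10)
  expect_equal(s$q, kf / sum(kf), tolerance = 1e-10)
})

test_that("equilibrium solutions are Boltzmann with zero velocity and force", {
  rt <- sym_table()
  cond <- thermo_condition(gamma = 1, delta_eps = 0.4)
  s <- meanfield_solve(rt, cond)
  expect_equal(s$v, 0)
  expect_equal(s$A, 0, tolerance = 1e-9)
  for (j in 1:4)
    expect_equal(s$q[, j], exp(-free_energy_matrix(cond, rt))[, j],
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("solve() limits reproduce the closed forms at extreme gamma", {
  ## 10 random general tables; equilibrium and far-from-equilibrium to 4 digits
  for (seed in 1:10) {
    rt <- general_table(seed, fidelity = exp(runif(1, 1, 4)))
    cond <- thermo_condition(gamma = 1, delta_eps = 0.5)
    lim <- meanfield_limits(rt, cond)
    s_eq <- meanfield_solve(rt, cond)
    s_inf <- meanfield_solve(rt, thermo_condition(gamma = 1e6, delta_eps = 0.5))
    expect_equal(s_eq$eps, lim$eps_max, tolerance = 1e-5)
    expect_equal(s_eq$eps2, lim$eps2_max, tolerance = 1e-5)
    expect_equal(s_inf$eps, lim$eps_min, tolerance = 1e-4)
    expect_equal(s_inf$eps2, lim$eps2_min, tolerance = 1e-4)
    expect_equal(s_inf$v, reduced_kinetics(rt)$k_bar, tolerance = 1e-4)
  }
})

test_that("the equilibrium error ceiling is 3/4 for zero mismatch penalty", {
  cond <- thermo_condition(gamma = 1, delta_eps = 0)
  lim <- meanfield_limits(general_table(31), cond)
  expect_equal(lim$eps_max, 0.75)
  ## and zero-mismatch tables have eps_min = 0 (probe the analytic branch)
  expect_equal(meanfield_limits(jc_table(1, 1e-300), cond)$eps_min, 0, tolerance = 1e-12)
})

test_that("error rates stay within [eps_min, eps_max] along the whole curve", {
  rt <- sym_table()
  cond <- thermo_condition(gamma = 1)
  lim <- meanfield_limits(rt, cond)
  cv <- velocity_error_curves(rt, cond, A_max = 10, n_grid = 101)
  expect_true(all(cv$eps <= lim$eps_max + 1e-9))
  expect_true(all(cv$eps >= lim$eps_min - 1e-9))
  expect_true(all(diff(cv$eps) <= 1e-12)) # eps falls monotonically in gamma
})

test_that("mean-field theory is exact for symmetric template models", {
  ## property test: random symmetric models vs Gillespie, v and q within 3 SE
  set.seed(99)
  for (rep in 1:5) {
    pars <- c(exp(rnorm(1, 0, 0.3)), sort(exp(rnorm(3, log(0.08), 0.5)), TRUE))
    rt <- sym_table(pars)
    gamma <- exp(runif(1, 0.5, 6))
    cond <- thermo_condition(gamma = gamma)
    s <- meanfield_solve(rt, cond)
    tmpl <- generate_template(60000, seed = 1000 + rep)
    tr <- simulate_elongation(rt, cond, tmpl, seed = rep, max_events = 6e4)
    est <- estimate_observables(tr)
    expect_lt(abs(est$v_hat - s$v), 3.5 * est$v_se)
    ## pairing distribution: multinomial SEs per class (pooled over columns)
    q_sim <- est$q_hat %*% diag(4) # plain matrix
    for (j in 1:4) {
      n_j <- sum(tr$template[seq_len(est$n)] == colnames(rt$k_f)[j])
      se <- se_prop(s$q[, j], max(n_j, 1))
      expect_true(all(abs(q_sim[, j] - s$q[, j]) < 4 * se))
    }
  }
})

test_that("pairing statistics are site-independent along the chain", {
  ## the factorization assumption, checked for a general (asymmetric) table:
  ## the first and second halves of a long grown chain have the same
  ## mismatch fraction within sampling error
  rt <- general_table(37, fidelity = 8)
  cond <- thermo_condition(gamma = 50)
  tmpl <- generate_template(80000, seed = 5)
  tr <- simulate_elongation(rt, cond, tmpl, seed = 6, max_events = 8e4)
  n <- tr$net_length_added
  comp <- rt$alphabet$complement[tr$template[seq_len(n)]]
  mism <- tr$grown != comp
  h <- floor(n / 2)
  p1 <- mean(mism[1:h]); p2 <- mean(mism[(h + 1):n])
  se <- sqrt(se_prop(p1, h)^2 + se_prop(p2, n - h)^2)
  expect_lt(abs(p1 - p2), 3.5 * se)
})

test_that("realized states match the imposed external force", {
  ## inverting A(gamma) and recomputing the entropy production closes the
  ## matching condition to high precision
  rt <- sym_table()
  cond <- thermo_condition(gamma = 1)
  cv <- elongation_curves(rt, cond, A_max = 6, n_grid = 151)
  for (A in c(0.5, 1.5, 3, 5)) {
    st <- realize_at_force(cv, A)
    ci <- cond; ci$gamma <- st$gamma
    expect_equal(meanfield_solve(rt, ci)$A, A, tolerance = 1e-6)
  }
})

test_that("curves are single-branch for high Q and bistable for low Q", {
  rt <- jc_table(1, 0.1)
  cond <- thermo_condition(gamma = 1)
  hi <- velocity_error_curves(rescale_fidelity(rt, 0.3), cond, A_max = 8, n_grid = 201)
  expect_false(attr(hi, "bistable"))
  expect_true(all(diff(hi$v) >= -1e-12))
  lo <- velocity_error_curves(rescale_fidelity(rt, 0.002), cond, A_max = 8, n_grid = 201)
  expect_true(attr(lo, "bistable"))
  expect_gte(max(lo$branch_id), 3)
  ## branch endpoints reach the closed-form limits
  lim <- meanfield_limits(rescale_fidelity(rt, 0.3), cond)
  expect_equal(hi$eps[1], lim$eps_max, tolerance = 1e-3)
  expect_equal(hi$eps[nrow(hi)], lim$eps_min, tolerance = 1e-2)
})

test_that("fidelity response interpolators agree with direct solves", {
  rt <- jc_table(1, 0.1)
  cond <- thermo_condition(gamma = 1)
  A <- 2
  fr <- fidelity_response(rt, cond, A, Q_grid = 10^seq(-3.2, -0.5, length.out = 60))
  set.seed(8)
  for (Q in 10^runif(6, -3, -0.7)) {
    rtq <- rescale_fidelity(rt, Q)
    cv <- elongation_curves(rtq, cond, A_max = A + 2, n_grid = 301)
    st <- realize_at_force(cv, A)
    expect_equal(fr$eps2(Q), st$eps2, tolerance = 2e-6)
    expect_equal(fr$v_rel(Q), st$v / reduced_kinetics(rtq)$k_bar, tolerance = 2e-6)
  }
})
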