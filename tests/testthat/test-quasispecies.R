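test_that("replication rates scale with fitness, velocity and genome length", {
  expect_equal(replication_rate(2, 1.5, 0.5, 10), 2 * 1.5 * 0.5 / 20)
  expect_equal(replication_rate(1, 1, 1, 20), replication_rate(1, 1, 1, 10) / 2)
  expect_equal(replication_rate(1, 1, 0, 10), 0)
})

test_that("the error threshold has its closed form and limits", {
  expect_equal(error_threshold(1, 20)$eps2_star, 0)
  expect_equal(error_threshold(1, 20)$eps_star, 0)
  th <- error_threshold(10, 50)
  expect_equal(th$eps2_star, 1 - 10^(-1 / 50), tolerance = 1e-12)
  ## decreasing in L at fixed sigma
  e <- vapply(c(10, 20, 50, 200), function(L) error_threshold(4, L)$eps2_star, numeric(1))
  expect_true(all(diff(e) < 0))
  ## eps_star inverts the pair composition: a pair with per-copy error
  ## eps_star has net error eps2_star
  e2 <- function(e) 1 - (1 - e)^2 - e^2 / 3
  expect_equal(e2(th$eps_star), th$eps2_star, tolerance = 1e-12)
})

test_that("threshold agrees with a brute-force two-class stationary solve", {
  for (sigma in c(2, 5, 20)) for (L in c(10, 25)) {
    ## eigenvalue crossing of the 2x2 growth matrix diag-dominant branch
    f <- function(e2) sigma * (1 - e2)^L - 1
    root <- uniroot(f, c(1e-12, 0.9), tol = 1e-12)$root
    expect_equal(error_threshold(sigma, L)$eps2_star, root, tolerance = 1e-9)
  }
})

test_that("mean fitness is continuous with a single kink at the threshold", {
  land <- fitness_landscape(20, 6)
  e2s <- error_threshold(6, 20)$eps2_star
  expect_equal(mean_fitness(e2s, land), 1, tolerance = 1e-12)
  expect_equal(mean_fitness(e2s - 1e-9, land), mean_fitness(e2s + 1e-9, land),
               tolerance = 1e-6)
  expect_equal(mean_fitness(0, land), 6)
  expect_equal(mean_fitness(1, land), 1)
  ## piecewise smooth: strictly decreasing below, flat above
  es <- seq(0, e2s * 0.98, length.out = 20)
  expect_true(all(diff(mean_fitness(es, land)) < 0))
  expect_equal(mean_fitness(0.9, land), mean_fitness(0.95, land))
})

test_that("the master-frequency time course solves the two-type dynamics", {
  ## independent oracle: RK4 integration of the linear ODE for (n_m, n_u)
  rk4 <- function(sigma, Q2, k, x0, t_end, h = 1e-3) {
    W <- matrix(c(sigma * k * Q2, sigma * k * (1 - Q2), 0, k), 2, 2)
    y <- c(x0, 1 - x0)
    ts <- seq(0, t_end, by = h)
    for (i in seq_len(length(ts) - 1)) {
      k1 <- W %*% y; k2 <- W %*% (y + h / 2 * k1)
      k3 <- W %*% (y + h / 2 * k2); k4 <- W %*% (y + h * k3)
      y <- as.vector(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    }
    y[1] / sum(y)
  }
  for (ps in list(c(4, 0.6, 0.3), c(10, 0.9, 0.01), c(2, 0.4, 0.8))) {
    sigma <- ps[1]; Q2 <- ps[2]; x0 <- ps[3]
    for (tt in c(0.5, 2, 5)) {
      expect_equal(master_frequency_timecourse(sigma, Q2, 1, tt, x0),
                   rk4(sigma, Q2, 1, x0, tt), tolerance = 1e-8)
    }
  }
  ## perfect fidelity fixes the master; stationary start stays put
  expect_equal(master_frequency_timecourse(3, 1, 1, 50, 0.2), 1, tolerance = 1e-6)
  xs <- stationary_master_frequency(5, 0.7)
  expect_equal(master_frequency_timecourse(5, 0.7, 1, c(1, 10, 30), xs),
               rep(xs, 3), tolerance = 1e-10)
})

test_that("stationary frequency is the long-time limit of the time course", {
  for (ps in list(c(4, 0.6), c(20, 0.2), c(3, 0.6), c(2, 0.3))) {
    xs <- stationary_master_frequency(ps[1], ps[2])
    xt <- master_frequency_timecourse(ps[1], ps[2], 1, 150, 0.5)
    expect_equal(xt, xs, tolerance = 1e-8)
  }
  expect_equal(stationary_master_frequency(4, 0.25), 0) # sigma*Q2 = 1
  expect_equal(stationary_master_frequency(4, 0.2), 0)  # below threshold
  expect_equal(stationary_master_frequency(4, 1), 1)
})

test_that("Jukes-Cantor drift matches a per-site Monte Carlo chain", {
  expect_equal(hamming_drift(0.1, 0), 0)
  expect_equal(hamming_drift(0.2, 1e6), 0.75)
  set.seed(77)
  n_sites <- 1e5; eps2 <- 0.04; gens <- 12
  state <- rep(1L, n_sites)
  for (g in seq_len(gens)) {
    mut <- runif(n_sites) < eps2
    shift <- sample(1:3, sum(mut), replace = TRUE)
    state[mut] <- ((state[mut] - 1L + shift) %% 4L) + 1L
  }
  d_mc <- mean(state != 1L)
  d_th <- hamming_drift(eps2, gens)
  expect_lt(abs(d_mc - d_th), 3 * se_prop(d_th, n_sites))
  ## inverse relation
  expect_equal(hamming_drift(0.03, generations_to_drift(0.03, 0.3)), 0.3,
               tolerance = 1e-10)
})

test_that("neglecting back-mutation is an increasingly good approximation", {
  ## at fixed genome-wide copying fidelity the per-site error (hence the
  ## back-mutation flux) shrinks with L, so the closed form converges to the
  ## full Hamming-class eigen solve
  sigma <- 6; Q2 <- 0.7
  dev <- vapply(c(4, 8, 12, 16), function(L) {
    e <- 1 - Q2^(1 / L)
    full <- quasispecies_eigen(sigma, e, L)$x_master
    closed <- stationary_master_frequency(sigma, (1 - e)^L)
    abs(full - closed)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 0.001)
})
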