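test_that("population construction aggregates and validates genotypes", {
  p <- population(c("AUGC", "AUGC", "CCCC"), c(2, 1, 3))
  expect_equal(sum(p$counts), 6)
  expect_equal(length(p$genotypes), 2L)
  expect_error(population(c("AUG", "AUGC")), "same length")
  p0 <- population(c("AAAA", "CCCC"), c(1, 0))
  expect_equal(length(p0$genotypes), 1L) # zero-count entries dropped
})

test_that("mutation is per-site uniform over the alternatives", {
  g <- "AUGCAUGCAU"
  expect_identical(mutate_genotype(g, 0, seed = 1), g)
  m1 <- mutate_genotype(g, 1, seed = 2)
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(g, "")[[1]]))
  ## induced transition frequencies follow the Hamming-distance form
  set.seed(30)
  L <- 4; eps <- 0.3; n <- 4e4
  parent <- "AUGC"
  kids <- vapply(seq_len(n), function(i) mutate_genotype(parent, eps), character(1))
  hd <- vapply(strsplit(kids, ""), function(k)
    sum(k != strsplit(parent, "")[[1]]), numeric(1))
  p_th <- dbinom(0:L, L, eps)
  p_obs <- tabulate(hd + 1L, nbins = L + 1) / n
  expect_true(all(abs(p_obs - p_th) < 4 * se_prop(p_th, n)))
  ## an individual child genotype at HD 2 appears with (eps/3)^2 (1-eps)^2
  child <- "CUGA" # differs at sites 1 and 4
  expect_equal(mutation_probability(parent, child, eps), (eps / 3)^2 * (1 - eps)^2)
  f_obs <- mean(kids == child)
  expect_lt(abs(f_obs - mutation_probability(parent, child, eps)),
            4 * se_prop(mutation_probability(parent, child, eps), n))
})

test_that("waiting times at a fixed state are exponential with the total rate", {
  ## single genotype, constant-N mode: total rate = 2 * N * r
  L <- 8; N <- 40; r <- 0.7
  land <- fitness_landscape(L, 1)
  pop <- population(rep(paste(rep("A", L), collapse = ""), N))
  dts <- vapply(1:3000, function(i) {
    tr <- run_eigen_model(pop, land, eps_site = 0, rep_rate = r,
                          mode = "constant", t_grid = c(0, 100), seed = 7000 + i)
    attr(tr, "first_event_time")
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(dts, "pexp", rate = 2 * N * r))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(dts) - 1 / (2 * N * r)), 4 * stats::sd(dts) / sqrt(length(dts)))
})

test_that("growth mode is a pure birth process with exponential mean", {
  L <- 6; r <- 1
  land <- fitness_landscape(L, 1)
  g <- paste(rep("A", L), collapse = "")
  t_grid <- c(0, 0.5, 1, 1.5)
  Ns <- t(vapply(1:300, function(i) {
    tr <- run_eigen_model(population(g), land, eps_site = 0, rep_rate = r,
                          mode = "growth", t_grid = t_grid, seed = 100 + i)
    tr$N
  }, numeric(4)))
  mN <- colMeans(Ns)
  seN <- apply(Ns, 2, stats::sd) / sqrt(nrow(Ns))
  expect_true(all(abs(mN - exp(r * t_grid)) < 3.5 * pmax(seN, 1e-12)))
})

test_that("constant-N mode keeps the expected population size constant", {
  L <- 10; N0 <- 150
  land <- fitness_landscape(L, 3)
  pop <- random_pool(N0, L, seed = 9)
  Nf <- vapply(1:40, function(i) {
    tr <- run_eigen_model(pop, land, eps_site = 0.01, rep_rate = 1,
                          mode = "constant", t_grid = c(0, 4), seed = 300 + i,
                          master = paste(rep("A", L), collapse = ""))
    tr$N[2]
  }, numeric(1))
  se <- stats::sd(Nf) / sqrt(length(Nf))
  expect_lt(abs(mean(Nf) - N0), 3.5 * se)
})

test_that("ensemble means track the closed form and tighten with size", {
  v1 <- validate_against_closed_form(4, 0.65, L = 12, n_traj = 60,
                                     t_grid = seq(0, 2.5, length.out = 12),
                                     seed = 11)
  expect_true(all(abs(v1$mean_x - v1$theory) < 4 * pmax(v1$se_x, 0.005)))
  ## a larger ensemble deviates less in the aggregate
  v2 <- validate_against_closed_form(4, 0.65, L = 12, n_traj = 240,
                                     t_grid = seq(0, 2.5, length.out = 12),
                                     seed = 31)
  expect_lt(mean(abs(v2$mean_x - v2$theory)), mean(abs(v1$mean_x - v1$theory)) + 0.01)
})

test_that("the steady state forgets initial and boundary conditions", {
  sigma <- 6; L <- 8; eps <- 0.03
  x_hat <- stationary_master_frequency(sigma, (1 - eps)^L)
  master <- paste(rep("A", L), collapse = "")
  land <- fitness_landscape(L, sigma, master = strsplit(master, "")[[1]])
  late <- function(pop, mode, seed) {
    tr <- run_eigen_model(pop, land, eps_site = eps, rep_rate = 1, mode = mode,
                          t_grid = seq(0, 40, length.out = 60), seed = seed,
                          max_events = 3e6)
    mean(tail(tr$x_master, 20), na.rm = TRUE)
  }
  a <- mean(vapply(1:4, function(i)
    late(population(rep(master, 400)), "constant", 500 + i), numeric(1)))
  ## a random pool seeded with a single master copy (discovery of an exact
  ## L-mer from scratch is not what the statement is about)
  pool <- random_pool(399, L, seed = 17)
  pool <- population(c(pool$genotypes, master), c(pool$counts, 1))
  b <- mean(vapply(1:4, function(i) late(pool, "constant", 600 + i), numeric(1)))
  expect_lt(abs(a - x_hat), 0.06)
  expect_lt(abs(b - x_hat), 0.06)
  expect_lt(abs(a - b), 0.08)
})

test_that("genotype-resolved fidelity resolves master vs background classes", {
  rt <- jc_table(1, 0.1)
  cond <- thermo_condition(gamma = 1)
  master <- strsplit("AUGCAUGCAUGCAUGCAUGC", "")[[1]]
  land <- fitness_landscape(20, 10, master = master,
                            fidelity_peak = list(Q_master = 0.002, Q_background = 0.05))
  cls <- genotype_error_rate(NULL, land, rt, cond, A = 1.5)
  expect_lt(cls$master$eps2, cls$background$eps2)
  expect_equal(genotype_error_rate(paste(master, collapse = ""), land, rt, cond, 1.5),
               cls$master$eps2)
  expect_equal(genotype_error_rate("AAAAAAAAAAAAAAAAAAAA", land, rt, cond, 1.5),
               cls$background$eps2)
  expect_error(fitness_landscape(20, 2, fidelity_peak = list(Q_master = 0.1, Q_background = 0.01)),
               "Q_master")
})
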