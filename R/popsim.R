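## Genotypes are strings over the 4-letter alphabet, packed 2 bits per site
## into numeric codes (exact up to L = 26) for the C++ population kernel.

.pack_genotype <- function(s, alphabet) {
  idx <- match(strsplit(s, "")[[1]], alphabet$bases) - 1
  if (anyNA(idx)) stop("genotype contains letters outside the alphabet")
  sum(idx * 4^(seq_along(idx) - 1))
}

.unpack_genotype <- function(code, L, alphabet) {
  out <- character(L)
  for (i in seq_len(L)) {
    out[i] <- alphabet$bases[(code %% 4) + 1]
    code <- code %/% 4
  }
  paste(out, collapse = "")
}

#' Construct a replicator population
#'
#' @param genotypes Character vector of genotype strings (all of length `L`).
#' @param counts Nonnegative integer counts, one per genotype.
#' @param alphabet Alphabet preset or list.
#' @return Object of class `population`: aggregated genotype -> count map
#'   (zero-count entries dropped), genome length `L`, time `t = 0`.
#' @export
population <- function(genotypes, counts = rep(1, length(genotypes)),
                       alphabet = "rna") {
  if (is.character(alphabet)) alphabet <- .alphabets[[alphabet]]
  stopifnot(length(genotypes) == length(counts), all(counts >= 0),
            all(counts == round(counts)))
  L <- unique(nchar(genotypes))
  if (length(L) != 1L) stop("all genotypes must have the same length")
  if (L > 26) stop("genome length above 26 is not supported by the packed representation")
  agg <- tapply(counts, genotypes, sum)
  agg <- agg[agg > 0]
  structure(list(genotypes = names(agg), counts = as.numeric(agg),
                 L = as.integer(L), t = 0, alphabet = alphabet),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> N = %d individuals, %d genotypes, L = %d, t = %g\n",
              as.integer(sum(x$counts)), length(x$genotypes), x$L, x$t))
  invisible(x)
}

#' Random replicator pool
#'
#' @param N Pool size.
#' @param L Genome length.
#' @param seed Integer seed.
#' @param alphabet Alphabet preset.
#' @return A [population()] of N uniform-random genotypes.
#' @export
random_pool <- function(N, L, seed, alphabet = "rna") {
  if (is.character(alphabet)) alphabet <- .alphabets[[alphabet]]
  set.seed(seed)
  g <- vapply(seq_len(N), function(i)
    paste(sample(alphabet$bases, L, replace = TRUE), collapse = ""), character(1))
  population(g, alphabet = alphabet)
}

#' Mutate a genotype
#'
#' Per-site independent substitution: each site mutates with probability
#' `eps_site`, uniformly into one of the 3 alternative bases.
#'
#' @param genotype Genotype string.
#' @param eps_site Per-site substitution probability in [0, 1].
#' @param seed Optional seed (local).
#' @param alphabet Alphabet preset or list.
#' @return Mutated genotype string.
#' @export
mutate_genotype <- function(genotype, eps_site, seed = NULL, alphabet = "rna") {
  if (is.character(alphabet)) alphabet <- .alphabets[[alphabet]]
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(genotype, "")[[1]]
  hit <- runif(length(s)) < eps_site
  if (any(hit)) {
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(alphabet$bases, b), 1), character(1))
  }
  paste(s, collapse = "")
}

#' Genotype-to-genotype mutation probability
#'
#' The mutation matrix element for per-site independent errors:
#' `(eps/3)^h * (1-eps)^(L-h)` with `h` the Hamming distance.
#'
#' @param parent,child Genotype strings of equal length.
#' @param eps_site Per-site error rate.
#' @export
mutation_probability <- function(parent, child, eps_site) {
  a <- strsplit(parent, "")[[1]]; b <- strsplit(child, "")[[1]]
  stopifnot(length(a) == length(b))
  h <- sum(a != b)
  (eps_site / 3)^h * (1 - eps_site)^(length(a) - h)
}

#' Per-genotype inverse fidelity and error rate
#'
#' Under a single-peak fidelity landscape the master genotype catalyzes
#' replication with `Q_master`, everyone else with `Q_background`; the
#' per-site error rate at the ambient force follows from the single-molecule
#' theory for the correspondingly rescaled rate table.
#'
#' @param genotype Genotype string (or NULL to query both classes).
#' @param landscape A [fitness_landscape()] with `fidelity_peak` set.
#' @param base_rates A [rate_table()] whose mismatch rescaling realizes the Q
#'   values.
#' @param cond A [thermo_condition()].
#' @param A Ambient external force (kT per monomer).
#' @return For a genotype, its per-site two-replication error rate; with
#'   `genotype = NULL`, a list with `master` and `background` entries, each
#'   `list(Q, eps, eps2, v_rel)`.
#' @export
genotype_error_rate <- function(genotype = NULL, landscape, base_rates, cond, A) {
  fp <- landscape$fidelity_peak
  if (is.null(fp)) stop("landscape has no fidelity_peak")
  one <- function(Q) {
    rt <- rescale_fidelity(base_rates, Q)
    cv <- elongation_curves(rt, cond, A_max = A + 2, n_grid = 241)
    st <- realize_at_force(cv, A)
    if (!is.finite(st$v)) stop(sprintf("no stationary state at force A = %g for Q = %g", A, Q))
    list(Q = Q, eps = st$eps, eps2 = st$eps2,
         v_rel = st$v / reduced_kinetics(rt)$k_bar)
  }
  classes <- list(master = one(fp$Q_master), background = one(fp$Q_background))
  if (is.null(genotype)) return(classes)
  is_m <- !is.null(landscape$master) &&
    identical(paste(landscape$master, collapse = ""), genotype)
  if (is_m) classes$master$eps2 else classes$background$eps2
}

#' Stochastic Eigen-model population dynamics
#'
#' Gillespie simulation of the reaction set: replication of each individual
#' at its genotype's rate producing a mutated progeny and, in `"constant"`
#' mode, degradation of each individual at the population-mean replication
#' rate (so the expected population size is constant; in `"growth"` mode the
#' population grows exponentially). Waiting times are exponential with the
#' total transformation rate; reactions are chosen by the cumulative-rate
#' rule.
#'
#' @param pop Initial [population()].
#' @param landscape A [fitness_landscape()] (its `master` must be set, or
#'   `master` supplied here).
#' @param eps_site Per-site error rate per replication event: either one
#'   number (uniform) or `c(master=, background=)` for a genotype-resolved
#'   fidelity landscape.
#' @param rep_rate Replication rate of a background individual; the master
#'   replicates at `sigma` times this (or supply `c(master=, background=)`).
#' @param mode `"constant"` (replication + degradation) or `"growth"`.
#' @param t_grid Output time grid.
#' @param seed Integer seed.
#' @param master Master genotype string; default from the landscape.
#' @param max_events Safety cap on the number of reactions.
#' @return Object of class `population_trajectory`: data.frame `t, N,
#'   x_master, mean_hd` with the final [population()] in attribute `final`
#'   and the exit `status`.
#' @export
run_eigen_model <- function(pop, landscape, eps_site, rep_rate = NULL,
                            mode = c("constant", "growth"), t_grid, seed,
                            master = NULL, max_events = 5e7) {
  mode <- match.arg(mode)
  if (is.null(master)) {
    if (!is.null(landscape$master)) master <- paste(landscape$master, collapse = "")
    else if (landscape$sigma == 1) master <- pop$genotypes[1] # tracking reference only
    else stop("no master genotype given")
  }
  stopifnot(nchar(master) == pop$L)
  if (is.null(rep_rate)) rep_rate <- landscape$k0 / (2 * landscape$L)
  if (length(rep_rate) == 1L)
    rep_rate <- c(master = landscape$sigma * rep_rate, background = rep_rate)
  if (length(eps_site) == 1L)
    eps_site <- c(master = eps_site, background = eps_site)
  ab <- pop$alphabet
  codes <- vapply(pop$genotypes, .pack_genotype, numeric(1), alphabet = ab)
  set.seed(seed)
  res <- .cpp_popsim(codes, pop$counts, .pack_genotype(master, ab), pop$L,
                     rep_rate[["master"]], rep_rate[["background"]],
                     eps_site[["master"]], eps_site[["background"]],
                     as.integer(mode == "constant"), as.double(t_grid),
                     as.double(max_events))
  traj <- data.frame(t = res$t, N = res$N, x_master = res$x_master,
                     mean_hd = res$mean_hd)
  final <- NULL
  if (length(res$final_codes)) {
    gs <- vapply(res$final_codes, .unpack_genotype, character(1),
                 L = pop$L, alphabet = ab)
    final <- population(gs, res$final_counts, ab)
    final$t <- max(t_grid)
  }
  structure(traj, class = c("population_trajectory", "data.frame"),
            final = final, status = res$status, seed = seed, master = master,
            first_event_time = res$first_event_time)
}

#' Crystallization of a genome from a random pool
#'
#' Constant-size stochastic evolution started from `N0 - 1` uniform-random
#' genotypes plus a single copy of the master sequence, with genotype-resolved
#' fidelity (the master is the better replicase) and replication rates from
#' the single-molecule theory at the ambient force. Tracks the master
#' frequency and the mean fractional Hamming distance to the master.
#'
#' @param landscape A [fitness_landscape()] with `fidelity_peak` and `master`
#'   set (a random master is drawn if unset).
#' @param base_rates A [rate_table()].
#' @param cond A [thermo_condition()].
#' @param A Ambient external force (kT per monomer).
#' @param N0 Initial pool size.
#' @param t_max Final time (units of 1/k0).
#' @param seed Integer seed.
#' @param n_out Number of output times.
#' @return A `population_trajectory` (see [run_eigen_model()]), with the
#'   single-molecule class parameters in attribute `classes`.
#' @export
run_crystallization <- function(landscape, base_rates, cond, A, N0, t_max,
                                seed, n_out = 100) {
  cls <- genotype_error_rate(NULL, landscape, base_rates, cond, A)
  k_bar <- reduced_kinetics(base_rates)$k_bar
  rr <- c(master = replication_rate(landscape$sigma, landscape$k0 * k_bar,
                                    cls$master$v_rel, landscape$L),
          background = replication_rate(1, landscape$k0 * k_bar,
                                        cls$background$v_rel, landscape$L))
  ee <- c(master = cls$master$eps2, background = cls$background$eps2)
  set.seed(seed + 1L)
  master <- if (is.null(landscape$master))
    sample(base_rates$alphabet$bases, landscape$L, replace = TRUE)
  else landscape$master
  master_s <- paste(master, collapse = "")
  pool <- random_pool(N0 - 1L, landscape$L, seed + 2L, base_rates$alphabet)
  pop <- population(c(pool$genotypes, master_s), c(pool$counts, 1),
                    base_rates$alphabet)
  t_grid <- seq(0, t_max, length.out = n_out)
  out <- run_eigen_model(pop, landscape, eps_site = ee, rep_rate = rr,
                         mode = "constant", t_grid = t_grid, seed = seed,
                         master = master_s)
  attr(out, "classes") <- cls
  out
}

#' Ensemble test of the stochastic dynamics against the closed form
#'
#' Runs an ensemble of stochastic trajectories started from the pure master
#' state and compares the ensemble-mean master frequency with the
#' no-back-mutation closed form ([master_frequency_timecourse()]). In
#' `"constant"` mode (default) the ensemble holds N individuals throughout,
#' so the frequency dynamics match the deterministic solution up to O(1/N)
#' demographic effects; in `"growth"` mode the run starts from a single
#' master copy, where the small-founder discreteness adds a visible O(1)
#' early-time deviation from the deterministic curve that no ensemble size
#' removes.
#'
#' @param sigma,Q2 Landscape parameters (Q2 = probability of an error-free
#'   replication pair).
#' @param L Genome length.
#' @param n_traj Ensemble size.
#' @param t_grid Output times (units of 1/background rate).
#' @param seed Base seed; trajectory i uses `seed + i`.
#' @param N Population size in `"constant"` mode, and the event cap scale in
#'   `"growth"` mode.
#' @param mode `"constant"` or `"growth"`.
#' @return List with `t`, `mean_x`, `se_x`, `theory`, `max_abs_dev`,
#'   `n_traj`.
#' @export
validate_against_closed_form <- function(sigma, Q2, L, n_traj = 100,
                                         t_grid = seq(0, 3, length.out = 20),
                                         seed = 1, N = 1000,
                                         mode = c("constant", "growth")) {
  mode <- match.arg(mode)
  eps_site <- 1 - Q2^(1 / L)
  ab <- .alphabets$rna
  master <- paste(rep(ab$bases[1], L), collapse = "")
  land <- fitness_landscape(L, sigma, master = strsplit(master, "")[[1]])
  xm <- matrix(NA_real_, n_traj, length(t_grid))
  for (i in seq_len(n_traj)) {
    pop <- population(rep(master, if (mode == "constant") N else 1), alphabet = ab)
    tr <- run_eigen_model(pop, land, eps_site = eps_site, rep_rate = 1,
                          mode = mode, t_grid = t_grid, seed = seed + i,
                          max_events = if (mode == "growth") 4 * N else
                            16 * N * max(t_grid) * sigma + 1e4)
    xm[i, ] <- tr$x_master
  }
  mean_x <- colMeans(xm, na.rm = TRUE)
  se_x <- apply(xm, 2, stats::sd, na.rm = TRUE) / sqrt(colSums(!is.na(xm)))
  theory <- master_frequency_timecourse(sigma, Q2, k = 1, t_grid = t_grid, x0 = 1)
  list(t = t_grid, mean_x = mean_x, se_x = se_x, theory = theory,
       max_abs_dev = max(abs(mean_x - theory)), n_traj = n_traj)
}
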