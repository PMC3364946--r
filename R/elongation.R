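#' Generate or read a template sequence
#'
#' @param length Template length in bases.
#' @param dist Base probabilities in alphabet order (default uniform).
#' @param seed Optional integer seed (local to this call).
#' @param alphabet Alphabet preset or list.
#' @return Character vector of base letters.
#' @export
generate_template <- function(length, dist = NULL, seed = NULL, alphabet = "rna") {
  if (is.character(alphabet)) alphabet <- .alphabets[[alphabet]]
  dist <- .check_dist(dist)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  sample(alphabet$bases, length, replace = TRUE, prob = dist)
}

#' @rdname generate_template
#' @param file Path to a FASTA file; the first record is used.
#' @export
read_template_fasta <- function(file, alphabet = "rna") {
  if (is.character(alphabet)) alphabet <- .alphabets[[alphabet]]
  seqs <- seqinr::read.fasta(file, as.string = FALSE, forceDNAtolower = FALSE)
  tmpl <- toupper(as.character(seqs[[1]]))
  if (identical(alphabet$bases, .alphabets$rna$bases)) tmpl[tmpl == "T"] <- "U"
  bad <- setdiff(unique(tmpl), alphabet$bases)
  if (length(bad)) stop("template contains letters outside the alphabet: ",
                        paste(bad, collapse = ","))
  tmpl
}

#' @rdname generate_template
#' @param sequence Character vector of bases to write.
#' @param name Record name.
#' @export
write_template_fasta <- function(sequence, file, name = "template") {
  seqinr::write.fasta(list(sequence), names = name, file.out = file)
  invisible(file)
}

#' Simulate single-molecule templated elongation
#'
#' Gillespie simulation of reversible elongation: at each step one of the 5
#' enabled reactions fires (insertion of each of the 4 bases against the next
#' template base, with the forward table rates, or excision of the last added
#' base with its detailed-balance backward rate). The trajectory is
#' reproducible given the seed; shrinkage (negative-velocity conditions) is
#' simulated faithfully and reported via the termination status.
#'
#' @param rates A [rate_table()].
#' @param cond A [thermo_condition()].
#' @param template Character vector of template bases (see
#'   [generate_template()]).
#' @param seed Integer seed (required: every stochastic entry point is
#'   explicitly seeded).
#' @param max_events,max_length,max_time Stop criteria; at least one of
#'   `max_events`/`max_length` must be finite. `max_time <= 0` disables the
#'   time cap.
#' @param n_blocks Number of checkpoint blocks used for standard errors.
#' @param stop_at_zero If TRUE, a chain emptied by excision terminates with
#'   status `"shrunk_to_zero"`; by default the simulation continues (the
#'   length-0 state simply has no excision reaction), which is what the
#'   master equation prescribes and what near-equilibrium runs need.
#' @return Object of class `elongation_trajectory`: list with `template`,
#'   `grown` (bases added, same indexing as the template), `net_length_added`,
#'   `elapsed`, `n_events`, `status`, `seed`, block checkpoints, and the
#'   inputs.
#' @export
simulate_elongation <- function(rates, cond, template, seed,
                                max_events = 1e5, max_length = NULL,
                                max_time = 0, n_blocks = 25,
                                stop_at_zero = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ab <- rates$alphabet
  ti <- match(template, ab$bases) - 1L
  if (anyNA(ti)) stop("template contains letters outside the table's alphabet")
  kb <- backward_rates(rates, cond)
  if (is.null(max_length)) max_length <- length(template)
  set.seed(seed)
  res <- .cpp_elongate(ti, rates$k_f, kb, as.integer(max_events),
                       as.integer(max_length), as.double(max_time),
                       as.integer(n_blocks), as.integer(stop_at_zero))
  grown <- ab$bases[res$grown + 1L]
  structure(list(template = template, grown = grown,
                 net_length_added = length(grown), elapsed = res$elapsed,
                 n_events = res$n_events, status = res$status, seed = seed,
                 block_t = res$block_t, block_len = res$block_len,
                 rates = rates, cond = cond),
            class = "elongation_trajectory")
}

#' @export
print.elongation_trajectory <- function(x, ...) {
  cat(sprintf("<elongation_trajectory> %d bases added in %.4g time units (%s, %g events, seed %d)\n",
              x$net_length_added, x$elapsed, x$status, x$n_events, x$seed))
  invisible(x)
}

#' Estimate elongation observables from a trajectory
#'
#' Velocity is net length added over elapsed time; the error rate is the
#' mismatch fraction of the final grown chain; the entropy production per
#' monomer is obtained from the empirical pairing distribution of the chain
#' (free energies of the pairs actually present plus the sequence-disorder
#' term). Standard errors come from block averaging of the checkpointed
#' trajectory; the empirical pairing distribution `q_hat` is returned for
#' direct comparison with the mean-field theory.
#'
#' @param traj An [simulate_elongation()] result.
#' @param cond A [thermo_condition()]; defaults to the one stored in `traj`.
#' @return List with `v_hat`, `v_se`, `eps_hat`, `eps_se`, `eps2_hat`,
#'   `A_hat`, `q_hat` (4x4 empirical pairing distribution), `n`.
#' @export
estimate_observables <- function(traj, cond = traj$cond) {
  n <- traj$net_length_added
  if (n <= 0) stop("no net growth: estimators undefined")
  rates <- traj$rates
  ab <- rates$alphabet
  tmpl <- traj$template[seq_len(n)]
  comp <- ab$complement[tmpl]
  mism <- traj$grown != comp
  eps_hat <- mean(mism)
  v_hat <- n / traj$elapsed
  ## block SEs from checkpoint increments
  bt <- traj$block_t; bl <- traj$block_len
  v_se <- eps_se <- NA_real_
  if (length(bt) >= 4) {
    dv <- diff(bl) / diff(bt)
    dv <- dv[is.finite(dv)]
    if (length(dv) >= 3) v_se <- stats::sd(dv) / sqrt(length(dv))
  }
  eps_se <- sqrt(max(eps_hat * (1 - eps_hat), 1 / n) / n)
  ## empirical pairing distribution q_hat(incoming | template)
  tab <- table(factor(traj$grown, levels = ab$bases),
               factor(tmpl, levels = ab$bases))
  cs <- colSums(tab)
  q_hat <- sweep(unclass(tab), 2, pmax(cs, 1), "/")
  p_hat <- cs / sum(cs)
  dg <- free_energy_matrix(cond, rates)
  lg <- log(cond$gamma)
  term <- q_hat * (lg - dg - ifelse(q_hat > 0, log(q_hat), 0))
  A_hat <- sum(p_hat * colSums(term))
  ret <- vapply(1:4, function(j) sum(q_hat[, j] * q_hat[j, ]), numeric(1))
  eps2_hat <- .harmonic_mean(1 - ret, p_hat)
  list(v_hat = v_hat, v_se = v_se, eps_hat = eps_hat, eps_se = eps_se,
       eps2_hat = eps2_hat, A_hat = A_hat, q_hat = q_hat, n = n)
}
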