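#' @useDynLib quasitherm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rnorm runif uniroot splinefun approx
#' @importFrom utils read.delim write.table head tail
NULL

## Alphabet presets. Rates are tabulated incoming-base x template-base; the
## complement map defines which entry of each column is the Watson-Crick one.
.alphabets <- list(
  rna = list(bases = c("A", "U", "G", "C"),
             complement = c(A = "U", U = "A", G = "C", C = "G")),
  dna = list(bases = c("A", "T", "G", "C"),
             complement = c(A = "T", T = "A", G = "C", C = "G"))
)

#' Nucleotide alphabet with complement map
#'
#' @param preset `"rna"` (A,U,G,C) or `"dna"` (A,T,G,C).
#' @return List with `bases` (ordered letters) and `complement`
#'   (named involutive map).
#' @examples
#' alphabet("rna")$complement[["G"]]
#' @export
alphabet <- function(preset = c("rna", "dna")) {
  preset <- match.arg(preset)
  .alphabets[[preset]]
}

.check_alphabet <- function(a) {
  stopifnot(is.list(a), length(a$bases) == 4L,
            !anyDuplicated(a$bases), all(names(a$complement) %in% a$bases))
  comp <- a$complement
  if (!all(comp[comp[a$bases]] == a$bases))
    stop("complement map is not an involution over the alphabet")
  invisible(a)
}

#' Construct a base-incorporation rate table
#'
#' A `rate_table` holds the 16 forward rate constants k_f(incoming | template)
#' of templated single-nucleotide insertion, with rows indexing the incoming
#' base and columns the template base, over a 4-letter alphabet with a
#' Watson-Crick complement map. All entries must be strictly positive and
#' finite (empirical tables may well have mismatch rates exceeding the
#' Watson-Crick rate in a column; that is not checked because it is not
#' required).
#'
#' @param k_f 4x4 numeric matrix of forward rates, rows = incoming base,
#'   columns = template base, in the units of the source data (apparent
#'   second-order rate constants for the packaged tables).
#' @param alphabet Alphabet preset name or list as returned by [alphabet()].
#' @param name Optional label carried in printouts and provenance metadata.
#' @return Object of class `rate_table`.
#' @examples
#' rt <- random_rate_table("jc", params = c(k_correct = 1, k_mismatch = 0.05))
#' reduced_kinetics(rt)
#' @export
rate_table <- function(k_f, alphabet = "rna", name = NULL) {
  if (is.character(alphabet)) alphabet <- .alphabets[[match.arg(alphabet, names(.alphabets))]]
  .check_alphabet(alphabet)
  k_f <- as.matrix(k_f)
  stopifnot(identical(dim(k_f), c(4L, 4L)))
  if (!all(is.finite(k_f)) || any(k_f <= 0))
    stop("all 16 forward rates must be strictly positive and finite")
  dimnames(k_f) <- list(incoming = alphabet$bases, template = alphabet$bases)
  structure(list(k_f = k_f, alphabet = alphabet, name = name),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat("<rate_table", if (!is.null(x$name)) paste0("'", x$name, "'"), ">\n")
  cat("  alphabet:", paste(x$alphabet$bases, collapse = ""), "\n")
  print(signif(x$k_f, 4))
  rk <- reduced_kinetics(x)
  cat(sprintf("  k_bar = %.4g   Q = %.4g\n", rk$k_bar, rk$Q))
  invisible(x)
}

## index of the Watson-Crick (complementary) incoming base for each template
## column, as a row index into k_f
.wc_index <- function(rt) {
  match(rt$alphabet$complement[colnames(rt$k_f)], rownames(rt$k_f))
}

## logical 4x4 matrix, TRUE where the entry is the Watson-Crick pair
.wc_mask <- function(rt) {
  m <- matrix(FALSE, 4, 4, dimnames = dimnames(rt$k_f))
  m[cbind(.wc_index(rt), seq_len(4))] <- TRUE
  m
}

.check_dist <- function(template_dist) {
  if (is.null(template_dist)) template_dist <- rep(0.25, 4)
  stopifnot(length(template_dist) == 4L, all(template_dist >= 0))
  s <- sum(template_dist)
  if (s <= 0) stop("template distribution must have positive total mass")
  template_dist / s
}

## harmonic mean over the template distribution; the convention used for
## velocities and error rates (a zero-probability base drops out)
.harmonic_mean <- function(x, p) {
  keep <- p > 0
  if (any(x[keep] == 0)) return(0)
  1 / sum(p[keep] / x[keep])
}

#' Reduced kinetic description: mean rate and inverse fidelity
#'
#' Collapses a 16-rate table to the two far-from-equilibrium aggregates that
#' control its phase behaviour: the mean base incorporation rate
#' \eqn{\bar k = \langle \sum_{n'} k_f(n'|n) \rangle} and the relative inverse
#' fidelity \eqn{Q = \langle Q_n \rangle} with
#' \eqn{Q_n = \sum_{n' \ne \bar n} k_f(n'|n) / k_f(\bar n|n)} (mismatch-to-match
#' ratio per template base). Angle brackets denote the harmonic mean over the
#' template base distribution, taken after the per-column summation; with this
#' convention the far-from-equilibrium error rate is exactly `Q/(1+Q)`.
#'
#' @param rates A [rate_table()].
#' @param template_dist Probabilities of the 4 template bases (template
#'   column order); default uniform.
#' @return List with components `k_bar`, `Q`, and the per-template-base
#'   vectors `k_n` (column sums) and `Q_n`.
#' @export
reduced_kinetics <- function(rates, template_dist = NULL) {
  p <- .check_dist(template_dist)
  k <- rates$k_f
  wc <- .wc_index(rates)
  k_n <- colSums(k)
  kc <- k[cbind(wc, seq_len(4))]
  Q_n <- (k_n - kc) / kc
  list(k_bar = .harmonic_mean(k_n, p),
       Q = .harmonic_mean(Q_n, p),
       k_n = setNames(k_n, colnames(k)),
       Q_n = setNames(Q_n, colnames(k)))
}

#' Rescale mismatch rates to a target inverse fidelity
#'
#' Multiplies the 12 mismatch entries by one common factor so that the table's
#' inverse fidelity equals `target_Q`, leaving the Watson-Crick entries
#' untouched. Because Q is homogeneous of degree one in the mismatch block the
#' factor is exact, `target_Q / Q`.
#'
#' @inheritParams reduced_kinetics
#' @param target_Q Desired inverse fidelity (>= 0). `0` returns a table whose
#'   mismatch entries are zero; such a table is flagged (attribute
#'   `zero_mismatch`) and is not a valid `rate_table` input elsewhere.
#' @return A [rate_table()] (or flagged matrix when `target_Q = 0`).
#' @export
rescale_fidelity <- function(rates, target_Q, template_dist = NULL) {
  if (target_Q < 0) stop("target_Q must be nonnegative")
  rk <- reduced_kinetics(rates, template_dist)
  s <- target_Q / rk$Q
  k <- rates$k_f
  mis <- !.wc_mask(rates)
  k[mis] <- k[mis] * s
  if (target_Q == 0) {
    attr(k, "zero_mismatch") <- TRUE
    return(k)
  }
  rate_table(k, rates$alphabet,
             name = if (!is.null(rates$name)) sprintf("%s (Q=%.3g)", rates$name, target_Q))
}

#' Jukes-Cantor reduction of a rate table
#'
#' Returns the two-parameter table (one Watson-Crick rate, one common mismatch
#' rate) whose reduced kinetics `(k_bar, Q)` match the input's exactly:
#' `k_wc = k_bar/(1+Q)`, `k_mis = k_bar * Q / (3 (1+Q))`.
#'
#' @inheritParams reduced_kinetics
#' @return A [rate_table()].
#' @export
jukes_cantor_reduction <- function(rates, template_dist = NULL) {
  rk <- reduced_kinetics(rates, template_dist)
  kc <- rk$k_bar / (1 + rk$Q)
  ki <- rk$k_bar * rk$Q / (3 * (1 + rk$Q))
  k <- matrix(ki, 4, 4)
  k[cbind(.wc_index(rates), 1:4)] <- kc
  rate_table(k, rates$alphabet,
             name = if (!is.null(rates$name)) paste(rates$name, "(JC)"))
}

#' Generate a random rate table
#'
#' @param kind `"jc"` (two parameters: `k_correct`, `k_mismatch`),
#'   `"symmetric"` (four parameters: the set of rates against any template
#'   base is the same up to complement relabelling, the class for which the
#'   mean-field theory is exact), or `"general"` (16 independent rates).
#' @param params For `"jc"`, numeric `c(k_correct, k_mismatch)`. For
#'   `"symmetric"`, length-4 numeric: rate of inserting the complementary base
#'   and the three mismatch rates (ranked). For `"general"`, optional list
#'   with `log_sd` spread (default 1) and `fidelity` mean match/mismatch ratio
#'   (default 10).
#' @param seed Integer seed for the random kinds; ignored for `"jc"`/
#'   `"symmetric"` when `params` is supplied in full.
#' @param alphabet Alphabet preset.
#' @return A [rate_table()].
#' @export
random_rate_table <- function(kind = c("jc", "symmetric", "general"),
                              params = NULL, seed = NULL, alphabet = "rna") {
  kind <- match.arg(kind)
  if (is.character(alphabet)) alphabet <- .alphabets[[alphabet]]
  if (!is.null(seed)) set.seed(seed)
  wc <- match(alphabet$complement[alphabet$bases], alphabet$bases)
  if (kind == "jc") {
    if (is.null(params)) params <- c(k_correct = 1, k_mismatch = 0.05)
    if (params[2] == 0) stop("zero mismatch rates are not representable; use a small positive rate")
    k <- matrix(params[[2]], 4, 4)
    k[cbind(wc, 1:4)] <- params[[1]]
  } else if (kind == "symmetric") {
    if (is.null(params))
      params <- c(exp(rnorm(1, 0, 0.5)), sort(exp(rnorm(3, log(0.05), 0.7)), decreasing = TRUE))
    stopifnot(length(params) == 4L, all(params > 0))
    k <- matrix(NA_real_, 4, 4)
    for (j in 1:4) {
      others <- setdiff(1:4, wc[j])
      k[wc[j], j] <- params[1]
      k[others, j] <- params[2:4]
    }
  } else {
    if (is.null(params)) params <- list()
    log_sd <- if (is.null(params$log_sd)) 1 else params$log_sd
    fid <- if (is.null(params$fidelity)) 10 else params$fidelity
    k <- matrix(exp(rnorm(16, log(1 / fid), log_sd)), 4, 4)
    k[cbind(wc, 1:4)] <- exp(rnorm(4, 0, log_sd))
  }
  rate_table(k, alphabet, name = paste0("random-", kind))
}
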