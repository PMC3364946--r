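## shared model builders for the tests

jc_table <- function(k_correct = 1, k_mismatch = 0.05, alphabet = "rna") {
  random_rate_table("jc", c(k_correct, k_mismatch), alphabet = alphabet)
}

## a fixed heterogeneous 16-rate table (general, asymmetric)
general_table <- function(seed = 4242, fidelity = 10) {
  random_rate_table("general", list(fidelity = fidelity, log_sd = 0.8), seed = seed)
}

sym_table <- function(params = c(1, 0.12, 0.05, 0.02)) {
  random_rate_table("symmetric", params)
}

cond_at <- function(gamma, ...) thermo_condition(gamma = gamma, ...)

## standard error of a binomial proportion
se_prop <- function(p, n) sqrt(pmax(p * (1 - p), 1 / n) / n)
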