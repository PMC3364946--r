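## File formats: TSV for rate tables / curves / trajectories, flat YAML for
## configs, FASTA for templates. Provenance/metadata lines start with '#eef'.

#' Write and read rate tables as TSV
#'
#' 4 rows (incoming base) x 4 columns (template base) with a header row and
#' row names; lines starting `#eef` carry provenance metadata and are
#' ignored by the reader (but returned as an attribute). Row names may be
#' NTP style (`ATP`) or bare letters.
#'
#' @param rates A [rate_table()].
#' @param path File path.
#' @param provenance Character vector of metadata lines (without the `#eef`).
#' @export
write_rate_table <- function(rates, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provenance) writeLines(paste("#eef", p), con)
  ab <- paste(rates$alphabet$bases, collapse = "")
  writeLines(paste("#eef alphabet:", if (ab == "AUGC") "rna" else "dna"), con)
  writeLines(paste(c("", colnames(rates$k_f)), collapse = "\t"), con)
  for (i in 1:4)
    writeLines(paste(c(rownames(rates$k_f)[i],
                       formatC(rates$k_f[i, ], format = "g", digits = 8)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  lines <- readLines(path)
  meta <- sub("^#eef\\s*", "", lines[startsWith(lines, "#eef")])
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) != 5L)
    stop(sprintf("malformed rate table '%s': expected header + 4 data lines, found %d (line %d)",
                 path, length(body), length(body) + 1L))
  ab_line <- grep("^alphabet:", meta, value = TRUE)
  preset <- if (length(ab_line)) trimws(sub("alphabet:", "", ab_line[1])) else "rna"
  alphabet <- .alphabets[[preset]]
  if (is.null(alphabet)) stop("unknown alphabet preset in file: ", preset)
  hdr <- strsplit(body[1], "\t")[[1]]
  cols <- hdr[nzchar(hdr)]
  k <- matrix(NA_real_, 4, 4)
  rows <- character(4)
  for (i in 1:4) {
    f <- strsplit(body[i + 1], "\t")[[1]]
    if (length(f) != 5L)
      stop(sprintf("malformed rate table '%s' at line %d: expected 5 fields, found %d",
                   path, which(lines == body[i + 1]), length(f)))
    rows[i] <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals))
      stop(sprintf("malformed rate table '%s' at line %d: non-numeric rate",
                   path, which(lines == body[i + 1])))
    k[i, ] <- vals
  }
  ## NTP-style row labels (ATP, UTP/TTP, ...) reduce to their base letter
  rows <- sub("TP$", "", rows)
  rows <- substr(rows, 1, 1)
  ro <- match(alphabet$bases, rows)
  co <- match(alphabet$bases, cols)
  if (anyNA(ro) || anyNA(co))
    stop(sprintf("rate table '%s': row/column labels do not match alphabet {%s}",
                 path, paste(alphabet$bases, collapse = ",")))
  rt <- rate_table(k[ro, co], alphabet,
                   name = sub("\\.tsv$", "", basename(path)))
  attr(rt, "provenance") <- meta
  rt
}

#' Packaged reference rate tables
#'
#' The packaged tables are synthetic illustrative stand-ins for the
#' experimentally characterized polymerase systems they are named after
#' (activated nonenzymatic template-directed synthesis, the R18 polymerase
#' ribozyme, poliovirus 3Dpol, Dpo4 and pol-gamma); they are constructed, not
#' measured, values, chosen to reproduce the qualitative layout of those
#' systems in the (k_bar, Q) plane: the nonenzymatic chemistry is orders of
#' magnitude slower than any polymerase, and fidelity improves from
#' nonenzymatic through ribozyme to the protein polymerases. See each file's
#' `#eef` header.
#'
#' @param name Fixture name; see `list_fixtures()`.
#' @return A [rate_table()] (with `provenance` attribute).
#' @export
load_fixture <- function(name) {
  dir <- system.file("extdata", package = "quasitherm")
  avail <- list_fixtures()
  if (!name %in% avail)
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(avail, collapse = ", ")))
  read_rate_table(file.path(dir, paste0("synthetic-", name, ".tsv")))
}

#' @rdname load_fixture
#' @export
list_fixtures <- function() {
  dir <- system.file("extdata", package = "quasitherm")
  f <- list.files(dir, pattern = "^synthetic-.*\\.tsv$")
  sub("^synthetic-(.*)\\.tsv$", "\\1", f)
}

#' Write and read thermodynamic conditions as flat YAML
#'
#' Keys: `gamma` (or `A_nominal`), `K_eq`, `delta_eps`, `g`, `ntp_types`.
#'
#' @param cond A [thermo_condition()].
#' @param path File path.
#' @export
write_thermo_config <- function(cond, path) {
  yaml::write_yaml(unclass(cond), path)
  invisible(path)
}

#' @rdname write_thermo_config
#' @export
read_thermo_config <- function(path) {
  x <- yaml::read_yaml(path)
  thermo_condition(gamma = x$gamma, A_nominal = x$A_nominal,
                   K_eq = if (is.null(x$K_eq)) 10 else x$K_eq,
                   delta_eps = if (is.null(x$delta_eps)) 0.5 else x$delta_eps,
                   g = x$g,
                   ntp_types = if (is.null(x$ntp_types)) 4L else x$ntp_types)
}

#' Read/write a run configuration
#'
#' Flat YAML of run parameters (rate table path or fixture name, thermo
#' parameters, landscape parameters, grids, seeds, output paths). Configs
#' round-trip read -> write -> read identically; every stochastic entry
#' point requires an explicit `seed`.
#'
#' @param x Named list of configuration values.
#' @param path File path.
#' @export
write_run_config <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @param stochastic If TRUE, require a `seed` entry.
#' @export
read_run_config <- function(path, stochastic = FALSE) {
  x <- yaml::read_yaml(path)
  if (stochastic && is.null(x$seed))
    stop("config has no 'seed': stochastic runs require an explicit seed")
  x
}

#' Export curves or trajectories as TSV with a metadata block
#'
#' @param df data.frame to write.
#' @param path File path.
#' @param meta Named list written as `#eef key: value` header lines
#'   (seed, config hash, fixture provenance, ...).
#' @export
write_curves_tsv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta$package <- as.character(utils::packageVersion("quasitherm"))
  for (k in names(meta))
    writeLines(sprintf("#eef %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_tsv
#' @export
read_curves_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#eef")]
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          sep = "\t", header = TRUE)
  meta <- list()
  for (m in sub("^#eef\\s*", "", meta_lines)) {
    kv <- strsplit(m, ":\\s*")[[1]]
    if (length(kv) >= 2) meta[[kv[1]]] <- paste(kv[-1], collapse = ": ")
  }
  attr(df, "meta") <- meta
  df
}
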