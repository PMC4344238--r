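DNA_BASES <- c("A", "C", "G", "T")

#' @useDynLib trninfer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd quantile rnorm runif setNames p.adjust pbinom ks.test
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; non-ACGT characters (e.g. `N`) are preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## integer encoding: A=0, C=1, G=2, T=3, anything else -1
dna_to_int <- function(x) {
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
  m[is.na(m)] <- 0L
  m - 1L
}

int_to_dna <- function(v) {
  out <- rep("N", length(v))
  ok <- v >= 0L & v <= 3L
  out[ok] <- DNA_BASES[v[ok] + 1L]
  paste(out, collapse = "")
}

revcomp_int <- function(v) {
  out <- rev(v)
  ok <- out >= 0L
  out[ok] <- 3L - out[ok]
  out
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(df, path, row.names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = row.names)
}

## evaluate expr with a temporary RNG state seeded by `seed`; restores the
## caller's RNG afterwards so library code does not perturb user simulations
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Report-style rounding (0.05 rounds up), used for the percentage columns
#' of per-TF reports.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## empirical permutation p-value: #extreme / n, floored at 1/(n+1)
emp_pvalue <- function(n_extreme, n) {
  max(n_extreme / n, 1 / (n + 1))
}
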