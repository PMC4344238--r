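#' Build a position-specific scoring matrix from aligned binding sites
#'
#' Tallies per-column nucleotide counts over a set of equal-length sites and
#' converts them to frequencies with an additive pseudocount:
#' `freq[b, j] = (count[b, j] + pseudocount) / (n_sites + 4 * pseudocount)`.
#'
#' @param sites character vector of equal-length DNA site sequences.
#' @param pseudocount non-negative pseudocount added per cell (default 0.25).
#' @param motif_id motif identifier.
#' @param source provenance label: one of `"denovo"`, `"reference"`,
#'   `"rebuilt"`.
#' @return an object of class `pssm` with `counts` and `freq` (4 x width
#'   matrices, rows A/C/G/T), `n_sites`, `width`, `motif_id` and `source`.
#' @export
build_pssm <- function(sites, pseudocount = 0.25, motif_id = "motif",
                       source = "denovo") {
  if (length(sites) < 1) stop("need at least one site")
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites must all have equal width")
  mat <- do.call(rbind, strsplit(toupper(sites), "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j)
    tabulate(match(mat[, j], DNA_BASES), nbins = 4), numeric(4))
  counts <- matrix(counts, nrow = 4, dimnames = list(DNA_BASES, NULL))
  new_pssm(counts, n_sites = length(sites), pseudocount = pseudocount,
           motif_id = motif_id, source = source)
}

new_pssm <- function(counts, n_sites, pseudocount = 0.25, motif_id = "motif",
                     source = "denovo") {
  stopifnot(nrow(counts) == 4)
  rownames(counts) <- DNA_BASES
  freq <- sweep(counts + pseudocount, 2,
                colSums(counts) + 4 * pseudocount, "/")
  structure(list(motif_id = motif_id, width = ncol(counts), counts = counts,
                 freq = freq, n_sites = n_sites, pseudocount = pseudocount,
                 source = source),
            class = "pssm")
}

## construct directly from a frequency matrix (synthetic ground truth,
## reference libraries); counts are scaled to n_sites
pssm_from_freq <- function(freq, motif_id = "motif", n_sites = 20,
                           source = "reference") {
  stopifnot(nrow(freq) == 4)
  freq <- sweep(freq, 2, colSums(freq), "/")
  dimnames(freq) <- list(DNA_BASES, NULL)
  structure(list(motif_id = motif_id, width = ncol(freq),
                 counts = freq * n_sites, freq = freq, n_sites = n_sites,
                 pseudocount = 0, source = source),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s' (%s): width %d, %d sites, consensus %s\n",
              x$motif_id, x$source, x$width, round(x$n_sites),
              pssm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PSSM
#' @param pssm a `pssm` object.
#' @return character consensus (most frequent base per column).
#' @export
pssm_consensus <- function(pssm) {
  paste(DNA_BASES[apply(pssm$freq, 2, which.max)], collapse = "")
}

#' Reverse complement a PSSM
#' @param pssm a `pssm` object.
#' @return the reverse-complemented `pssm`.
#' @export
pssm_revcomp <- function(pssm) {
  counts <- pssm$counts[4:1, rev(seq_len(pssm$width)), drop = FALSE]
  rownames(counts) <- DNA_BASES
  out <- new_pssm(counts, n_sites = pssm$n_sites,
                  pseudocount = pssm$pseudocount,
                  motif_id = pssm$motif_id, source = pssm$source)
  out
}

## log2-odds matrix against an order-0 stationary background
pssm_logodds <- function(pssm, bg) {
  log2(pssm$freq / bg$stationary)
}

## per-column information content (bits) against a background
pssm_info <- function(pssm, bg) {
  colSums(pssm$freq * log2(pssm$freq / bg$stationary))
}

#' Exact score distribution of a PSSM under an order-0 background
#'
#' Computes, by dynamic programming over score-rounded columns, the exact
#' distribution of the log-odds score of a random width-w word drawn i.i.d.
#' from the background's stationary mononucleotide frequencies. Scores are
#' rounded to `granularity` (default 1e-3) so the support stays tractable.
#'
#' @param pssm a `pssm` object.
#' @param bg a `dna_background` (its stationary frequencies are used).
#' @param granularity rounding unit for log-odds scores.
#' @return an object of class `pssm_score_dist`: a list with `scores`
#'   (ascending achievable totals, in score units) and `tail` (`P(S >= s)`
#'   for each).
#' @export
pssm_score_dist <- function(pssm, bg, granularity = 1e-3) {
  lodds <- pssm_logodds(pssm, bg)
  s_int <- round(lodds / granularity)
  ## zero-probability cells (possible with pseudocount 0) sit at the bottom
  ## of the distribution; give them a finite floor well below everything else
  if (any(!is.finite(s_int))) {
    floor_val <- min(s_int[is.finite(s_int)]) - 2000
    s_int[!is.finite(s_int)] <- floor_val
  }
  p <- bg$stationary
  lo <- 0; hi <- 0
  dist <- 1  # probability vector over score offsets lo..hi
  for (j in seq_len(ncol(s_int))) {
    cj <- s_int[, j]
    nlo <- lo + min(cj); nhi <- hi + max(cj)
    nd <- numeric(nhi - nlo + 1)
    for (b in 1:4) {
      sh <- (lo + cj[b]) - nlo  # offset of dist within nd
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * p[b]
    }
    dist <- nd; lo <- nlo; hi <- nhi
  }
  keep <- dist > 0
  sc <- (lo:hi)[keep]
  pr <- dist[keep]
  tail <- rev(cumsum(rev(pr)))
  structure(list(scores = sc * granularity, tail = pmin(tail, 1),
                 granularity = granularity),
            class = "pssm_score_dist")
}

#' P-value of log-odds scores under the exact null distribution
#'
#' @param score numeric vector of log2-odds scores.
#' @param dist a `pssm_score_dist` from [pssm_score_dist()].
#' @return `P(S >= score)` for each score (monotone non-increasing in score).
#' @export
pssm_score_pvalue <- function(score, dist) {
  ## index of the smallest achievable score >= score (within rounding)
  idx <- findInterval(score - dist$granularity / 2, dist$scores) + 1
  out <- numeric(length(score))
  inb <- idx <= length(dist$scores)
  out[inb] <- dist$tail[idx[inb]]
  out[!inb] <- 0
  out[score <= dist$scores[1]] <- 1
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pssms a `pssm` or list of `pssm` objects.
#' @param path output file path.
#' @param bg optional `dna_background` supplying the background frequency
#'   line (uniform if omitted).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pssms, path, bg = NULL) {
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  freqs <- if (is.null(bg)) rep(0.25, 4) else bg$stationary
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, freqs), collapse = " "),
               ""), con)
  for (p in pssms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      p$width, round(p$n_sites)), con)
    for (j in seq_len(p$width))
      writeLines(paste(sprintf("%.6f", p$freq[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' @param path file path.
#' @return named list of `pssm` objects (source `"reference"`).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1
      while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j]))
        j <- j + 1
      if (j > length(lines)) stop("malformed MEME file: missing matrix for ", id)
      hdr <- lines[j]
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
      ns <- suppressWarnings(as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr)))
      if (is.na(ns)) ns <- 20
      rows <- lines[(j + 1):(j + w)]
      freq <- t(vapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
      out[[id]] <- pssm_from_freq(t(freq), motif_id = id, n_sites = ns)
      i <- j + w + 1
    } else i <- i + 1
  }
  out
}
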