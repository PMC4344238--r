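#' Train a Markov background model on DNA sequences
#'
#' Fits an order-`order` Markov chain to a set of DNA sequences by
#' maximum likelihood with a +1 pseudocount in every context cell, together
#' with the stationary (order-0) mononucleotide composition. The default
#' third-order model is the background used for de novo motif discovery on
#' pooled intergenic sequences.
#'
#' @param sequences character vector of DNA sequences (ACGT; N allowed and
#'   skipped).
#' @param order non-negative integer Markov order (default 3).
#' @return an object of class `dna_background` with elements `order`,
#'   `trans` (4^order x 4 matrix of transition frequencies, rows summing
#'   to 1) and `stationary` (named length-4 mononucleotide frequencies).
#' @export
train_background <- function(sequences, order = 3) {
  if (length(sequences) == 0 || all(nchar(sequences) == 0))
    stop("cannot train a background model on empty input")
  stopifnot(order >= 0)
  total <- sum(nchar(sequences))
  if (total <= 4^(order + 1))
    warning(sprintf(
      "only %d bases for an order-%d model (< 4^%d); estimates will lean on pseudocounts",
      total, order, order + 1))

  ints <- lapply(sequences, dna_to_int)
  base_counts <- rep(1, 4)  # +1 pseudocount
  for (v in ints) {
    ok <- v >= 0L
    base_counts <- base_counts + tabulate(v[ok] + 1L, nbins = 4)
  }
  stationary <- setNames(base_counts / sum(base_counts), DNA_BASES)

  ncontext <- 4^order
  counts <- matrix(1, nrow = ncontext, ncol = 4)  # +1 pseudocount per cell
  if (order == 0) {
    counts[1, ] <- base_counts
  } else {
    pow <- 4^((order - 1):0)
    for (v in ints) {
      n <- length(v)
      if (n <= order) next
      valid <- v >= 0L
      ctx <- rep(0L, n - order)
      ok <- rep(TRUE, n - order)
      for (j in seq_len(order)) {
        idx <- seq.int(j, n - order + j - 1)
        ctx <- ctx + v[idx] * pow[j]
        ok <- ok & valid[idx]
      }
      nxt <- v[(order + 1):n]
      ok <- ok & valid[(order + 1):n]
      if (!any(ok)) next
      tab <- table(factor(ctx[ok], levels = 0:(ncontext - 1)),
                   factor(nxt[ok], levels = 0:3))
      counts <- counts + as.matrix(tab)
    }
  }
  trans <- counts / rowSums(counts)
  rownames(trans) <- context_labels(order)
  colnames(trans) <- DNA_BASES
  structure(list(order = order, trans = trans, stationary = stationary),
            class = "dna_background")
}

context_labels <- function(order) {
  if (order == 0) return("")
  g <- expand.grid(rep(list(DNA_BASES), order), stringsAsFactors = FALSE)
  ## first factor varies fastest; we encode context with the first position
  ## as the most significant digit, so reverse the column order
  apply(g[, rev(seq_len(order)), drop = FALSE], 1, paste, collapse = "")
}

#' @export
print.dna_background <- function(x, ...) {
  cat(sprintf("DNA background model (order %d)\n", x$order))
  cat("stationary frequencies:",
      paste(sprintf("%s=%.3f", names(x$stationary), x$stationary),
            collapse = " "), "\n")
  invisible(x)
}

#' Sample sequences from a background model
#'
#' Draws DNA sequences from a fitted `dna_background` Markov chain; used to
#' generate synthetic intergenic sequence and null sequence for calibration
#' checks.
#'
#' @param bg a `dna_background` object.
#' @param lengths integer vector; one sequence is generated per element.
#' @return character vector of sequences.
#' @export
sample_background <- function(bg, lengths) {
  pow <- if (bg$order > 0) 4^((bg$order - 1):0) else integer(0)
  cum <- t(apply(bg$trans, 1, cumsum))
  cst <- cumsum(bg$stationary)
  order <- bg$order
  vapply(lengths, function(L) {
    if (L <= 0) return("")
    u <- runif(L)
    v <- integer(L)
    for (i in seq_len(L)) {
      if (order == 0 || i <= order) {
        v[i] <- findInterval(u[i], cst, left.open = TRUE)
      } else {
        ctx <- sum(v[(i - order):(i - 1)] * pow)
        v[i] <- findInterval(u[i], cum[ctx + 1L, ], left.open = TRUE)
      }
    }
    int_to_dna(pmin(v, 3L))
  }, character(1))
}
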