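#' Read an expression matrix from TSV
#'
#' Expects gene ids in the first column and condition ids in the header.
#'
#' @param path TSV file.
#' @return numeric matrix (genes x conditions) with dimnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#' @param mat genes x conditions matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Standardize expression rows to z-scores
#'
#' Row-standardizes a (log-scale, normalized) expression matrix: each row is
#' centred and scaled to unit standard deviation (denominator n-1). Constant
#' rows cannot be standardized and are dropped with a warning.
#'
#' @param mat numeric matrix, genes x conditions (>= 2 conditions).
#' @return the standardized matrix (possibly with fewer rows).
#' @export
standardize_rows <- function(mat) {
  stopifnot(ncol(mat) >= 2)
  sds <- apply(mat, 1, sd)
  drop <- sds < 1e-12 | is.na(sds)
  if (any(drop)) {
    warning(sprintf("dropping %d constant expression row(s): %s",
                    sum(drop),
                    paste(head(rownames(mat)[drop], 5), collapse = ", ")))
    mat <- mat[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  (mat - rowMeans(mat)) / sds
}

#' Refine a motif-defined gene set into a condition-specific bicluster
#'
#' Greedy alternating refinement of a gene set against a row-standardized
#' expression matrix: starting from all conditions, the procedure alternately
#' drops the gene least correlated with the others and the condition whose
#' exclusion most improves the mean pairwise absolute correlation, stopping
#' when no drop improves the score beyond a chance-level gain. The refined
#' bicluster is accepted when it keeps at least `min_module` genes and
#' `min_conditions` conditions and its score beats `n_perm` equally-sized
#' random gene sets drawn from a within-row permuted copy of the matrix and
#' subjected to the same refinement (permutation p-value at most `p_max`).
#'
#' @param gene_set character vector of gene ids (genes absent from the
#'   matrix are dropped first).
#' @param matrix row-standardized expression matrix.
#' @param min_module minimum bicluster gene count (default 3).
#' @param min_conditions minimum bicluster condition count (default 30).
#' @param p_max permutation p-value threshold (default 0.001).
#' @param n_perm permutation draws (default 1000).
#' @param seed optional RNG seed.
#' @param min_gain minimum absolute score gain for a condition removal
#'   (gene removals require ten times this); controls greedy stopping.
#' @param var_protect conditions contributing less than this fraction of the
#'   average per-condition variance are protected from removal (they carry
#'   weak but genuine signal).
#' @return `NULL` on rejection, otherwise a list of class `bicluster` with
#'   `genes`, `conditions`, `mean_abs_pairwise_corr` and `p_value`.
#' @export
refine_coexpression <- function(gene_set, matrix, min_module = 3,
                                min_conditions = 30, p_max = 0.001,
                                n_perm = 1000, seed = NULL,
                                min_gain = 0.002, var_protect = 0.5) {
  genes <- intersect(unique(gene_set), rownames(matrix))
  if (length(genes) < min_module) return(NULL)
  if (ncol(matrix) < min_conditions) return(NULL)
  X <- matrix[genes, , drop = FALSE]
  fit <- run_refine(X, min_module, min_conditions, min_gain, var_protect)
  if (sum(fit$genes) < min_module || sum(fit$conditions) < min_conditions)
    return(NULL)
  null <- with_seed(seed, {
    ## null: equally sized random gene sets from a within-row permuted copy
    ## of the matrix (random sets from the raw matrix would be contaminated
    ## by genuine co-regulation), refined with the same greedy procedure
    perm <- t(apply(matrix, 1, sample))
    vapply(seq_len(n_perm), function(i) {
      rg <- sample.int(nrow(perm), length(genes))
      run_refine(perm[rg, , drop = FALSE], min_module, min_conditions,
                 min_gain, var_protect)$score
    }, numeric(1))
  })
  p <- emp_pvalue(sum(null >= fit$score - 1e-12), n_perm)
  if (p > p_max) return(NULL)
  structure(list(genes = genes[fit$genes],
                 conditions = colnames(matrix)[fit$conditions],
                 mean_abs_pairwise_corr = fit$score,
                 p_value = p),
            class = "bicluster")
}

## sign-align rows to the centroid (repressed members anti-correlate), then
## run the C++ greedy refinement
run_refine <- function(X, min_genes, min_conds, min_gain, var_protect) {
  cent <- colMeans(X)
  flips <- apply(X, 1, function(r) {
    rc <- suppressWarnings(cor(r, cent))
    !is.na(rc) && rc < 0
  })
  X[flips, ] <- -X[flips, , drop = FALSE]
  cpp_refine_bicluster(X, as.integer(min_genes), as.integer(min_conds),
                       min_gain, var_protect)
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d genes x %d conditions, mean |r| = %.3f (p = %.4g)\n",
              length(x$genes), length(x$conditions),
              x$mean_abs_pairwise_corr, x$p_value))
  invisible(x)
}

#' Distance-based operon predictions from gene annotations
#'
#' Fallback rule when curated predictions are unavailable: adjacent
#' co-strand genes with an intergenic gap of at most `max_gap` bp are
#' predicted to be in one operon. Pairs are directed in transcription order
#' (upstream gene first).
#'
#' @param genes gene table from [load_annotations()] (one genome).
#' @param max_gap maximum intergenic gap in bp (default 50).
#' @return data frame with columns `upstream_gene`, `downstream_gene`.
#' @export
predict_operons_by_distance <- function(genes, max_gap = 50) {
  out <- list()
  for (rep_id in unique(genes$replicon_id)) {
    g <- genes[genes$replicon_id == rep_id, ]
    g <- g[order(g$start), ]
    if (nrow(g) < 2) next
    for (i in 1:(nrow(g) - 1)) {
      gap <- g$start[i + 1] - g$end[i] - 1
      if (g$strand[i] != g$strand[i + 1] || gap > max_gap) next
      if (g$strand[i] == "+")
        out[[length(out) + 1]] <- data.frame(
          upstream_gene = g$gene_id[i], downstream_gene = g$gene_id[i + 1],
          stringsAsFactors = FALSE)
      else
        out[[length(out) + 1]] <- data.frame(
          upstream_gene = g$gene_id[i + 1], downstream_gene = g$gene_id[i],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(upstream_gene = character(0),
                      downstream_gene = character(0)))
  do.call(rbind, out)
}

#' Extend a target set through predicted operons
#'
#' Transitively adds downstream operon genes: a gene is added when it is
#' predicted (by distance) to be in an operon with a gene already in the set
#' and the pair's Pearson correlation across **all** conditions is at least
#' `r_min`. Never removes seed targets; idempotent.
#'
#' @param targets character vector of seed target gene ids.
#' @param operon_predictions data frame (`upstream_gene`, `downstream_gene`).
#' @param matrix expression matrix (all conditions).
#' @param r_min minimum Pearson correlation (default 0.8).
#' @return extended character vector of gene ids.
#' @export
operon_extend <- function(targets, operon_predictions, matrix, r_min = 0.8) {
  set <- unique(targets)
  repeat {
    added <- FALSE
    for (k in seq_len(nrow(operon_predictions))) {
      u <- operon_predictions$upstream_gene[k]
      d <- operon_predictions$downstream_gene[k]
      if (!(u %in% set) || d %in% set) next
      if (!(u %in% rownames(matrix)) || !(d %in% rownames(matrix))) next
      r <- suppressWarnings(cor(matrix[u, ], matrix[d, ]))
      if (!is.na(r) && r >= r_min) { set <- c(set, d); added <- TRUE }
    }
    if (!added) break
  }
  set
}
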