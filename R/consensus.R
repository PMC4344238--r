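ranked_edge_list <- function(df, approach_id, max_edges = 50000) {
  df <- df[order(-df$score, df$tf, df$target), , drop = FALSE]
  df <- df[df$tf != df$target, , drop = FALSE]
  if (nrow(df) > max_edges) df <- df[seq_len(max_edges), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$approach_id <- approach_id
  rownames(df) <- NULL
  df[, c("approach_id", "tf", "target", "score", "rank")]
}

#' CLR-style mutual-information network scores
#'
#' Estimates mutual information between every pair of genes via
#' equal-frequency binning (default 10 bins), converts each TF-target MI to
#' a background-corrected score `sqrt(max(z_tf, 0)^2 + max(z_target, 0)^2)`,
#' where `z_i` standardizes the MI against gene i's own MI distribution, and
#' ranks TF-target edges by this score. Self-edges are excluded.
#'
#' @param matrix expression matrix (genes x conditions; >= 20 conditions
#'   recommended, warns below).
#' @param tf_ids candidate regulator gene ids.
#' @param nbins number of equal-frequency bins (default 10).
#' @param max_edges truncation after ranking (default 50000).
#' @return a ranked edge list data frame (`approach_id`, `tf`, `target`,
#'   `score`, `rank`).
#' @export
clr_scores <- function(matrix, tf_ids, nbins = 10, max_edges = 50000) {
  if (ncol(matrix) < 20)
    warning("fewer than 20 conditions; mutual information estimates will be noisy")
  tf_ids <- intersect(tf_ids, rownames(matrix))
  stopifnot(length(tf_ids) > 0)
  m <- ncol(matrix)
  bins <- t(apply(matrix, 1, function(x)
    as.integer(floor((rank(x, ties.method = "first") - 1) * nbins / m))))
  mi <- cpp_mi_matrix(bins, as.integer(nbins))
  dimnames(mi) <- list(rownames(matrix), rownames(matrix))
  diag(mi) <- NA
  mu <- rowMeans(mi, na.rm = TRUE)
  sdv <- apply(mi, 1, sd, na.rm = TRUE)
  sdv[sdv < 1e-12] <- 1e-12
  z <- (mi - mu) / sdv           # z against the row gene's distribution
  zt <- t((t(mi) - mu) / sdv)    # z against the column gene's distribution
  z[z < 0] <- 0; zt[zt < 0] <- 0
  sc <- sqrt(z^2 + zt^2)
  rows <- do.call(rbind, lapply(tf_ids, function(tf) {
    targets <- setdiff(rownames(matrix), tf)
    data.frame(tf = tf, target = targets, score = sc[tf, targets],
               stringsAsFactors = FALSE)
  }))
  ranked_edge_list(rows, "clr", max_edges)
}

#' Tree-ensemble regression importance network scores
#'
#' For every target gene, fits a random-forest regression of the target's
#' expression on all TF expression profiles and scores each TF-target edge
#' by the TF's impurity importance. Constant targets are skipped.
#'
#' @param matrix expression matrix.
#' @param tf_ids candidate regulator gene ids (>= 2).
#' @param seed RNG seed for the forests.
#' @param num_trees trees per forest (default 200).
#' @param max_edges truncation after ranking.
#' @return a ranked edge list data frame.
#' @export
tree_importance_scores <- function(matrix, tf_ids, seed = NULL,
                                   num_trees = 200, max_edges = 50000) {
  tf_ids <- intersect(tf_ids, rownames(matrix))
  stopifnot(length(tf_ids) >= 2)
  preds <- t(matrix[tf_ids, , drop = FALSE])
  rows <- list()
  targets <- rownames(matrix)
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    y <- matrix[tg, ]
    if (sd(y) < 1e-12) next
    use <- setdiff(tf_ids, tg)
    if (length(use) < 2) next
    x <- preds[, use, drop = FALSE]
    fit <- ranger::ranger(
      x = x, y = y, num.trees = num_trees, importance = "impurity",
      mtry = max(1, floor(sqrt(ncol(x)))), min.node.size = 5,
      seed = if (is.null(seed)) NULL else seed + ti,
      num.threads = 1, verbose = FALSE)
    imp <- fit$variable.importance
    rows[[length(rows) + 1]] <- data.frame(
      tf = names(imp), target = tg, score = as.numeric(imp),
      stringsAsFactors = FALSE)
  }
  ranked_edge_list(do.call(rbind, rows), "tree", max_edges)
}

#' Import an externally computed ranked edge list
#'
#' Reads a TSV with columns `tf`, `target`, `score`, keeps the maximum score
#' for duplicated pairs (with a warning), sorts by score and truncates to
#' the top `max_edges` (default 50,000) interactions.
#'
#' @param path TSV file.
#' @param approach_id label for the approach.
#' @param max_edges truncation limit.
#' @return a ranked edge list data frame.
#' @export
import_ranked_list <- function(path, approach_id, max_edges = 50000) {
  df <- read_tsv(path)
  if (!all(c("tf", "target", "score") %in% names(df)))
    stop("ranked list must have columns tf, target, score")
  bad <- which(is.na(df$score) | df$tf == "" | df$target == "")
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(head(bad + 1, 5), collapse = ", "))
  key <- paste(df$tf, df$target, sep = "->")
  if (anyDuplicated(key)) {
    warning("duplicate (tf, target) rows; keeping the maximum score")
    df <- df[order(-df$score), ]
    df <- df[!duplicated(paste(df$tf, df$target, sep = "->")), ]
  }
  ranked_edge_list(df[, c("tf", "target", "score")], approach_id, max_edges)
}

#' Convert edge scores to empirical p-values
#'
#' `p = (# random scores >= score) / n_perm`, floored at `1 / (n_perm + 1)`.
#' For the built-in scorers the random scores are produced by re-running the
#' same scorer on a within-row permuted expression matrix (destroying
#' TF-target dependence while preserving marginals); for imported lists a
#' vector of null scores must be supplied.
#'
#' @param edges ranked edge list.
#' @param null_scores optional numeric vector of null scores.
#' @param matrix,tf_ids expression matrix and regulators, used to generate
#'   null scores for approaches `"clr"` and `"tree"` when `null_scores` is
#'   missing.
#' @param n_perm number of random scores (default 10000).
#' @param seed RNG seed.
#' @return the edge list with a `p_value` column.
#' @export
scores_to_pvalues <- function(edges, null_scores = NULL, matrix = NULL,
                              tf_ids = NULL, n_perm = 10000, seed = NULL) {
  stopifnot(nrow(edges) > 0)
  if (is.null(null_scores)) {
    stopifnot(!is.null(matrix), !is.null(tf_ids))
    approach <- edges$approach_id[1]
    null_scores <- with_seed(seed, {
      perm <- t(apply(matrix, 1, sample))
      dimnames(perm) <- dimnames(matrix)
      nl <- switch(approach,
                   clr = clr_scores(perm, tf_ids),
                   tree = tree_importance_scores(perm, tf_ids, seed = seed),
                   stop("no built-in null for approach ", approach))
      if (nrow(nl) > n_perm) sample(nl$score, n_perm) else nl$score
    })
  }
  n <- length(null_scores)
  srt <- sort(null_scores)
  n_ge <- n - findInterval(edges$score - 1e-12, srt)
  edges$p_value <- pmax(n_ge / n, 1 / (n + 1))
  edges
}

#' Combine approach p-values into consensus expression edges
#'
#' For each TF-target pair present in at least one approach's truncated
#' ranking, averages the `-log10` p-values over the three approach slots
#' (a missing approach contributes 0): `R_exp = (1/3) * sum(-log10 p)`.
#' Pairs absent from every list are not emitted. The divisor stays 3 even
#' when fewer approaches are supplied.
#'
#' @param p_lists list (length 1-3) of edge lists carrying `p_value`
#'   columns (from [scores_to_pvalues()]).
#' @return data frame with `tf`, `target`, one `p_<approach>` column per
#'   input, and `r_exp`, sorted by decreasing `r_exp`.
#' @export
combine_rexp <- function(p_lists) {
  stopifnot(length(p_lists) >= 1, length(p_lists) <= 3)
  keyed <- lapply(p_lists, function(e)
    setNames(e$p_value, paste(e$tf, e$target, sep = "->")))
  keys <- unique(unlist(lapply(keyed, names)))
  contrib <- vapply(keyed, function(kp) {
    v <- kp[keys]
    out <- -log10(v)
    out[is.na(v)] <- 0
    out
  }, numeric(length(keys)))
  contrib <- matrix(contrib, nrow = length(keys))
  r_exp <- rowSums(contrib) / 3
  parts <- strsplit(keys, "->", fixed = TRUE)
  out <- data.frame(tf = vapply(parts, `[`, "", 1),
                    target = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  for (i in seq_along(p_lists)) {
    nm <- paste0("p_", p_lists[[i]]$approach_id[1])
    out[[nm]] <- unname(keyed[[i]][keys])
  }
  out$r_exp <- r_exp
  out <- out[order(-out$r_exp, out$tf, out$target), ]
  rownames(out) <- NULL
  out
}

#' Precision-targeted score cutoff for the consensus network
#'
#' Walks the ranked consensus edges in prefixes of `interval` predictions,
#' computes the gold-standard-restricted precision of each prefix, and
#' returns the `r_exp` score at the boundary of the largest prefix whose
#' precision is at least `target_precision` (`NA` when no prefix qualifies).
#'
#' @param edges consensus edges (from [combine_rexp()]), ranked.
#' @param gold a [gold_standard()].
#' @param target_precision required precision (default 0.95).
#' @param interval prefix step (default 100).
#' @return the score cutoff, or `NA`.
#' @export
threshold_by_precision <- function(edges, gold, target_precision = 0.95,
                                   interval = 100) {
  n <- nrow(edges)
  stops <- unique(c(seq(interval, n, by = interval), n))
  best <- NA_real_
  for (s in stops) {
    pre <- edges[seq_len(s), , drop = FALSE]
    prec <- restricted_precision(pre, gold)
    if (!is.na(prec) && prec >= target_precision) best <- pre$r_exp[s]
  }
  best
}
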