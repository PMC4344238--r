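new_trn_network <- function(edges) {
  cols <- c("tf", "target", "cluster_id", "provenance", "score", "sign")
  for (cl in setdiff(cols, names(edges)))
    edges[[cl]] <- rep(NA, nrow(edges))
  edges <- edges[, cols]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 tfs = unique(edges$tf),
                 targets = unique(edges$target)),
            class = "trn_network")
}

#' @export
print.trn_network <- function(x, ...) {
  cat(sprintf("TRN: %d interactions, %d TFs, %d target genes\n",
              nrow(x$edges), length(x$tfs), length(x$targets)))
  tab <- table(x$edges$provenance)
  cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Build the comparative-genomics core network
#'
#' Emits one edge from each cluster's rank-1 TF to every bicluster member
#' gene and every operon-extended gene. Edge sign is annotated from the mean
#' signed TF-member correlation over the bicluster's conditions (activation
#' when positive, repression when negative, undetermined when the TF is not
#' on the array); the sign is metadata only. Genes shared by clusters with
#' different rank-1 TFs keep both edges (combinatorial regulation).
#'
#' @param biclusters named list of `bicluster` objects.
#' @param rankings named list cluster id -> ranking from
#'   [rank_tfs_for_cluster()] (rank-1 row is used).
#' @param matrix expression matrix (for sign annotation).
#' @param operon_predictions optional operon pair predictions for target
#'   extension (with `matrix` and `r_min` as in [operon_extend()]).
#' @param r_min operon correlation threshold.
#' @return a `trn_network`.
#' @export
build_core_network <- function(biclusters, rankings, matrix,
                               operon_predictions = NULL, r_min = 0.8) {
  rows <- list()
  for (cid in names(biclusters)) {
    rk <- rankings[[cid]]
    if (is.null(rk) || !nrow(rk)) next
    tf <- rk$tf_id[rk$rank == 1]
    score <- rk$r_score[rk$rank == 1]
    cl <- biclusters[[cid]]
    targets <- cl$genes
    if (!is.null(operon_predictions))
      targets <- operon_extend(targets, operon_predictions, matrix,
                               r_min = r_min)
    sign <- edge_sign(tf, cl, matrix)
    rows[[length(rows) + 1]] <- data.frame(
      tf = tf, target = targets, cluster_id = cid,
      provenance = "comparative", score = score, sign = sign,
      stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(0), target = character(0),
               cluster_id = character(0), provenance = character(0),
               score = numeric(0), sign = character(0))
  edges <- edges[!duplicated(paste(edges$tf, edges$target, sep = "->")), ,
                 drop = FALSE]
  new_trn_network(edges)
}

edge_sign <- function(tf, bicluster, matrix) {
  if (!(tf %in% rownames(matrix))) return("undetermined")
  conds <- intersect(bicluster$conditions, colnames(matrix))
  genes <- intersect(setdiff(bicluster$genes, tf), rownames(matrix))
  if (!length(genes) || length(conds) < 3) return("undetermined")
  rs <- vapply(genes, function(g)
    suppressWarnings(cor(matrix[tf, conds], matrix[g, conds])), numeric(1))
  m <- mean(rs, na.rm = TRUE)
  if (is.na(m) || abs(m) < 1e-9) "undetermined"
  else if (m > 0) "activation" else "repression"
}

#' Merge the core network with consensus expression edges
#'
#' Core (comparative-genomics) predictions take precedence at TF
#' granularity: expression edges are added only for TFs that do not appear
#' as regulators in the core network. Expression edges must already be
#' operon-extended; they are filtered at `cutoff` here.
#'
#' @param core the core `trn_network`.
#' @param expression_edges consensus edges (`tf`, `target`, `r_exp`).
#' @param cutoff minimum `r_exp` (default 1.3).
#' @return the merged `trn_network`.
#' @export
merge_networks <- function(core, expression_edges, cutoff = 1.3) {
  ex <- expression_edges
  if (!is.null(ex) && nrow(ex)) {
    if (!is.na(cutoff)) ex <- ex[ex$r_exp >= cutoff, , drop = FALSE]
    ex <- ex[!(ex$tf %in% core$edges$tf), , drop = FALSE]
    ex <- ex[!duplicated(paste(ex$tf, ex$target, sep = "->")), , drop = FALSE]
  }
  if (is.null(ex) || !nrow(ex)) return(core)
  add <- data.frame(tf = ex$tf, target = ex$target,
                    cluster_id = NA_character_, provenance = "expression",
                    score = ex$r_exp, sign = "undetermined",
                    stringsAsFactors = FALSE)
  new_trn_network(rbind(core$edges, add))
}

#' Export a network to a TSV edge list with a summary block
#'
#' Writes the edge table to `path` and a small summary table
#' (`<path>.summary`) with the headline counts (clusters, TFs, motifs when
#' supplied, interactions, genes).
#'
#' @param net a `trn_network`.
#' @param path output TSV path.
#' @param n_motifs optional motif count for the summary.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, n_motifs = NA) {
  write_tsv(net$edges, path)
  s <- network_summary(net, n_motifs)
  write_tsv(data.frame(quantity = names(s), value = unlist(s)),
            paste0(path, ".summary"))
  invisible(path)
}

network_summary <- function(net, n_motifs = NA) {
  list(clusters = length(unique(stats::na.omit(net$edges$cluster_id))),
       tfs = length(net$tfs),
       motifs = n_motifs,
       interactions = nrow(net$edges),
       genes = length(unique(c(net$edges$tf, net$edges$target))))
}

#' Read a network exported by [export_network()]
#' @param path TSV path.
#' @return a `trn_network`.
#' @export
read_network <- function(path) {
  df <- read_tsv(path)
  df$cluster_id <- as.character(df$cluster_id)
  new_trn_network(df)
}
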