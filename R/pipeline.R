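#' Control parameters for the TRN inference pipeline
#'
#' Defaults follow the workflow's published operating point: upstream IGRs
#' strictly longer than 40 bp, at least 4 IGR sequences per footprinting
#' group, an order-3 background, up to 3 ZOOPS motifs per group at E <= 0.01
#' with width cap 30, motif clustering at 33% hit overlap and q < 0.01,
#' bicluster acceptance at >= 3 genes, >= 30 conditions and permutation
#' p <= 0.001, operon extension at r >= 0.8, 1000-draw criterion nulls,
#' top-50,000 edge lists with 10,000-draw score nulls, and a 95%
#' precision-targeted consensus cutoff (fallback score cutoff 1.3).
#'
#' @param ... named overrides.
#' @return a list of class `trn_control`.
#' @export
infer_trn_control <- function(...) {
  ctl <- list(
    min_igr_len = 40, min_seqs = 4, bg_order = 3,
    nmotifs = 3, evalue_max = 0.01, widths = c(10, 14), max_width = 30,
    p_max_hits = 1e-5, q_max = 0.01, min_overlap = 0.33, hit_bin = 5,
    n_shuffle = 1000,
    min_module = 3, min_conditions = 30, bicluster_p = 0.001,
    n_perm_bicluster = 1000,
    operon_max_gap = 50, operon_r = 0.8,
    n_null = 1000,
    clr_bins = 10, tree_num_trees = 100, n_perm_scores = 10000,
    max_edges = 50000,
    precision_target = 0.95, pr_interval = 100, rexp_cutoff = 1.3,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(ctl))
  if (length(unknown)) stop("unknown control fields: ",
                            paste(unknown, collapse = ", "))
  ctl[names(dots)] <- dots
  class(ctl) <- "trn_control"
  ctl
}

#' Infer an integrated transcriptional regulatory network
#'
#' Runs the full workflow on a `trn_data` input (see [simulate_trn_data()]
#' for the synthetic variant): upstream-IGR extraction across genomes,
#' order-3 background training, per-ortholog-group ZOOPS motif discovery,
#' genome-wide scanning, motif family clustering, expression bicluster
#' refinement of motif-defined gene sets, four-criterion TF-to-cluster
#' linking with permutation p-values, core network assembly with operon
#' extension, an expression-only consensus network (CLR-style and
#' tree-ensemble scorers), precision-targeted thresholding, and the
#' precedence merge in which comparative-genomics predictions displace
#' expression-only predictions for the same TF.
#'
#' @param data a `trn_data` (fields: `target_genome`, `genome_ids`,
#'   `genomes`, `annotations`, `groups`, `expression`, `tf_table`,
#'   `library`, optional `gold`).
#' @param control a [infer_trn_control()].
#' @param gold optional `gold_standard` used only to pick the consensus
#'   score cutoff (defaults to `data$gold`); pass `NULL` to use the fixed
#'   fallback cutoff.
#' @param verbose print stage progress.
#' @return an object of class `trn_fit`.
#' @export
infer_trn <- function(data, control = infer_trn_control(),
                      gold = data$gold, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  target <- data$target_genome
  tf_ids <- data$tf_table$tf_id

  expr <- standardize_rows(data$expression)

  say("extracting upstream intergenic regions ...")
  igrs <- do.call(rbind, lapply(data$genome_ids, function(g)
    extract_upstream_igrs(data$annotations[data$annotations$genome_id == g, ],
                          data$genomes[[g]], min_len = control$min_igr_len)))
  bg <- train_background(igrs$sequence, order = control$bg_order)
  fp_groups <- assemble_footprinting_groups(data$groups, igrs,
                                            min_seqs = control$min_seqs,
                                            target_genome = target)
  say("footprinting %d ortholog groups ...", length(fp_groups))
  ## shared background pool and search calibration across all groups
  grp_lengths <- unlist(lapply(fp_groups, nchar), use.names = FALSE)
  grp_sizes <- vapply(fp_groups, length, integer(1))
  pool_cal <- with_seed(control$seed, {
    null_pool <- build_null_pool(bg, max(grp_lengths), 200)
    cal <- discovery_calibration(bg, lengths = grp_lengths,
                                 n_seqs = grp_sizes,
                                 widths = control$widths,
                                 null_pool = null_pool)
    list(pool = null_pool, cal = cal)
  })
  motifs <- list()
  for (gid in names(fp_groups)) {
    found <- discover_motifs_zoops(fp_groups[[gid]], bg,
                                   nmotifs = control$nmotifs,
                                   max_width = control$max_width,
                                   evalue_max = control$evalue_max,
                                   widths = control$widths,
                                   null_pool = pool_cal$pool,
                                   calibration = pool_cal$cal)
    for (m in found) {
      m$motif_id <- paste0(gid, "_", m$motif_id)
      motifs[[m$motif_id]] <- m
    }
  }
  say("found %d phylogenetically conserved motifs", length(motifs))
  fit <- structure(list(control = control, background = bg,
                        n_fp_groups = length(fp_groups),
                        motifs = motifs),
                   class = "trn_fit")
  if (!length(motifs)) {
    fit$network <- new_trn_network(data.frame(tf = character(0),
                                              target = character(0)))
    return(fit)
  }

  contexts <- lapply(setNames(data$genome_ids, data$genome_ids), function(g)
    igr_scan_context(igrs[igrs$genome_id == g, ]))
  say("scanning the target genome ...")
  hits_target <- do.call(rbind, lapply(motifs, scan_for_hits, igrs = NULL,
                                       bg = bg, p_max = control$p_max_hits,
                                       context = contexts[[target]]))
  say("clustering %d motifs ...", length(motifs))
  clusters <- cluster_motifs(motifs, hits_target,
                             q_max = control$q_max,
                             min_overlap = control$min_overlap,
                             bin = control$hit_bin,
                             n_shuffle = control$n_shuffle,
                             seed = control$seed)
  say("%d motif family clusters", length(clusters))

  say("rebuilding species PSSMs and refining biclusters ...")
  biclusters <- list()
  cluster_pssms <- list()
  mocc_by_cluster <- list()
  cluster_info <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    ## genes supported by at least two member motifs (chance hits are
    ## member-specific; genuine shared sites are found by most members)
    h_all <- hits_target[hits_target$motif_id %in% cl$members, , drop = FALSE]
    support <- tapply(h_all$motif_id, h_all$gene_id,
                      function(x) length(unique(x)))
    genes <- names(support)[support >= min(2, length(cl$members))]
    bic <- refine_coexpression(genes, expr,
                               min_module = control$min_module,
                               min_conditions = control$min_conditions,
                               p_max = control$bicluster_p,
                               n_perm = control$n_perm_bicluster,
                               seed = control$seed + ci)
    if (is.null(bic)) next
    rb <- rebuild_cluster_pssms(cl, motifs, contexts, bg,
                                p_max = control$p_max_hits)
    if (is.null(rb$species_pssms[[target]])) next
    cid <- cl$cluster_id
    biclusters[[cid]] <- bic
    cluster_pssms[[cid]] <- rb$species_pssms[[target]]
    mocc_by_cluster[[cid]] <- motif_occurrence_correlations(
      rb$species_hits, data$groups, data$genome_ids, target)
    cluster_info[[cid]] <- list(members = cl$members,
                                representative = rb$representative,
                                species_pssms = rb$species_pssms)
  }
  say("%d biclusters accepted", length(biclusters))
  fit$motif_clusters <- clusters
  fit$cluster_info <- cluster_info
  fit$biclusters <- biclusters
  fit$cluster_pssms <- cluster_pssms
  if (!length(biclusters)) {
    fit$network <- new_trn_network(data.frame(tf = character(0),
                                              target = character(0)))
    return(fit)
  }

  say("linking TFs to clusters ...")
  gene_table <- data$annotations[data$annotations$genome_id == target, ]
  presence <- tf_presence_matrix(tf_ids, data$groups, data$genome_ids, target)
  qtab <- dbd_q_table(cluster_pssms, data$library,
                      n_shuffle = control$n_shuffle, seed = control$seed)
  tf_table <- data$tf_table
  if (is.null(tf_table$replicon_id)) {
    idx <- match(tf_table$tf_id, gene_table$gene_id)
    tf_table$replicon_id <- gene_table$replicon_id[idx]
    tf_table$gene_index <- gene_table$gene_index[idx]
  }
  nulls <- build_nulls(tf_table, biclusters, expr, gene_table, qtab,
                       mocc_by_cluster, presence, n = control$n_null,
                       seed = control$seed)
  scores <- score_tf_clusters(tf_table, biclusters, expr, gene_table, qtab,
                              mocc_by_cluster, presence, nulls)
  rankings <- lapply(setNames(names(biclusters), names(biclusters)),
                     function(cid)
                       rank_tfs_for_cluster(scores, top_k = 3,
                                            cluster_id = cid))
  fit$presence <- presence
  fit$dbd_qtab <- qtab
  fit$nulls <- nulls
  fit$scores <- scores
  fit$rankings <- rankings

  say("assembling the core network ...")
  operon_preds <- predict_operons_by_distance(gene_table,
                                              max_gap = control$operon_max_gap)
  core <- build_core_network(biclusters, rankings, expr,
                             operon_predictions = operon_preds,
                             r_min = control$operon_r)
  fit$operon_predictions <- operon_preds
  fit$core <- core

  say("expression-only consensus network ...")
  clr <- clr_scores(expr, tf_ids, nbins = control$clr_bins,
                    max_edges = control$max_edges)
  clr <- scores_to_pvalues(clr, matrix = expr, tf_ids = tf_ids,
                           n_perm = control$n_perm_scores,
                           seed = control$seed + 101)
  tree <- tree_importance_scores(expr, tf_ids, seed = control$seed + 202,
                                 num_trees = control$tree_num_trees,
                                 max_edges = control$max_edges)
  tree <- scores_to_pvalues(tree, matrix = expr, tf_ids = tf_ids,
                            n_perm = control$n_perm_scores,
                            seed = control$seed + 303)
  consensus <- combine_rexp(list(clr, tree))
  consensus <- extend_consensus_edges(consensus, operon_preds, expr,
                                      r_min = control$operon_r)
  cutoff <- if (!is.null(gold)) {
    threshold_by_precision(consensus, gold,
                           target_precision = control$precision_target,
                           interval = control$pr_interval)
  } else control$rexp_cutoff
  if (is.na(cutoff)) cutoff <- Inf
  fit$consensus <- consensus
  fit$consensus_cutoff <- cutoff

  fit$network <- merge_networks(core, consensus, cutoff = cutoff)
  fit$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  say("done in %.1f s: %d interactions", fit$elapsed, nrow(fit$network$edges))
  fit
}

## operon extension of consensus edges: downstream chain genes inherit the
## seed edge's score
extend_consensus_edges <- function(edges, operon_preds, matrix, r_min = 0.8) {
  if (!nrow(edges) || !nrow(operon_preds)) return(edges)
  add <- list()
  for (tf in unique(edges$tf)) {
    sub <- edges[edges$tf == tf, , drop = FALSE]
    ext <- operon_extend(sub$target, operon_preds, matrix, r_min = r_min)
    new <- setdiff(ext, sub$target)
    if (!length(new)) next
    ## walk each new gene back to its operon seed to inherit a score
    for (g in new) {
      up <- operon_preds$upstream_gene[operon_preds$downstream_gene == g]
      seed_score <- max(sub$r_exp[sub$target %in% up], -Inf)
      if (!is.finite(seed_score)) seed_score <- max(sub$r_exp)
      row <- sub[1, , drop = FALSE]
      row$target <- g
      row$r_exp <- seed_score
      add[[length(add) + 1]] <- row
    }
  }
  if (!length(add)) return(edges)
  out <- rbind(edges, do.call(rbind, add))
  out <- out[!duplicated(paste(out$tf, out$target, sep = "->")), ]
  out <- out[order(-out$r_exp, out$tf, out$target), ]
  rownames(out) <- NULL
  out
}

#' @export
print.trn_fit <- function(x, ...) {
  cat("Integrated TRN inference fit\n")
  cat(sprintf("  footprinting groups : %d\n", x$n_fp_groups))
  cat(sprintf("  conserved motifs    : %d\n", length(x$motifs)))
  cat(sprintf("  motif clusters      : %d\n", length(x$motif_clusters)))
  cat(sprintf("  biclusters          : %d\n", length(x$biclusters)))
  if (!is.null(x$network)) {
    s <- network_summary(x$network, n_motifs = length(x$motifs))
    cat(sprintf("  network             : %d interactions, %d TFs, %d genes\n",
                s$interactions, s$tfs, s$genes))
  }
  invisible(x)
}

#' @export
summary.trn_fit <- function(object, gold = NULL, ...) {
  print(object)
  if (!is.null(gold) && !is.null(object$network)) {
    ev <- evaluate_network(object$network, gold)
    cat(sprintf("  vs gold standard    : precision %.3f, recall %.3f\n",
                ev$precision, ev$recall))
  }
  invisible(object)
}

#' Evaluate a network against a gold standard
#'
#' @param net a `trn_network`.
#' @param gold a `gold_standard`.
#' @return list with `precision`, `restricted_precision`, `recall`,
#'   `n_predictions`.
#' @export
evaluate_network <- function(net, gold) {
  preds <- net$edges[, c("tf", "target")]
  list(precision = precision(preds, gold),
       restricted_precision = restricted_precision(preds, gold),
       recall = recall(preds, gold),
       n_predictions = nrow(net$edges))
}

#' Re-rank cluster regulators using the correlation criterion only
#'
#' Sets the proximity, DBD and phylogenetic p-values to 1 for every pair and
#' re-ranks, giving the expression-only baseline linker for comparisons with
#' the integrated four-criterion ranking.
#'
#' @param scores score table from [score_tf_clusters()].
#' @return named list cluster id -> ranking (as [rank_tfs_for_cluster()]).
#' @export
corr_only_rankings <- function(scores) {
  s <- scores
  s$p_prox <- 1; s$p_dbd <- 1; s$p_pc <- 1
  s$r_score <- -log10(s$p_corr)
  lapply(setNames(unique(s$cluster_id), unique(s$cluster_id)),
         function(cid) rank_tfs_for_cluster(s, top_k = 3, cluster_id = cid))
}

#' Rank-1 accuracy of a cluster-regulator assignment
#'
#' Maps each bicluster to its true regulator (the gold-standard TF with the
#' largest overlap between its targets and the bicluster's genes) and
#' reports the fraction of clusters whose rank-1 TF matches. Clusters whose
#' genes overlap no gold TF are skipped.
#'
#' @param rankings named list cluster id -> ranking table.
#' @param biclusters named list of `bicluster` objects.
#' @param gold a `gold_standard`.
#' @return list with `accuracy`, `n_clusters`, and the per-cluster
#'   assignment table.
#' @export
rank1_accuracy <- function(rankings, biclusters, gold) {
  gp <- gold$pairs
  rows <- list()
  for (cid in names(biclusters)) {
    genes <- biclusters[[cid]]$genes
    ov <- vapply(unique(gp$tf), function(tf)
      sum(gp$target[gp$tf == tf] %in% genes), integer(1))
    if (!any(ov > 0)) next
    true_tf <- names(which.max(ov))
    rk <- rankings[[cid]]
    rows[[cid]] <- data.frame(cluster_id = cid, true_tf = true_tf,
                              rank1_tf = rk$tf_id[rk$rank == 1],
                              hit = rk$tf_id[rk$rank == 1] == true_tf,
                              top3 = true_tf %in% rk$tf_id,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  list(accuracy = if (is.null(tab)) NA_real_ else mean(tab$hit),
       top3_rate = if (is.null(tab)) NA_real_ else mean(tab$top3),
       n_clusters = if (is.null(tab)) 0L else nrow(tab),
       table = tab)
}
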