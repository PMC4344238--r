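#' Mean absolute TF-to-cluster expression correlation
#'
#' Averages, over the genes of a bicluster, the absolute Pearson correlation
#' between the TF's expression profile and each member gene, restricted to
#' the bicluster's condition subset. The TF itself is excluded from the gene
#' list if a member. Absolute values are used because repression produces
#' anti-correlation.
#'
#' @param tf_id TF gene id.
#' @param bicluster a `bicluster` (or any list with `genes` and `conditions`).
#' @param matrix expression matrix.
#' @return the mean absolute correlation, or `NA` when the TF is not on the
#'   array (its p-value then defaults to 1).
#' @export
corr_mean <- function(tf_id, bicluster, matrix) {
  if (!(tf_id %in% rownames(matrix))) return(NA_real_)
  genes <- setdiff(bicluster$genes, tf_id)
  genes <- intersect(genes, rownames(matrix))
  if (!length(genes)) return(NA_real_)
  conds <- intersect(bicluster$conditions, colnames(matrix))
  tf <- matrix[tf_id, conds]
  rs <- vapply(genes, function(g)
    suppressWarnings(abs(cor(tf, matrix[g, conds]))), numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Minimum TF-to-cluster genomic distance in genes
#'
#' The minimum, over cluster members on the TF's replicon, of the absolute
#' difference in gene rank (`gene_index`); 0 when the TF is itself a member.
#' Undefined (`NA`) when no member shares a replicon with the TF, in which
#' case the proximity p-value defaults to 1.
#'
#' @param tf_id TF gene id.
#' @param cluster_genes character vector of member gene ids.
#' @param genes gene table with `gene_id`, `replicon_id`, `gene_index`.
#' @return integer distance or `NA`.
#' @export
prox_min <- function(tf_id, cluster_genes, genes) {
  i <- match(tf_id, genes$gene_id)
  if (is.na(i)) return(NA_integer_)
  if (tf_id %in% cluster_genes) return(0L)
  memb <- genes[genes$gene_id %in% cluster_genes &
                genes$replicon_id == genes$replicon_id[i], ]
  if (!nrow(memb)) return(NA_integer_)
  as.integer(min(abs(memb$gene_index - genes$gene_index[i])))
}

#' Cluster-vs-reference-library DBD similarity q-values
#'
#' Compares every cluster PSSM against every reference-library PSSM with
#' [compare_pssms()] and BH-adjusts the p-values over the full comparison
#' set. [dbd_score()] then reads the per-family minimum off this table.
#'
#' @param cluster_pssms named list of cluster PSSMs (names = cluster ids).
#' @param library reference motif library: a list of entries, each a list
#'   with `pssm`, `tf_name`, `dbd_family`.
#' @param n_shuffle shuffles per comparison.
#' @param seed RNG seed.
#' @return data frame with `cluster_id`, `tf_name`, `dbd_family`, `p_value`,
#'   `q_value`.
#' @export
dbd_q_table <- function(cluster_pssms, library, n_shuffle = 1000,
                        seed = NULL) {
  rows <- list()
  k <- 0
  for (cid in names(cluster_pssms)) {
    for (e in library) {
      k <- k + 1
      sd_k <- if (is.null(seed)) NULL else seed + k
      cmp <- compare_pssms(cluster_pssms[[cid]], e$pssm,
                           n_shuffle = n_shuffle, seed = sd_k)
      rows[[k]] <- data.frame(cluster_id = cid, tf_name = e$tf_name,
                              dbd_family = e$dbd_family,
                              p_value = cmp$p_value,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- qvalues(out$p_value)
  out
}

#' DBD similarity score for a TF-cluster pair
#'
#' `-log10` of the smallest q-value among comparisons of the cluster's PSSM
#' to library PSSMs of the TF's DBD family; undefined (`NA`) when the family
#' is absent from the library or unlabelled.
#'
#' @param dbd_family the TF's DBD family label (may be `""`).
#' @param cluster_id cluster id.
#' @param qtab q-value table from [dbd_q_table()].
#' @return numeric score or `NA`.
#' @export
dbd_score <- function(dbd_family, cluster_id, qtab) {
  if (is.null(dbd_family) || is.na(dbd_family) || dbd_family == "")
    return(NA_real_)
  q <- qtab$q_value[qtab$cluster_id == cluster_id &
                    qtab$dbd_family == dbd_family]
  if (!length(q)) return(NA_real_)
  -log10(max(min(q), 1e-300))
}

#' Per-genome motif-occurrence vectors over ortholog groups
#'
#' For each genome, builds a vector indexed by ortholog group holding
#' `-log10` of the best motif-hit p-value in any member IGR of that group
#' (0 when no hit), then correlates each genome's vector with the target
#' genome's vector ("motif occurrence correlations").
#'
#' @param species_hits named list genome -> hit data frame (from
#'   [rebuild_cluster_pssms()]).
#' @param groups ortholog groups.
#' @param genome_ids genomes (vector order defines the result order).
#' @param target_genome target genome id.
#' @return named numeric vector of motif occurrence correlations (one per
#'   genome; the target's self-correlation is 1).
#' @export
motif_occurrence_correlations <- function(species_hits, groups, genome_ids,
                                          target_genome) {
  gids <- names(groups)
  vecs <- sapply(genome_ids, function(g) {
    h <- species_hits[[g]]
    v <- setNames(numeric(length(gids)), gids)
    if (!is.null(h) && nrow(h)) {
      best <- tapply(h$p_value, h$gene_id, min)
      for (gid in gids) {
        memb <- groups[[gid]][[g]]
        if (is.null(memb)) next
        p <- best[names(best) %in% memb]
        if (length(p)) v[gid] <- max(-log10(pmax(min(p), 1e-300)), 0)
      }
    }
    v
  })
  tv <- vecs[, target_genome]
  out <- apply(vecs, 2, function(v) {
    if (sd(v) < 1e-12 || sd(tv) < 1e-12) return(NA_real_)
    cor(v, tv)
  })
  out[target_genome] <- 1
  out
}

#' Phylogenetic correlation between motif and TF occurrence
#'
#' Pearson correlation between the motif occurrence correlations (one per
#' genome) and the TF's presence/absence vector across the same genomes.
#' Undefined (`NA`) when either vector has zero variance (e.g. a TF present
#' in every genome).
#'
#' @param presence_row binary named vector, the TF's presence per genome.
#' @param mocc motif occurrence correlations from
#'   [motif_occurrence_correlations()].
#' @return numeric correlation in `[-1, 1]` or `NA`.
#' @export
phylo_corr <- function(presence_row, mocc) {
  g <- intersect(names(mocc), names(presence_row))
  m <- mocc[g]; pres <- presence_row[g]
  m[is.na(m)] <- 0
  if (sd(m) < 1e-12 || sd(pres) < 1e-12) return(NA_real_)
  cor(m, pres)
}

#' Empirical permutation p-value
#'
#' `p = (# null values at least as extreme) / length(null)`, floored at
#' `1 / (length(null) + 1)` so that p is never exactly 0. An undefined
#' observation (`NA`) yields p = 1 (neutral evidence).
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics.
#' @param direction `"ge"` when large values are extreme (correlation, DBD,
#'   phylogenetic correlation), `"le"` for distances.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed, null, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (is.na(observed)) return(1)
  null <- null[!is.na(null)]
  if (!length(null)) return(1)
  n_ext <- if (direction == "ge") sum(null >= observed - 1e-12)
           else sum(null <= observed + 1e-12)
  min(1, emp_pvalue(n_ext, length(null)))
}

#' Permutation nulls for the four TF-cluster criteria
#'
#' Each null value is the criterion statistic for a randomly drawn
#' TF-cluster pairing: a random TF against a random gene set matching a
#' random cluster's size and condition subset (correlation); a random TF
#' against a random cluster (proximity, phylogenetic correlation); a random
#' library family against a random cluster (DBD). All draws are seeded.
#'
#' @param tf_table TF table (`tf_id`, `dbd_family`).
#' @param biclusters named list of `bicluster` objects.
#' @param matrix expression matrix.
#' @param gene_table gene table for the target genome.
#' @param qtab DBD q-value table (or `NULL` to skip the DBD null).
#' @param mocc_by_cluster named list cluster id -> motif occurrence
#'   correlation vector (or `NULL` to skip the phylogenetic null).
#' @param presence TF presence matrix.
#' @param n null draws per criterion (default 1000).
#' @param seed RNG seed.
#' @return list with numeric vectors `corr`, `prox`, `dbd`, `pc`.
#' @export
build_nulls <- function(tf_table, biclusters, matrix, gene_table,
                        qtab = NULL, mocc_by_cluster = NULL, presence = NULL,
                        n = 1000, seed = NULL) {
  stopifnot(length(biclusters) > 0, nrow(tf_table) > 0)
  cl_ids <- names(biclusters)
  with_seed(seed, {
    corr <- vapply(seq_len(n), function(i) {
      cl <- biclusters[[sample(cl_ids, 1)]]
      tf <- sample(tf_table$tf_id, 1)
      size <- min(length(cl$genes), nrow(matrix) - 1)
      fake <- list(genes = sample(setdiff(rownames(matrix), tf), size),
                   conditions = cl$conditions)
      v <- corr_mean(tf, fake, matrix)
      if (is.na(v)) 0 else v
    }, numeric(1))
    prox <- vapply(seq_len(n), function(i) {
      cl <- biclusters[[sample(cl_ids, 1)]]
      tf <- sample(tf_table$tf_id, 1)
      ## random same-size gene set placed anywhere in the genome
      fake_genes <- sample(gene_table$gene_id, min(length(cl$genes),
                                                   nrow(gene_table)))
      v <- prox_min(tf, fake_genes, gene_table)
      if (is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    dbd <- if (!is.null(qtab) && nrow(qtab)) {
      ## a random library PSSM against a random cluster PSSM
      idx <- sample.int(nrow(qtab), n, replace = TRUE)
      -log10(pmax(qtab$q_value[idx], 1e-300))
    } else numeric(0)
    pc <- if (!is.null(mocc_by_cluster) && length(mocc_by_cluster) &&
              !is.null(presence)) {
      vapply(seq_len(n), function(i) {
        mocc <- mocc_by_cluster[[sample(names(mocc_by_cluster), 1)]]
        tf <- sample(rownames(presence), 1)
        v <- phylo_corr(presence[tf, ], mocc)
        if (is.na(v)) 0 else v
      }, numeric(1))
    } else numeric(0)
    list(corr = corr, prox = prox, dbd = dbd, pc = pc)
  })
}

#' Combined regulator score from four criterion p-values
#'
#' `R = -log10(p_corr * p_prox * p_dbd * p_pc)`; undefined criteria enter
#' with p = 1 and contribute nothing.
#'
#' @param p_corr,p_prox,p_dbd,p_pc p-values in `(0, 1]` (NA treated as 1).
#' @return the combined score (>= 0).
#' @export
r_score <- function(p_corr, p_prox = 1, p_dbd = 1, p_pc = 1) {
  ps <- c(p_corr, p_prox, p_dbd, p_pc)
  ps[is.na(ps)] <- 1
  if (any(ps <= 0 | ps > 1)) stop("p-values must lie in (0, 1]")
  -log10(prod(ps))
}

#' Score all TF-cluster pairs on the four criteria
#'
#' @param tf_table TF table (`tf_id`, `dbd_family`).
#' @param biclusters named list of `bicluster` objects.
#' @param matrix expression matrix.
#' @param gene_table gene table for the target genome.
#' @param qtab DBD q-value table (or `NULL`).
#' @param mocc_by_cluster named list cluster -> motif occurrence correlations
#'   (or `NULL`).
#' @param presence TF presence matrix (or `NULL`).
#' @param nulls permutation nulls from [build_nulls()].
#' @return data frame, one row per TF-cluster pair, with the four criterion
#'   scores, their p-values and `r_score`.
#' @export
score_tf_clusters <- function(tf_table, biclusters, matrix, gene_table,
                              qtab = NULL, mocc_by_cluster = NULL,
                              presence = NULL, nulls) {
  rows <- list()
  for (cid in names(biclusters)) {
    cl <- biclusters[[cid]]
    mocc <- mocc_by_cluster[[cid]]
    for (i in seq_len(nrow(tf_table))) {
      tf <- tf_table$tf_id[i]
      cm <- corr_mean(tf, cl, matrix)
      pm <- prox_min(tf, cl$genes, gene_table)
      db <- if (is.null(qtab)) NA_real_
            else dbd_score(tf_table$dbd_family[i], cid, qtab)
      pc <- if (is.null(mocc) || is.null(presence) ||
                !(tf %in% rownames(presence))) NA_real_
            else phylo_corr(presence[tf, ], mocc)
      p_corr <- permutation_pvalue(cm, nulls$corr, "ge")
      p_prox <- permutation_pvalue(
        if (is.na(pm)) NA_real_ else as.numeric(pm), nulls$prox, "le")
      p_dbd <- if (length(nulls$dbd)) permutation_pvalue(db, nulls$dbd, "ge") else 1
      p_pc <- if (length(nulls$pc)) permutation_pvalue(pc, nulls$pc, "ge") else 1
      rows[[length(rows) + 1]] <- data.frame(
        tf_id = tf, cluster_id = cid,
        corr_mean = cm, p_corr = p_corr,
        prox_min = ifelse(is.na(pm), NA_integer_, pm), p_prox = p_prox,
        dbd_score = db, p_dbd = p_dbd,
        phylo_corr = pc, p_pc = p_pc,
        r_score = r_score(p_corr, p_prox, p_dbd, p_pc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank candidate regulators for a cluster
#'
#' Orders TFs by descending `r_score`; ties broken by smaller `p_dbd`, then
#' smaller `p_corr`, then `tf_id`. The rank-1 TF is flagged as the cluster's
#' network regulator.
#'
#' @param scores score table from [score_tf_clusters()] (one cluster's rows,
#'   or pass `cluster_id` to filter).
#' @param top_k how many candidates to return (default 3).
#' @param cluster_id optional cluster filter.
#' @return the top rows, with `rank` and `network_tf` columns added.
#' @export
rank_tfs_for_cluster <- function(scores, top_k = 3, cluster_id = NULL) {
  if (!is.null(cluster_id))
    scores <- scores[scores$cluster_id == cluster_id, , drop = FALSE]
  stopifnot(nrow(scores) > 0)
  o <- order(-scores$r_score, scores$p_dbd, scores$p_corr, scores$tf_id)
  out <- scores[o, , drop = FALSE][seq_len(min(top_k, nrow(scores))), ,
                                   drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$network_tf <- out$rank == 1
  rownames(out) <- NULL
  out
}
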