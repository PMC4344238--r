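## per-column Pearson correlation between two frequency matrices
## (4 x wa) vs (4 x wb); zero-variance columns contribute 0
column_cor_matrix <- function(fa, fb) {
  ca <- sweep(fa, 2, colMeans(fa), "-")
  cb <- sweep(fb, 2, colMeans(fb), "-")
  sa <- sqrt(colSums(ca^2)); sb <- sqrt(colSums(cb^2))
  C <- crossprod(ca, cb)
  den <- outer(sa, sb)
  out <- ifelse(den > 1e-12, C / den, 0)
  matrix(out, nrow = ncol(fa))
}

#' Compare two PSSMs by best ungapped overlap
#'
#' The similarity statistic is the mean per-column Pearson correlation of
#' frequency columns over the best ungapped alignment with at least
#' `min_overlap_cols` overlapping columns, maximised over offsets and both
#' orientations of `b`. Significance is assessed against `n_shuffle`
#' column-shuffled versions of `b` (the same statistic, maximised the same
#' way), giving an empirical p-value.
#'
#' @param a,b `pssm` objects (widths >= 4).
#' @param n_shuffle number of column shuffles for the null (default 1000).
#' @param min_overlap_cols minimum overlap width (default 6; very short
#'   overlaps of near-one-hot columns make the shuffle null degenerate).
#' @param seed optional RNG seed for the shuffle null.
#' @return list with `offset` (alignment of b relative to a), `orientation`
#'   (`"+"` or `"-"`), `stat` and `p_value`.
#' @export
compare_pssms <- function(a, b, n_shuffle = 1000, min_overlap_cols = 6,
                          seed = NULL) {
  stopifnot(a$width >= 4, b$width >= 4)
  fb_r <- pssm_revcomp(b)$freq
  Cf <- column_cor_matrix(a$freq, b$freq)
  Cr <- column_cor_matrix(a$freq, fb_r)
  of <- cpp_best_overlap(Cf, min_overlap_cols)
  orv <- cpp_best_overlap(Cr, min_overlap_cols)
  if (!is.na(of$stat) && (is.na(orv$stat) || of$stat >= orv$stat)) {
    obs <- of$stat; off <- of$offset; orient <- "+"
  } else {
    obs <- orv$stat; off <- orv$offset; orient <- "-"
  }
  null <- with_seed(seed, {
    perms <- t(replicate(n_shuffle, sample.int(b$width)))
    cpp_pair_null(Cf, Cr, perms, min_overlap_cols)
  })
  p <- emp_pvalue(sum(null >= obs - 1e-12), n_shuffle)
  list(offset = off, orientation = orient, stat = obs, p_value = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values (monotone in p-rank).
#' @export
qvalues <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

## site identity for clustering: a hit is a (gene, site-center) pair; the
## strand is ignored because the same physical site is found on either
## strand depending on motif orientation, and registers jitter across motif
## variants of different widths
hit_sites <- function(hits) {
  if (!nrow(hits))
    return(data.frame(gene_id = character(0), center = numeric(0)))
  w <- if ("width" %in% names(hits)) hits$width else 0
  data.frame(gene_id = hits$gene_id, center = hits$offset + (w - 1) / 2)
}

## overlap coefficient |A & B| / min(|A|, |B|) where two sites match when
## they share the gene and their centers lie within tol bp; a single shared
## site is never counted as overlap (chance co-hits chain unrelated motifs)
hit_overlap <- function(a, b, tol = 5) {
  if (!nrow(a) || !nrow(b)) return(0)
  match_count <- function(x, y) {
    sum(vapply(seq_len(nrow(x)), function(i)
      any(y$gene_id == x$gene_id[i] & abs(y$center - x$center[i]) <= tol),
      logical(1)))
  }
  m <- max(match_count(a, b), match_count(b, a))
  if (m < 2) return(0)
  m / min(nrow(a), nrow(b))
}

## dedupe near-identical hits within a set (same gene, centers within tol)
dedupe_hits <- function(hits, tol = 5) {
  if (!nrow(hits)) return(hits)
  s <- hit_sites(hits)
  o <- order(hits$p_value)
  keep <- logical(nrow(hits))
  taken <- s[0, ]
  for (i in o) {
    if (nrow(taken) &&
        any(taken$gene_id == s$gene_id[i] &
            abs(taken$center - s$center[i]) <= tol)) next
    keep[i] <- TRUE
    taken <- rbind(taken, s[i, ])
  }
  hits[keep, , drop = FALSE]
}

#' Cluster redundant motifs by hit overlap and PSSM similarity
#'
#' Builds a graph over motifs in which an edge joins two motifs when (i)
#' their target-genome hit sets overlap by at least `min_overlap` (overlap
#' coefficient `|A & B| / min(|A|, |B|)` on strand-agnostic site centers
#' matched within `bin` bp) and
#' (ii) the PSSM-comparison q-value is below `q_max`. Single-linkage
#' connected components form the motif family clusters; motifs without an
#' edge become singletons. Unless `pair_q` is supplied, q-values are
#' computed by BH adjustment of [compare_pssms()] p-values over the set of
#' candidate pairs passing the overlap screen.
#'
#' @param motifs list of `pssm` objects.
#' @param hits data frame of target-genome hits for all motifs (from
#'   [scan_for_hits()], rows for these motifs).
#' @param pair_q optional precomputed named vector of q-values with names
#'   `"id1||id2"` (sorted ids).
#' @param q_max q-value threshold (default 0.01).
#' @param min_overlap hit-overlap threshold (default 0.33).
#' @param bin hit offset bin width in bp.
#' @param n_shuffle shuffles per PSSM comparison.
#' @param seed RNG seed for comparisons.
#' @return list of clusters; each has `cluster_id`, `members` (motif ids),
#'   and `hits` (the union hit set, a data frame).
#' @export
cluster_motifs <- function(motifs, hits, pair_q = NULL, q_max = 0.01,
                           min_overlap = 0.33, bin = 5, n_shuffle = 1000,
                           seed = NULL) {
  ids <- vapply(motifs, function(m) m$motif_id, character(1))
  names(motifs) <- ids
  hit_sets <- lapply(ids, function(id)
    hit_sites(dedupe_hits(hits[hits$motif_id == id, , drop = FALSE], bin)))
  names(hit_sets) <- ids
  n <- length(ids)
  ## candidate pairs by overlap coefficient
  cand <- list()
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ov <- hit_overlap(hit_sets[[i]], hit_sets[[j]], tol = bin)
      if (ov >= min_overlap)
        cand[[length(cand) + 1]] <- list(i = i, j = j, overlap = ov)
    }
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (length(cand)) {
    key <- vapply(cand, function(p)
      paste(sort(c(ids[p$i], ids[p$j])), collapse = "||"), character(1))
    if (is.null(pair_q)) {
      ps <- vapply(seq_along(cand), function(k) {
        p <- cand[[k]]
        sd_k <- if (is.null(seed)) NULL else seed + k
        compare_pssms(motifs[[p$i]], motifs[[p$j]], n_shuffle = n_shuffle,
                      seed = sd_k)$p_value
      }, numeric(1))
      qv <- setNames(qvalues(ps), key)
    } else qv <- pair_q
    for (k in seq_along(cand)) {
      q <- qv[[key[k]]]
      if (!is.null(q) && !is.na(q) && q < q_max) {
        ri <- find(cand[[k]]$i); rj <- find(cand[[k]]$j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  ## deterministic order: by smallest member id
  comp <- comp[order(vapply(comp, function(m) min(ids[m]), character(1)))]
  lapply(seq_along(comp), function(ci) {
    members <- ids[comp[[ci]]]
    h <- hits[hits$motif_id %in% members, , drop = FALSE]
    ## union hit set, deduplicated on site identity (best p kept)
    h <- dedupe_hits(h, bin)
    list(cluster_id = sprintf("mc%03d", ci), members = members, hits = h)
  })
}

#' Rebuild per-genome PSSMs for a motif family cluster
#'
#' Scans the cluster's representative motif (the member with most target
#' hits) against each genome's IGRs and rebuilds a species-specific PSSM
#' from the hit site sequences.
#'
#' @param cluster a cluster from [cluster_motifs()].
#' @param motifs named list of `pssm` objects (members available by id).
#' @param contexts named list of [igr_scan_context()] objects, one per genome.
#' @param bg a `dna_background`.
#' @param p_max scan p-value threshold.
#' @param pseudocount pseudocount for rebuilt PSSMs.
#' @return list with `representative` (motif id), `species_pssms` (named
#'   list genome -> `pssm`, missing when a genome had no hits) and
#'   `species_hits` (named list genome -> hit data frame).
#' @export
rebuild_cluster_pssms <- function(cluster, motifs, contexts, bg,
                                  p_max = 1e-4, pseudocount = 0.25) {
  counts <- table(cluster$hits$motif_id)
  rep_id <- if (length(counts)) names(which.max(counts)) else cluster$members[1]
  rep_pssm <- motifs[[rep_id]]
  species_pssms <- list()
  species_hits <- list()
  for (g in names(contexts)) {
    ctx <- contexts[[g]]
    h <- scan_for_hits(rep_pssm, NULL, bg, p_max = p_max, context = ctx)
    species_hits[[g]] <- h
    if (!nrow(h)) next
    seqs <- setNames(ctx$igrs$gene_id, ctx$igrs$gene_id)
    words <- vapply(seq_len(nrow(h)), function(r) {
      i <- match(h$gene_id[r], ctx$igrs$gene_id)
      v <- if (h$strand[r] == "+") ctx$fwd[[i]] else ctx$rev[[i]]
      off <- if (h$strand[r] == "+") h$offset[r]
             else length(ctx$fwd[[i]]) - rep_pssm$width + 2L - h$offset[r]
      int_to_dna(v[off:(off + rep_pssm$width - 1)])
    }, character(1))
    species_pssms[[g]] <- build_pssm(
      words, pseudocount = pseudocount,
      motif_id = paste0(cluster$cluster_id, "_", g), source = "rebuilt")
  }
  list(representative = rep_id, species_pssms = species_pssms,
       species_hits = species_hits)
}
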