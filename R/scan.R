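#' Precompute an integer-encoded scanning context for a set of IGRs
#'
#' Scanning many motifs against the same intergenic regions repeatedly
#' re-encodes sequences; this helper does the encoding once.
#'
#' @param igrs IGR table from [extract_upstream_igrs()].
#' @return an object of class `igr_scan_context`.
#' @export
igr_scan_context <- function(igrs) {
  fwd <- lapply(igrs$sequence, dna_to_int)
  rev <- lapply(fwd, revcomp_int)
  structure(list(igrs = igrs[, c("gene_id", "genome_id", "length")],
                 fwd = fwd, rev = rev),
            class = "igr_scan_context")
}

#' Scan intergenic regions for motif occurrences
#'
#' Scores every window of every IGR (both strands) with the motif's log-odds
#' against the order-0 stationary background and keeps the best hit per IGR
#' per strand whose exact-word-null p-value is at most `p_max`. Windows
#' containing `N` are skipped. The p-value is computed from the exact score
#' distribution of a random width-w word under the order-0 background
#' ([pssm_score_dist()]).
#'
#' @param pssm a `pssm`.
#' @param igrs IGR table (or `NULL` when `context` is supplied).
#' @param bg a `dna_background`.
#' @param p_max p-value threshold for retained hits.
#' @param context optional precomputed [igr_scan_context()].
#' @return data frame of hits: `motif_id`, `genome_id`, `gene_id`, `offset`
#'   (1-based window start on the IGR's given orientation), `strand`,
#'   `score`, `p_value`.
#' @export
scan_for_hits <- function(pssm, igrs, bg, p_max = 1e-4, context = NULL) {
  if (is.null(context)) context <- igr_scan_context(igrs)
  lodds <- pssm_logodds(pssm, bg)
  dist <- pssm_score_dist(pssm, bg)
  w <- pssm$width
  res <- list()
  for (i in seq_along(context$fwd)) {
    v <- context$fwd[[i]]
    if (length(v) < w) next
    for (str in c("+", "-")) {
      sc <- cpp_scan_scores(if (str == "+") v else context$rev[[i]], lodds)
      if (all(is.na(sc))) next
      best <- which.max(sc)
      p <- pssm_score_pvalue(sc[best], dist)
      if (p > p_max) next
      off <- if (str == "+") best else length(v) - w + 2L - best
      res[[length(res) + 1]] <- data.frame(
        motif_id = pssm$motif_id,
        genome_id = context$igrs$genome_id[i],
        gene_id = context$igrs$gene_id[i],
        offset = off, strand = str, width = w, score = sc[best],
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(motif_id = character(0), genome_id = character(0),
                      gene_id = character(0), offset = integer(0),
                      strand = character(0), width = integer(0),
                      score = numeric(0), p_value = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
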