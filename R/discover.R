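#' De novo ZOOPS motif discovery in a group of sequences
#'
#' A zero-or-one-occurrence-per-sequence (ZOOPS) motif finder for groups of
#' upstream intergenic sequences of orthologous genes. Candidate motifs are
#' seeded from the most widely shared k-mers (mismatch-tolerant, both
#' strands), refined by a few rounds of best-site alignment against the
#' background, and trimmed to their informative core. Significance is
#' assessed with a leave-one-out per-sequence hit test: each contributing
#' sequence is re-scanned with the motif rebuilt without its own site and
#' its best-hit score is converted to a Gumbel tail probability against best
#' hits on sequences drawn from the (order-3) background model. The group
#' statistic (the sum of the three largest per-sequence log evidences) is
#' then standardized against the same statistic produced by running the
#' whole search on background-model groups ([discovery_calibration()]), so
#' both repeat-like background structure and the optimism of the site search
#' itself are absorbed into the null. Sites of an accepted motif are masked
#' before searching for the next one.
#'
#' @param seq_group named character vector of DNA sequences (>= 4).
#' @param bg a `dna_background`.
#' @param nmotifs maximum number of motifs to return (default 3).
#' @param max_width maximum motif width (default 30).
#' @param evalue_max significance threshold; motifs above it are not emitted
#'   (default 0.01).
#' @param widths candidate seed widths (trimming can shorten them).
#' @param n_seeds seeds evaluated per width.
#' @param em_iter site-realignment iterations per seed.
#' @param pseudocount pseudocount for site tallies.
#' @param null_pool optional list of integer-encoded background sequences
#'   (shared across groups for speed); generated from `bg` when missing.
#' @param n_null background sequences in the per-sequence null when
#'   `null_pool` is missing.
#' @param calibration optional [discovery_calibration()] shared across
#'   groups; computed for this group's geometry when missing.
#' @return list of `pssm` objects (possibly empty), each carrying a `sites`
#'   data frame (`seq_index`, `strand`, `offset`, `site`) and an `evalue` as
#'   attributes.
#' @export
discover_motifs_zoops <- function(seq_group, bg, nmotifs = 3, max_width = 30,
                                  evalue_max = 0.01,
                                  widths = c(8, 12), n_seeds = 6,
                                  em_iter = 5, pseudocount = 0.25,
                                  null_pool = NULL, n_null = 200,
                                  calibration = NULL) {
  widths <- widths[widths <= max_width]
  if (is.null(names(seq_group)))
    names(seq_group) <- paste0("seq", seq_along(seq_group))
  work <- lapply(seq_group, dna_to_int)
  widths <- widths[widths <= min(vapply(work, length, integer(1)))]
  if (!length(widths)) return(list())
  if (is.null(null_pool))
    null_pool <- build_null_pool(bg, max(vapply(work, length, integer(1))),
                                 n_null)
  if (is.null(calibration))
    calibration <- discovery_calibration(
      bg, lengths = vapply(work, length, integer(1)),
      n_seqs = length(work), widths = widths, n_seeds = n_seeds,
      em_iter = em_iter, pseudocount = pseudocount, null_pool = null_pool)
  out <- list()
  for (round_i in seq_len(nmotifs)) {
    best <- NULL
    for (w in widths) {
      cand_best <- best_candidate(work, w, bg, n_seeds, em_iter, pseudocount,
                                  null_pool)
      if (is.null(cand_best)) next
      wkey <- as.character(w)
      mu <- calibration$mu[[wkey]] %||% calibration$mu_all
      sdv <- calibration$sd[[wkey]] %||% calibration$sd_all
      frac <- calibration$frac[[wkey]] %||% calibration$frac_all
      z <- (cand_best$t3 - mu) / max(sdv, 1e-6)
      cand_best$evalue <- length(widths) * frac *
        stats::pnorm(z, lower.tail = FALSE)
      if (is.null(best) || cand_best$evalue < best$evalue ||
          (cand_best$evalue == best$evalue && cand_best$t3 > best$t3))
        best <- cand_best
    }
    if (is.null(best) || best$evalue > evalue_max) break
    pssm <- build_pssm(best$sites$site, pseudocount = pseudocount,
                       motif_id = sprintf("m%d", round_i), source = "denovo")
    attr(pssm, "sites") <- best$sites
    attr(pssm, "evalue") <- best$evalue
    out[[length(out) + 1]] <- pssm
    work <- mask_sites(work, best$sites)
  }
  out
}

## best seed-refined candidate at one width, with its group evidence
best_candidate <- function(work, w, bg, n_seeds, em_iter, pseudocount,
                           null_pool) {
  seeds <- top_seed_kmers(work, w, n_seeds)
  cand <- NULL
  for (sk in seeds) {
    fit <- zoops_refine(work, sk, bg, em_iter, pseudocount)
    if (!is.null(fit) && (is.null(cand) || fit$llr > cand$llr)) cand <- fit
  }
  if (is.null(cand)) return(NULL)
  cand <- trim_motif(cand, bg, min_width = 8)
  if (is.null(cand)) return(NULL)
  sig <- motif_significance(cand, work, bg, pseudocount, null_pool)
  cand$t3 <- sig$t3
  cand$support <- sig$support
  cand
}

#' Calibrate motif-discovery significance on background groups
#'
#' Runs the same seed/refine/score search on groups of background-model
#' sequences matched to the input geometry, and records the group evidence
#' statistic per candidate width. Discovery converts observed statistics to
#' E-values against this empirical null, which absorbs the optimism of the
#' site search itself.
#'
#' @param bg a `dna_background`.
#' @param lengths pool of sequence lengths to resample calibration groups
#'   from.
#' @param n_seqs sequences per calibration group (a vector is resampled).
#' @param widths candidate widths (must match the discovery call).
#' @param n_cal number of background groups (default 80).
#' @param n_seeds,em_iter,pseudocount as in [discover_motifs_zoops()].
#' @param null_pool shared background pool (generated when missing).
#' @return an object of class `discovery_calibration` with per-width means
#'   and standard deviations of the null statistic.
#' @export
discovery_calibration <- function(bg, lengths, n_seqs, widths = c(8, 12),
                                  n_cal = 80, n_seeds = 6, em_iter = 5,
                                  pseudocount = 0.25, null_pool = NULL) {
  if (is.null(null_pool)) null_pool <- build_null_pool(bg, max(lengths), 200)
  t3s <- setNames(lapply(widths, function(w) numeric(0)),
                  as.character(widths))
  for (b in seq_len(n_cal)) {
    n <- if (length(n_seqs) > 1) sample(n_seqs, 1) else n_seqs
    L <- sample(lengths, n, replace = TRUE)
    grp <- lapply(sample_background(bg, L), dna_to_int)
    for (w in widths) {
      if (w > min(L)) next
      cand <- best_candidate(grp, w, bg, n_seeds, em_iter, pseudocount,
                             null_pool)
      wkey <- as.character(w)
      t3s[[wkey]] <- c(t3s[[wkey]], if (is.null(cand)) 0 else cand$t3)
    }
  }
  ## a null group may yield no candidate at a width; the null is modelled as
  ## a point mass at "no candidate" times a normal over realized statistics
  ## robust one-sided location/scale of the realized null statistics: the
  ## null is left-skewed and only its right tail matters, so the scale comes
  ## from the median-to-upper-quartile distance
  scale_up <- function(v) max((unname(quantile(v, 0.75)) -
                                 stats::median(v)) / 0.6745, 0.5)
  summarize <- function(v, f) {
    pos <- v[v > 0]
    if (length(pos) >= 10) f(pos) else NULL
  }
  all_pos <- unlist(t3s); all_pos <- all_pos[all_pos > 0]
  structure(list(
    mu = lapply(t3s, summarize, f = stats::median),
    sd = lapply(t3s, summarize, f = scale_up),
    frac = lapply(t3s, function(v)
      if (length(v) >= 10) mean(v > 0) else NULL),
    mu_all = stats::median(all_pos),
    sd_all = scale_up(all_pos),
    frac_all = mean(unlist(t3s) > 0),
    n_cal = n_cal, widths = widths),
    class = "discovery_calibration")
}

## most widely shared k-mers, counting occurrences up to floor(w/5)
## mismatches on either strand; candidates are the windows of the sequences
## (subsampled for long inputs)
top_seed_kmers <- function(work, w, n_seeds, max_cand = 400) {
  cand <- list()
  for (v in work) {
    n <- length(v) - w + 1
    if (n < 1) next
    for (i in seq_len(n)) {
      win <- v[i:(i + w - 1)]
      if (all(win >= 0L)) cand[[length(cand) + 1]] <- win
    }
  }
  if (!length(cand)) return(character(0))
  cm <- do.call(rbind, cand)
  cm <- unique(cm)
  if (nrow(cm) > max_cand)
    cm <- cm[seq(1, nrow(cm), length.out = max_cand), , drop = FALSE]
  supp <- cpp_seed_support(cm, work, max_mismatch = w %/% 5)
  o <- order(-supp[, 1], -supp[, 2])
  keep <- o[supp[o, 1] >= min(2, length(work))]
  keep <- head(keep, n_seeds)
  vapply(keep, function(i) int_to_dna(cm[i, ]), character(1))
}

## iterative best-site (ZOOPS) refinement from a single k-mer seed
zoops_refine <- function(work, seed, bg, em_iter, pseudocount) {
  w <- nchar(seed)
  iv <- dna_to_int(seed) + 1L
  freq <- matrix(0.1 / 3, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  freq[cbind(iv, seq_len(w))] <- 0.9
  sites <- NULL
  for (it in seq_len(em_iter)) {
    lodds <- log2(freq / bg$stationary)
    sites <- best_sites(work, lodds)
    if (is.null(sites) || nrow(sites) < 3) return(NULL)
    counts <- site_counts(sites$site)
    freq <- sweep(counts + pseudocount, 2,
                  nrow(sites) + 4 * pseudocount, "/")
  }
  llr <- sum(sites$score)
  list(freq = freq, sites = sites, llr = llr, width = w)
}

## best window per sequence over both strands; kept when the log-odds beats
## the ZOOPS prior odds of one site among 2L windows (so sequences without a
## convincing site stay out and do not dilute the PSSM)
best_sites <- function(work, lodds) {
  w <- ncol(lodds)
  rows <- lapply(seq_along(work), function(i) {
    v <- work[[i]]
    if (length(v) < w) return(NULL)
    sf <- cpp_scan_scores(v, lodds)
    sr <- cpp_scan_scores(revcomp_int(v), lodds)
    bf <- if (all(is.na(sf))) -Inf else max(sf, na.rm = TRUE)
    br <- if (all(is.na(sr))) -Inf else max(sr, na.rm = TRUE)
    if (max(bf, br) <= log2(2 * (length(v) - w + 1))) return(NULL)
    if (bf >= br) {
      off <- which.max(sf)
      site <- int_to_dna(v[off:(off + w - 1)])
      data.frame(seq_index = i, strand = "+", offset = off, site = site,
                 score = bf, stringsAsFactors = FALSE)
    } else {
      offr <- which.max(sr)
      off <- length(v) - w + 2 - offr  # position on the forward strand
      site <- int_to_dna(revcomp_int(v)[offr:(offr + w - 1)])
      data.frame(seq_index = i, strand = "-", offset = off, site = site,
                 score = br, stringsAsFactors = FALSE)
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

site_counts <- function(sites) {
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- vapply(seq_len(ncol(mat)), function(j)
    tabulate(match(mat[, j], DNA_BASES), nbins = 4), numeric(4))
  matrix(counts, nrow = 4, dimnames = list(DNA_BASES, NULL))
}

## drop uninformative flanking columns; the information threshold rises for
## small site counts, whose random columns carry substantial sampling IC
## (~ 3 / (2 ln 2 n) bits)
trim_motif <- function(fit, bg, min_info = NULL, min_width = 4) {
  if (is.null(min_info)) min_info <- 0.5 + 2 / max(1, nrow(fit$sites))
  info <- colSums(fit$freq * log2(fit$freq / bg$stationary))
  ## flanking columns co-selected by the site search can carry moderate IC;
  ## raise the cut relative to the strong (clearly informative) columns
  strong <- info[info >= min_info]
  if (length(strong) >= min_width)
    min_info <- max(min_info, 0.55 * stats::median(strong))
  keep <- which(info >= min_info)
  if (!length(keep)) return(NULL)
  lt <- min(keep); rt <- max(keep)
  if (rt - lt + 1 < min_width) {
    lt <- max(1, min(lt, ncol(fit$freq) - min_width + 1))
    rt <- min(ncol(fit$freq), lt + min_width - 1)
  }
  if (lt == 1 && rt == ncol(fit$freq)) return(fit)
  w_old <- ncol(fit$freq)
  sites <- fit$sites
  sites$site <- substr(sites$site, lt, rt)
  sites$offset <- ifelse(sites$strand == "+", sites$offset + lt - 1L,
                         sites$offset + (w_old - rt))
  fit$freq <- fit$freq[, lt:rt, drop = FALSE]
  fit$sites <- sites
  fit$width <- rt - lt + 1
  fit
}

## shared pool of background sequences for discovery nulls; prefixes of a
## Markov-chain sample are themselves valid samples, so one long pool serves
## all sequence lengths
build_null_pool <- function(bg, max_len, n_null = 60) {
  lapply(sample_background(bg, rep(max_len, n_null)), dna_to_int)
}

## leave-one-out evidence: each sequence's best hit (scored with the motif
## rebuilt without that sequence's site) becomes a Gumbel tail probability
## against best hits on background-model sequences of the same length; the
## group statistic t3 sums the three largest -log evidences
motif_significance <- function(fit, work, bg, pseudocount, null_pool,
                               alpha = 0.01) {
  w <- ncol(fit$freq)
  n <- length(work)
  counts <- site_counts(fit$sites$site)
  n_sites <- nrow(fit$sites)
  freq_full <- sweep(counts + pseudocount, 2, n_sites + 4 * pseudocount, "/")
  qs <- rep(NA_real_, n)
  M <- length(null_pool)
  for (i in seq_len(n)) {
    v <- work[[i]]
    if (length(v) < w) next
    si <- fit$sites[fit$sites$seq_index == i, ]
    if (nrow(si) == 1 && n_sites > 3) {
      c_loo <- counts - site_counts(si$site)
      f_loo <- sweep(c_loo + pseudocount, 2,
                     (n_sites - 1) + 4 * pseudocount, "/")
      lodds <- log2(f_loo / bg$stationary)
    } else {
      lodds <- log2(freq_full / bg$stationary)
    }
    sf <- cpp_scan_scores(v, lodds)
    sr <- cpp_scan_scores(revcomp_int(v), lodds)
    sc <- suppressWarnings(max(c(sf, sr), na.rm = TRUE))
    if (!is.finite(sc)) next
    L <- length(v)
    null_best <- vapply(null_pool, function(nv) {
      nv <- nv[seq_len(min(L, length(nv)))]
      s1 <- cpp_scan_scores(nv, lodds)
      s2 <- cpp_scan_scores(revcomp_int(nv), lodds)
      suppressWarnings(max(c(s1, s2), na.rm = TRUE))
    }, numeric(1))
    null_best <- null_best[is.finite(null_best)]
    if (length(null_best) < 10) next
    ## best-of-L scores are Gumbel; a moment fit extends the empirical null
    ## tail below 1/M
    beta <- sd(null_best) * sqrt(6) / pi
    mu <- mean(null_best) - 0.57722 * beta
    qs[i] <- 1 - exp(-exp(-(sc - mu) / max(beta, 1e-6)))
  }
  k <- sum(qs <= alpha, na.rm = TRUE)
  ev <- -log(pmax(qs[!is.na(qs)], 1e-300))
  t3 <- sum(sort(ev, decreasing = TRUE)[seq_len(min(3, length(ev)))])
  list(t3 = if (length(ev)) t3 else 0, support = k, qs = qs)
}

mask_sites <- function(work, sites) {
  w <- nchar(sites$site[1])
  for (r in seq_len(nrow(sites))) {
    i <- sites$seq_index[r]
    off <- sites$offset[r]
    work[[i]][off:(off + w - 1)] <- -1L
  }
  work
}
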