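#' Define a synthetic TRN benchmark scenario
#'
#' Bundles all parameters of the synthetic data generator. Presets:
#' `"default"` (the study conditions: 8 genomes, 300 ortholog groups, 12
#' TFs, 120 conditions, motif mutation rate 0.05/base/genome, expression
#' noise sd 0.4, a third of TFs post-transcriptionally regulated),
#' `"easy"` (mutation 0.02, noise 0.2, all TFs transcriptional),
#' `"hard"` (mutation 0.08, noise 0.6, ortholog loss 0.2, half the TFs
#' post-transcriptional) and `"post_transcriptional"` (as easy but every TF
#' post-transcriptionally regulated, so expression correlation carries no
#' information about the regulator).
#'
#' @param preset scenario preset name.
#' @param ... named overrides of individual fields.
#' @return an object of class `trn_scenario`.
#' @export
trn_scenario <- function(preset = c("default", "easy", "hard",
                                    "post_transcriptional"), ...) {
  preset <- match.arg(preset)
  s <- list(
    preset = preset,
    n_genomes = 8,
    n_ortholog_groups = 300,
    n_tfs = 12,
    regulon_size = c(5, 15),
    motif_width = c(10, 18),
    igr_length = c(60, 300),
    mutation_rate = 0.05,
    loss_prob = 0.1,
    n_conditions = 120,
    noise_sd = 0.4,
    frac_post_transcriptional = 0.33,
    active_condition_frac = 0.4,
    minus_strand_frac = 0.3,
    tf_adjacent_prob = 0.5,
    operon_gap = c(5, 30),
    operon_noise_sd = 0.1,
    gene_length = c(300, 900),
    seed = 1L)
  tweaks <- switch(preset,
    default = list(),
    easy = list(mutation_rate = 0.02, noise_sd = 0.2,
                frac_post_transcriptional = 0),
    hard = list(mutation_rate = 0.08, noise_sd = 0.6, loss_prob = 0.2,
                frac_post_transcriptional = 0.5),
    post_transcriptional = list(mutation_rate = 0.02, noise_sd = 0.2,
                                frac_post_transcriptional = 1))
  s[names(tweaks)] <- tweaks
  dots <- list(...)
  unknown <- setdiff(names(dots), names(s))
  if (length(unknown)) stop("unknown scenario fields: ",
                            paste(unknown, collapse = ", "))
  s[names(dots)] <- dots
  probs <- c(s$mutation_rate, s$loss_prob, s$frac_post_transcriptional,
             s$active_condition_frac, s$minus_strand_frac, s$tf_adjacent_prob)
  stopifnot(all(probs >= 0 & probs <= 1), s$n_genomes >= 4)
  structure(s, class = "trn_scenario")
}

#' @export
print.trn_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic TRN scenario '%s': %d genomes, %d ortholog groups, %d TFs, %d conditions (seed %d)\n",
    x$preset, x$n_genomes, x$n_ortholog_groups, x$n_tfs, x$n_conditions,
    x$seed))
  invisible(x)
}

## random order-3 background chain with mild composition skew
random_background_chain <- function(order = 3) {
  stationary <- setNames(c(0.22, 0.28, 0.28, 0.22), DNA_BASES)
  ncontext <- 4^order
  trans <- matrix(0, ncontext, 4, dimnames = list(context_labels(order),
                                                  DNA_BASES))
  for (i in seq_len(ncontext)) {
    g <- stats::rgamma(4, shape = 20 * stationary)
    trans[i, ] <- g / sum(g)
  }
  structure(list(order = order, trans = trans, stationary = stationary),
            class = "dna_background")
}

chain_sample <- function(bg, L) sample_background(bg, L)

## strong planted PSSM around a random consensus
random_planted_pssm <- function(width, motif_id) {
  cons <- sample.int(4, width, replace = TRUE)
  freq <- matrix(0.1 / 3, 4, width, dimnames = list(DNA_BASES, NULL))
  freq[cbind(cons, seq_len(width))] <- 0.9
  pssm_from_freq(freq, motif_id = motif_id, n_sites = 40, source = "reference")
}

## sample one site from a PSSM, then point-mutate at the per-base rate
sample_site <- function(pssm, mutation_rate = 0) {
  v <- vapply(seq_len(pssm$width), function(j)
    sample.int(4, 1, prob = pssm$freq[, j]), integer(1))
  mut <- runif(pssm$width) < mutation_rate
  if (any(mut))
    v[mut] <- vapply(v[mut], function(b)
      sample(setdiff(1:4, b), 1), integer(1))
  paste(DNA_BASES[v], collapse = "")
}

#' Simulate related genomes with planted regulatory motifs
#'
#' Generates, for each genome in the scenario, a single-replicon genome in
#' which every ortholog group contributes one gene: gene order is shared up
#' to small local shuffles, upstream intergenic gaps are drawn from an
#' order-3 Markov background, and a motif instance (sampled from the TF's
#' planted PSSM, then point-mutated at the per-genome rate) is embedded in
#' the upstream gap of every regulon member in genomes where the TF's
#' ortholog is present. Some regulon members head operons (extra co-strand
#' genes downstream at small gaps, target genome only). TF genes are placed
#' adjacent to one of their regulon members with the scenario probability.
#'
#' Assumes the RNG is already seeded (see [simulate_trn_data()]).
#'
#' @param scenario a `trn_scenario`.
#' @return list with `genomes` (named list genome -> named replicon vector),
#'   `annotations` (gene table over all genomes), `groups` (ortholog
#'   groups), `truth` (planted ground truth), `bg_chain` (the generating
#'   background).
#' @export
simulate_genomes <- function(scenario) {
  s <- scenario
  genome_ids <- sprintf("org%02d", seq_len(s$n_genomes))
  target <- genome_ids[1]
  group_ids <- sprintf("og%03d", seq_len(s$n_ortholog_groups))
  bg_chain <- random_background_chain(3)

  ## TFs, families, regulons
  tf_groups <- sample(group_ids, s$n_tfs)
  fam_pool <- c("Crp", "LacI", "GntR", "TetR", "LysR", "ArsR", "MarR",
                "IclR", "AraC", "DeoR", "Fur", "MerR", "RpiR", "BadM",
                "NtrC", "OmpR")
  families <- setNames(fam_pool[seq_len(s$n_tfs)], tf_groups)
  pool <- setdiff(group_ids, tf_groups)
  regulons <- list()
  for (tg in tf_groups) {
    size <- sample(seq(s$regulon_size[1], s$regulon_size[2]), 1)
    size <- min(size, length(pool))
    memb <- sample(pool, size)
    pool <- setdiff(pool, memb)
    regulons[[tg]] <- memb
  }
  planted <- lapply(tf_groups, function(tg)
    random_planted_pssm(sample(seq(s$motif_width[1], s$motif_width[2]), 1),
                        motif_id = paste0("planted_", tg)))
  names(planted) <- tf_groups
  regulator_of <- setNames(rep(NA_character_, length(group_ids)), group_ids)
  for (tg in tf_groups) regulator_of[regulons[[tg]]] <- tg

  ## presence of each group in each genome (target always present)
  presence <- matrix(runif(length(group_ids) * s$n_genomes) >= s$loss_prob,
                     nrow = length(group_ids),
                     dimnames = list(group_ids, genome_ids))
  presence[, target] <- TRUE

  ## strands and operons (operon chains exist in the target genome only)
  strands <- setNames(ifelse(runif(length(group_ids)) < s$minus_strand_frac,
                             "-", "+"), group_ids)
  operons <- list()
  for (tg in tf_groups) {
    memb <- regulons[[tg]]
    n_heads <- min(2, max(0, length(memb) - 3))
    if (n_heads == 0) next
    heads <- sample(memb, n_heads)
    for (h in heads)
      operons[[h]] <- sample(1:2, 1)  # number of extra downstream genes
  }

  ## target gene order; optionally relocate TF genes next to a regulon member
  ord <- sample(group_ids)
  for (tg in tf_groups) {
    if (runif(1) >= s$tf_adjacent_prob) next
    anchor <- sample(regulons[[tg]], 1)
    ord <- setdiff(ord, tg)
    pos <- match(anchor, ord)
    ord <- append(ord, tg, after = pos)
  }

  genomes <- list()
  ann <- list()
  truth_sites <- list()
  empty_ann <- data.frame(gene_id = character(0), replicon_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0))
  for (g in genome_ids) {
    keep <- ord[presence[ord, g]]
    if (g != target && length(keep) > 1) {
      ## small local shuffles of the shared order
      for (sw in seq_len(10)) {
        i <- sample(length(keep) - 1, 1)
        keep[c(i, i + 1)] <- keep[c(i + 1, i)]
      }
    }
    ## expand operon chains (target genome only), transcription order
    slots <- list()
    for (grp in keep) {
      chain <- list(list(gene = paste0(g, "_", grp), group = grp,
                         strand = strands[[grp]], op = FALSE))
      if (g == target && !is.null(operons[[grp]])) {
        extras <- lapply(seq_len(operons[[grp]]), function(k)
          list(gene = paste0(g, "_", grp, "_op", k), group = grp,
               strand = strands[[grp]], op = TRUE))
        chain <- c(chain, extras)
      }
      if (strands[[grp]] == "-") chain <- rev(chain)  # genome left-to-right
      slots <- c(slots, chain)
    }
    n <- length(slots)
    ## gap before slot i is small when slot i continues the operon of slot i-1
    op_cont <- vapply(seq_len(n), function(i) {
      i > 1 && slots[[i]]$group == slots[[i - 1]]$group
    }, logical(1))
    gap_len <- ifelse(op_cont,
                      sample(seq(s$operon_gap[1], s$operon_gap[2]), n,
                             replace = TRUE),
                      sample(seq(s$igr_length[1], s$igr_length[2]), n,
                             replace = TRUE))
    gap_len <- c(gap_len,
                 sample(seq(s$igr_length[1], s$igr_length[2]), 1))  # trailing
    ## motif insertions: gene's promoter gap is before it (+) or after it (-)
    inserts <- vector("list", n + 1)
    for (i in seq_len(n)) {
      sl <- slots[[i]]
      if (sl$op) next
      tg <- regulator_of[[sl$group]]
      if (is.na(tg) || !presence[tg, g]) next
      site <- sample_site(planted[[tg]], s$mutation_rate)
      gap_idx <- if (sl$strand == "+") i else i + 1
      fwd_site <- if (sl$strand == "+") site else revcomp(site)
      inserts[[gap_idx]] <- c(inserts[[gap_idx]],
                              setNames(fwd_site, sl$gene))
      truth_sites[[length(truth_sites) + 1]] <- data.frame(
        genome_id = g, gene_id = sl$gene, tf_group = tg, site = site,
        stringsAsFactors = FALSE)
    }
    ## realize gaps and genes
    gene_len <- sample(seq(s$gene_length[1], s$gene_length[2]), n,
                       replace = TRUE)
    pieces <- character(0)
    pos <- 0L
    rows <- list()
    for (i in seq_len(n + 1)) {
      ins <- inserts[[i]]
      L <- gap_len[i]
      need <- if (length(ins)) sum(nchar(ins) + 10) else 0
      if (L < need) L <- need + 10L
      gap <- chain_sample(bg_chain, L)
      if (length(ins)) {
        ## place insertions in disjoint segments of the gap
        seg <- floor(L / length(ins))
        for (k in seq_along(ins)) {
          w <- nchar(ins[k])
          lo <- (k - 1) * seg + 1
          hi <- k * seg - w
          at <- if (hi <= lo) lo else sample(lo:hi, 1)
          substr(gap, at, at + w - 1) <- ins[[k]]
        }
      }
      pieces <- c(pieces, gap)
      pos <- pos + nchar(gap)
      if (i <= n) {
        gene_seq <- paste(sample(DNA_BASES, gene_len[i], replace = TRUE,
                                 prob = bg_chain$stationary), collapse = "")
        pieces <- c(pieces, gene_seq)
        rows[[i]] <- data.frame(
          gene_id = slots[[i]]$gene, replicon_id = "chr",
          start = pos + 1L, end = pos + gene_len[i],
          strand = slots[[i]]$strand, stringsAsFactors = FALSE)
        pos <- pos + gene_len[i]
      }
    }
    genomes[[g]] <- setNames(paste(pieces, collapse = ""), "chr")
    ann[[g]] <- load_annotations(
      if (length(rows)) do.call(rbind, rows) else empty_ann, genome_id = g)
  }

  groups <- lapply(setNames(group_ids, group_ids), function(grp) {
    memb <- lapply(genome_ids[presence[grp, ]], function(g)
      paste0(g, "_", grp))
    setNames(memb, genome_ids[presence[grp, ]])
  })

  tf_ids <- paste0(target, "_", tf_groups)
  truth <- list(
    target_genome = target, genome_ids = genome_ids,
    tf_groups = tf_groups, tf_ids = setNames(tf_ids, tf_groups),
    families = families, regulons = regulons, planted_pssms = planted,
    operons = operons, strands = strands,
    presence = presence,
    sites = if (length(truth_sites)) do.call(rbind, truth_sites) else NULL)
  list(genomes = genomes, annotations = do.call(rbind, ann),
       groups = groups, truth = truth, bg_chain = bg_chain)
}

#' Simulate a gene expression compendium for a synthetic scenario
#'
#' Each TF gets a latent activity profile (standard normal per condition)
#' and an active condition subset. Regulon member expression follows
#' `sign * activity + noise` on active conditions and independent unit noise
#' elsewhere; transcriptionally regulated TFs' own rows track their activity,
#' post-transcriptionally regulated TFs' rows are independent noise; operon
#' members copy their head gene plus small noise; background genes are unit
#' noise. Assumes the RNG is already seeded.
#'
#' @param scenario a `trn_scenario`.
#' @param truth ground truth from [simulate_genomes()].
#' @return list with `matrix` (genes x conditions) and `truth_expression`
#'   (per-TF mode, sign and active condition sets).
#' @export
simulate_expression <- function(scenario, truth) {
  s <- scenario
  target <- truth$target_genome
  conds <- sprintf("C%03d", seq_len(s$n_conditions))
  ## all target-genome genes incl. operon genes
  tgt_genes <- character(0)
  for (grp in names(truth$strands)) {
    tgt_genes <- c(tgt_genes, paste0(target, "_", grp))
    if (!is.null(truth$operons[[grp]]))
      tgt_genes <- c(tgt_genes, paste0(target, "_", grp, "_op",
                                       seq_len(truth$operons[[grp]])))
  }
  m <- matrix(rnorm(length(tgt_genes) * s$n_conditions),
              nrow = length(tgt_genes),
              dimnames = list(tgt_genes, conds))
  n_post <- round(s$frac_post_transcriptional * length(truth$tf_groups))
  post <- sample(truth$tf_groups, n_post)
  modes <- setNames(ifelse(truth$tf_groups %in% post,
                           "post_transcriptional", "transcriptional"),
                    truth$tf_groups)
  signs <- setNames(sample(c(-1, 1), length(truth$tf_groups), replace = TRUE),
                    truth$tf_groups)
  active_sets <- list()
  for (tg in truth$tf_groups) {
    act <- rnorm(s$n_conditions)
    active <- sample(conds, round(s$active_condition_frac * s$n_conditions))
    active_sets[[tg]] <- active
    ai <- match(active, conds)
    for (grp in truth$regulons[[tg]]) {
      head_gene <- paste0(target, "_", grp)
      m[head_gene, ai] <- signs[[tg]] * act[ai] +
        rnorm(length(ai), sd = s$noise_sd)
      if (!is.null(truth$operons[[grp]]))
        for (k in seq_len(truth$operons[[grp]]))
          m[paste0(target, "_", grp, "_op", k), ] <-
            m[head_gene, ] + rnorm(s$n_conditions, sd = s$operon_noise_sd)
    }
    tf_gene <- truth$tf_ids[[tg]]
    if (modes[[tg]] == "transcriptional")
      m[tf_gene, ] <- act + rnorm(s$n_conditions, sd = s$noise_sd)
    ## post-transcriptional TFs keep their independent-noise row
  }
  list(matrix = m,
       truth_expression = list(modes = modes, signs = signs,
                               active_conditions = active_sets))
}

#' Generate a complete synthetic benchmark dataset
#'
#' Seeds the RNG from the scenario, simulates genomes, ortholog groups,
#' expression, a synthetic reference motif library (each planted PSSM,
#' re-sampled with noise, labelled with its TF's DBD family, plus decoy
#' families), and the gold-standard interaction set. Optionally writes every
#' pipeline input format plus the gold standard and a JSON manifest to a
#' directory.
#'
#' @param scenario a `trn_scenario`.
#' @param dir optional output directory (created if needed).
#' @return an object of class `trn_data`: inputs for [infer_trn()] plus
#'   `truth` and `gold`.
#' @export
simulate_trn_data <- function(scenario, dir = NULL) {
  set.seed(scenario$seed)
  gen <- simulate_genomes(scenario)
  expr <- simulate_expression(scenario, gen$truth)
  truth <- gen$truth
  truth$expression <- expr$truth_expression

  ## synthetic reference motif library: noised planted PSSMs + decoys
  library_entries <- list()
  for (tg in truth$tf_groups) {
    sites <- replicate(20, sample_site(truth$planted_pssms[[tg]], 0.05))
    entry_pssm <- build_pssm(sites, pseudocount = 0.25,
                             motif_id = paste0("REF_", truth$families[[tg]]),
                             source = "reference")
    library_entries[[length(library_entries) + 1]] <- list(
      pssm = entry_pssm, tf_name = paste0("REF_", truth$families[[tg]]),
      dbd_family = truth$families[[tg]])
  }
  ## decoy families pad the library towards a realistic reference size, so
  ## that a random family seldom matches any given cluster
  for (dd in 1:20) {
    dec <- random_planted_pssm(sample(10:16, 1),
                               motif_id = sprintf("REF_decoy%02d", dd))
    library_entries[[length(library_entries) + 1]] <- list(
      pssm = dec, tf_name = sprintf("REF_decoy%02d", dd),
      dbd_family = sprintf("Decoy%02d", dd))
  }

  ## gold standard: TF gene -> every regulon member gene incl. operon genes
  target <- truth$target_genome
  gold_rows <- list()
  for (tg in truth$tf_groups) {
    targets <- character(0)
    for (grp in truth$regulons[[tg]]) {
      targets <- c(targets, paste0(target, "_", grp))
      if (!is.null(truth$operons[[grp]]))
        targets <- c(targets, paste0(target, "_", grp, "_op",
                                     seq_len(truth$operons[[grp]])))
    }
    gold_rows[[tg]] <- data.frame(tf = truth$tf_ids[[tg]], target = targets,
                                  stringsAsFactors = FALSE)
  }
  gold_df <- do.call(rbind, gold_rows)
  gold <- gold_standard(gold_df, tfs_with_data = unname(truth$tf_ids))

  tf_table <- data.frame(tf_id = unname(truth$tf_ids),
                         dbd_family = unname(truth$families[truth$tf_groups]),
                         stringsAsFactors = FALSE)

  data <- structure(list(
    scenario = scenario,
    target_genome = target,
    genome_ids = truth$genome_ids,
    genomes = gen$genomes,
    annotations = gen$annotations,
    groups = gen$groups,
    expression = expr$matrix,
    tf_table = tf_table,
    library = library_entries,
    gold = gold,
    truth = truth), class = "trn_data")
  if (!is.null(dir)) write_trn_data(data, dir)
  data
}

#' @export
print.trn_data <- function(x, ...) {
  cat(sprintf(
    "synthetic TRN dataset: %d genomes, %d ortholog groups, %d TFs, %d genes x %d conditions\n",
    length(x$genome_ids), length(x$groups), nrow(x$tf_table),
    nrow(x$expression), ncol(x$expression)))
  invisible(x)
}

#' Write a synthetic dataset to pipeline input files
#'
#' Emits every format the pipeline reads: per-genome FASTA and gene-table
#' TSVs, the ortholog-group table, the expression matrix, the TF table, the
#' reference motif library (MEME minimal + family labels), the gold standard
#' (interactions + assayed TFs), true bicluster condition sets, planted
#' PSSMs, and a JSON manifest of scenario parameters.
#'
#' @param data a `trn_data` from [simulate_trn_data()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_trn_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(data$genomes)) {
    write_genome_fasta(data$genomes[[g]], file.path(dir, paste0(g, ".fasta")))
    write_tsv(data$annotations[data$annotations$genome_id == g,
                               c("gene_id", "replicon_id", "start", "end",
                                 "strand")],
              file.path(dir, paste0(g, "_genes.tsv")))
  }
  og <- do.call(rbind, lapply(names(data$groups), function(gid) {
    memb <- data$groups[[gid]]
    do.call(rbind, lapply(names(memb), function(g)
      data.frame(group_id = gid, genome_id = g, gene_id = memb[[g]],
                 stringsAsFactors = FALSE)))
  }))
  write_tsv(og, file.path(dir, "orthologs.tsv"))
  write_expression(data$expression, file.path(dir, "expression.tsv"))
  write_tsv(data$tf_table, file.path(dir, "tfs.tsv"))
  write_meme(lapply(data$library, `[[`, "pssm"),
             file.path(dir, "library.meme"))
  write_tsv(data.frame(
    tf_name = vapply(data$library, `[[`, "", "tf_name"),
    dbd_family = vapply(data$library, `[[`, "", "dbd_family")),
    file.path(dir, "library_labels.tsv"))
  emit_gold(data, dir)
  manifest <- unclass(data$scenario)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write the gold standard and ground-truth files
#'
#' @param data a `trn_data`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
emit_gold <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(data$gold$pairs, file.path(dir, "gold_interactions.tsv"))
  write_tsv(data.frame(tf_id = data$gold$tfs_with_data),
            file.path(dir, "gold_assayed_tfs.tsv"))
  tb <- do.call(rbind, lapply(names(data$truth$expression$active_conditions),
                              function(tg)
    data.frame(tf_id = data$truth$tf_ids[[tg]],
               condition = data$truth$expression$active_conditions[[tg]],
               stringsAsFactors = FALSE)))
  write_tsv(tb, file.path(dir, "true_biclusters.tsv"))
  write_meme(data$truth$planted_pssms, file.path(dir, "planted_motifs.meme"))
  invisible(dir)
}

#' Read a synthetic dataset back from files
#'
#' Inverse of [write_trn_data()] (ground truth is restored only to the
#' extent it was written: gold standard, planted PSSMs, true bicluster
#' condition sets).
#'
#' @param dir directory written by [write_trn_data()].
#' @return a `trn_data` (with a reduced `truth`).
#' @export
read_trn_data <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fa <- list.files(dir, pattern = "^org[0-9]+\\.fasta$", full.names = TRUE)
  genome_ids <- sub("\\.fasta$", "", basename(fa))
  genomes <- lapply(setNames(fa, genome_ids), read_genome_fasta)
  ann <- do.call(rbind, lapply(genome_ids, function(g)
    load_annotations(file.path(dir, paste0(g, "_genes.tsv")), g)))
  labels <- read_tsv(file.path(dir, "library_labels.tsv"))
  lib_pssms <- read_meme(file.path(dir, "library.meme"))
  library_entries <- lapply(seq_len(nrow(labels)), function(i)
    list(pssm = lib_pssms[[labels$tf_name[i]]], tf_name = labels$tf_name[i],
         dbd_family = labels$dbd_family[i]))
  structure(list(
    scenario = manifest,
    target_genome = sort(genome_ids)[1],
    genome_ids = genome_ids,
    genomes = genomes,
    annotations = ann,
    groups = read_ortholog_groups(file.path(dir, "orthologs.tsv")),
    expression = read_expression(file.path(dir, "expression.tsv")),
    tf_table = read_tsv(file.path(dir, "tfs.tsv")),
    library = library_entries,
    gold = read_gold_standard(file.path(dir, "gold_interactions.tsv"),
                              file.path(dir, "gold_assayed_tfs.tsv")),
    truth = list(
      planted_pssms = read_meme(file.path(dir, "planted_motifs.meme")),
      true_biclusters = read_tsv(file.path(dir, "true_biclusters.tsv")))),
    class = "trn_data")
}
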