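#' Load gene annotations from GFF3 or a gene table
#'
#' Accepts a GFF3 file, a 5-column TSV gene table (`gene_id`, `replicon_id`,
#' `start`, `end`, `strand`) or an equivalent data frame. Coordinates are
#' 1-based inclusive. Records are sorted by replicon then start and a
#' 0-based `gene_index` (rank along the replicon by start coordinate) is
#' assigned per replicon.
#'
#' @param annotation_source file path or data frame.
#' @param genome_id genome identifier attached to every record.
#' @return a data frame of gene records with columns `gene_id`, `genome_id`,
#'   `replicon_id`, `start`, `end`, `strand`, `gene_index`.
#' @export
load_annotations <- function(annotation_source, genome_id) {
  if (is.character(annotation_source) && length(annotation_source) == 1) {
    if (grepl("\\.gff3?(\\.gz)?$", annotation_source, ignore.case = TRUE)) {
      g <- rtracklayer::readGFF(annotation_source)
      g <- as.data.frame(g)
      g <- g[g$type %in% c("gene", "CDS") | !("type" %in% names(g)), ]
      id <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$Name)
      df <- data.frame(gene_id = id, replicon_id = as.character(g$seqid),
                       start = g$start, end = g$end,
                       strand = as.character(g$strand),
                       stringsAsFactors = FALSE)
    } else {
      df <- read_tsv(annotation_source)
    }
  } else {
    df <- as.data.frame(annotation_source, stringsAsFactors = FALSE)
  }
  need <- c("gene_id", "replicon_id", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) {
    out <- df[, need]
    out$genome_id <- character(0)
    out$gene_index <- integer(0)
    return(out[, c("gene_id", "genome_id", "replicon_id", "start", "end",
                   "strand", "gene_index")])
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 1) || any(df$end < df$start))
    stop("invalid coordinates: need 1 <= start <= end")
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(df$strand[!df$strand %in% c("+", "-")]), collapse = ","))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id within genome: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ","))
  df <- df[order(df$replicon_id, df$start, df$end), ]
  df$genome_id <- genome_id
  df$gene_index <- as.integer(stats::ave(df$start, df$replicon_id,
                                         FUN = function(x) seq_along(x) - 1L))
  rownames(df) <- NULL
  df[, c("gene_id", "genome_id", "replicon_id", "start", "end", "strand",
         "gene_index")]
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per replicon (uppercase).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*", "", names(ss))
  out
}

#' Write replicon sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Extract strand-aware upstream intergenic regions
#'
#' For each gene, takes the intergenic gap between the gene's
#' translation-start-proximal boundary and the nearest annotated gene body on
#' its upstream side (5' of the coding strand), and keeps it when strictly
#' longer than `min_len` bases. Sequences are reported in the gene's coding
#' orientation (minus-strand regions are reverse-complemented). A gene at a
#' replicon edge uses the replicon boundary; a shared gap between divergently
#' transcribed genes is assigned to both.
#'
#' @param genes gene table from [load_annotations()].
#' @param replicon_seqs named character vector of replicon sequences.
#' @param min_len minimum (exclusive) IGR length in bp; default 40.
#' @return data frame with columns `gene_id`, `genome_id`, `replicon_id`,
#'   `sequence`, `length`, `upstream_of_strand`.
#' @export
extract_upstream_igrs <- function(genes, replicon_seqs, min_len = 40) {
  out <- vector("list", nrow(genes))
  for (rep_id in unique(genes$replicon_id)) {
    if (!rep_id %in% names(replicon_seqs))
      stop("no sequence for replicon ", rep_id)
    seq <- replicon_seqs[[rep_id]]
    L <- nchar(seq)
    g <- genes[genes$replicon_id == rep_id, ]
    if (any(g$end > L)) stop("gene coordinates exceed replicon length on ", rep_id)
    for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      others <- g[g$gene_id != gi$gene_id, ]
      if (gi$strand == "+") {
        prev_end <- suppressWarnings(max(0L, others$end[others$start < gi$start]))
        from <- prev_end + 1L; to <- gi$start - 1L
        if (to < from) next
        s <- substr(seq, from, to)
      } else {
        cand <- others$start[others$end > gi$end]
        next_start <- if (length(cand)) min(cand) else L + 1L
        from <- gi$end + 1L; to <- next_start - 1L
        if (to < from) next
        s <- revcomp(substr(seq, from, to))
      }
      len <- nchar(s)
      if (len <= min_len) next
      out[[length(out) + 1]] <- data.frame(
        gene_id = gi$gene_id, genome_id = gi$genome_id,
        replicon_id = rep_id, sequence = s, length = len,
        upstream_of_strand = gi$strand, stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(gene_id = character(0), genome_id = character(0),
                      replicon_id = character(0), sequence = character(0),
                      length = integer(0), upstream_of_strand = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read an ortholog-group table
#'
#' @param x path to a TSV with columns `group_id`, `genome_id`, `gene_id`,
#'   or an equivalent data frame.
#' @return named list mapping group id to a named list of per-genome gene-id
#'   vectors.
#' @export
read_ortholog_groups <- function(x) {
  df <- if (is.character(x)) read_tsv(x) else as.data.frame(x)
  stopifnot(all(c("group_id", "genome_id", "gene_id") %in% names(df)))
  lapply(split(df, df$group_id), function(d)
    lapply(split(d$gene_id, d$genome_id), unique))
}

#' Assemble input groups for phylogenetic footprinting
#'
#' Collects the upstream IGR sequences of every member of each ortholog
#' group and keeps groups with at least `min_seqs` sequences and at least
#' one member from the target genome. Sequences are deduplicated by
#' (genome, gene).
#'
#' @param groups ortholog groups (see [read_ortholog_groups()]).
#' @param igrs IGR table from [extract_upstream_igrs()] (all genomes pooled).
#' @param min_seqs minimum number of IGR sequences per retained group.
#' @param target_genome genome id that must be represented in each group.
#' @return named list mapping group id to a named character vector of IGR
#'   sequences (names `genome|gene`).
#' @export
assemble_footprinting_groups <- function(groups, igrs, min_seqs = 4,
                                         target_genome) {
  key <- paste(igrs$genome_id, igrs$gene_id, sep = "|")
  seqs <- setNames(igrs$sequence, key)
  out <- list()
  for (gid in names(groups)) {
    memb <- groups[[gid]]
    if (!target_genome %in% names(memb)) next
    wanted <- unlist(lapply(names(memb), function(g)
      paste(g, memb[[g]], sep = "|")), use.names = FALSE)
    wanted <- unique(wanted)
    have <- wanted[wanted %in% names(seqs)]
    tg <- startsWith(have, paste0(target_genome, "|"))
    if (length(have) >= min_seqs && any(tg)) out[[gid]] <- seqs[have]
  }
  out
}

#' Transcription-factor presence/absence matrix across genomes
#'
#' An entry is 1 when the TF's ortholog group has at least one member in the
#' genome; TFs without an ortholog group are marked present only in the
#' target genome.
#'
#' @param tf_ids character vector of TF gene ids (target genome).
#' @param groups ortholog groups.
#' @param genome_ids genomes to tabulate (columns).
#' @param target_genome the target genome id.
#' @return binary matrix, TFs x genomes.
#' @export
tf_presence_matrix <- function(tf_ids, groups, genome_ids, target_genome) {
  ## map each TF to its group (a TF belongs to at most one group)
  tf2group <- setNames(rep(NA_character_, length(tf_ids)), tf_ids)
  for (gid in names(groups)) {
    tg <- groups[[gid]][[target_genome]]
    hit <- tf_ids %in% tg
    tf2group[hit] <- gid
  }
  m <- matrix(0L, nrow = length(tf_ids), ncol = length(genome_ids),
              dimnames = list(tf_ids, genome_ids))
  for (tf in tf_ids) {
    gid <- tf2group[[tf]]
    if (!is.na(gid)) {
      present <- genome_ids %in% names(groups[[gid]])[
        vapply(groups[[gid]], length, integer(1)) > 0]
      m[tf, present] <- 1L
    }
    m[tf, target_genome] <- 1L
  }
  m
}
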