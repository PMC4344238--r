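test_that("annotations are ordered and indexed per replicon", {
  g <- toy_genes(c(900, 100, 500))
  expect_equal(g$gene_id, c("gene02", "gene03", "gene01"))
  expect_equal(g$gene_index, 0:2)

  two <- load_annotations(data.frame(
    gene_id = paste0("g", 1:4),
    replicon_id = c("chr2", "chr1", "chr2", "chr1"),
    start = c(10, 5, 200, 300), end = c(50, 60, 260, 380),
    strand = "+"), genome_id = "g1")
  expect_equal(two$gene_index, c(0L, 1L, 0L, 1L))
  expect_equal(two$replicon_id, c("chr1", "chr1", "chr2", "chr2"))

  empty <- load_annotations(
    data.frame(gene_id = character(0), replicon_id = character(0),
               start = integer(0), end = integer(0), strand = character(0)),
    genome_id = "g1")
  expect_equal(nrow(empty), 0)
})

test_that("GFF3 annotation files are read", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tgene\t100\t400\t.\t+\t.\tID=geneA",
    "chr\ttest\tgene\t600\t900\t.\t-\t.\tID=geneB"), path)
  g <- load_annotations(path, "g1")
  expect_equal(g$gene_id, c("geneA", "geneB"))
  expect_equal(g$strand, c("+", "-"))
  expect_equal(g$gene_index, c(0L, 1L))
})

test_that("invalid annotations are rejected", {
  df <- data.frame(gene_id = c("a", "a"), replicon_id = "chr",
                   start = c(1, 100), end = c(50, 150), strand = "+")
  expect_error(load_annotations(df, "g1"), "duplicate gene_id")
  df2 <- data.frame(gene_id = "a", replicon_id = "chr",
                    start = 1, end = 50, strand = "*")
  expect_error(load_annotations(df2, "g1"), "strand")
  df3 <- data.frame(gene_id = "a", replicon_id = "chr",
                    start = 60, end = 50, strand = "+")
  expect_error(load_annotations(df3, "g1"), "coordinates")
})

test_that("upstream IGR coordinates follow the strand-aware gap rule", {
  seq <- paste(rep("ACGT", 300), collapse = "")  # 1200 bp
  genes <- load_annotations(data.frame(
    gene_id = c("up", "focal"), replicon_id = "chr",
    start = c(301, 501), end = c(400, 900), strand = "+"), "g1")
  igr <- extract_upstream_igrs(genes, c(chr = seq))
  focal <- igr[igr$gene_id == "focal", ]
  expect_equal(focal$length, 100)
  expect_equal(focal$sequence, substr(seq, 401, 500))
  ## "up" at the replicon edge gets positions 1..300
  expect_equal(igr$length[igr$gene_id == "up"], 300)
})

test_that("a 40 bp gap is excluded (strictly greater than 40)", {
  seq <- paste(rep("ACGT", 300), collapse = "")
  g40 <- load_annotations(data.frame(
    gene_id = c("up", "focal"), replicon_id = "chr",
    start = c(301, 441), end = c(400, 700), strand = "+"), "g1")
  igr <- extract_upstream_igrs(g40, c(chr = seq))
  expect_false("focal" %in% igr$gene_id)
  g41 <- load_annotations(data.frame(
    gene_id = c("up", "focal"), replicon_id = "chr",
    start = c(301, 442), end = c(400, 700), strand = "+"), "g1")
  igr41 <- extract_upstream_igrs(g41, c(chr = seq))
  expect_equal(igr41$length[igr41$gene_id == "focal"], 41)
})

test_that("minus-strand IGRs are taken downstream and reverse-complemented", {
  set.seed(9)
  seq <- random_dna(1, 1000)
  genes <- load_annotations(data.frame(
    gene_id = c("focal", "next"), replicon_id = "chr",
    start = c(101, 501), end = c(300, 800), strand = c("-", "+")), "g1")
  igr <- extract_upstream_igrs(genes, c(chr = seq))
  focal <- igr[igr$gene_id == "focal", ]
  expect_equal(focal$sequence, revcomp(substr(seq, 301, 500)))
  ## the shared gap also serves the divergent downstream gene
  expect_equal(igr$sequence[igr$gene_id == "next"], substr(seq, 301, 500))
})

test_that("IGR extraction is strand-consistent under reverse complement", {
  set.seed(10)
  L <- 2000
  seq <- random_dna(1, L)
  df <- data.frame(gene_id = c("a", "b", "c"), replicon_id = "chr",
                   start = c(101, 601, 1301), end = c(400, 1000, 1700),
                   strand = c("+", "-", "+"))
  igr <- extract_upstream_igrs(load_annotations(df, "g1"), c(chr = seq))
  ## mirror the replicon
  df2 <- df
  df2$start <- L - df$end + 1
  df2$end <- L - df$start + 1
  df2$strand <- chartr("+-", "-+", df$strand)
  igr2 <- extract_upstream_igrs(load_annotations(df2, "g1"),
                                c(chr = revcomp(seq)))
  for (g in df$gene_id)
    expect_equal(igr2$sequence[igr2$gene_id == g],
                 igr$sequence[igr$gene_id == g], label = g)
})

test_that("no IGR overlaps an annotated gene body", {
  set.seed(11)
  seq <- random_dna(1, 3000)
  starts <- sort(sample(seq(1, 2800, by = 40), 12))
  genes <- load_annotations(data.frame(
    gene_id = sprintf("g%02d", seq_along(starts)), replicon_id = "chr",
    start = starts, end = starts + 29,
    strand = sample(c("+", "-"), length(starts), replace = TRUE)), "g1")
  igr <- extract_upstream_igrs(genes, c(chr = seq), min_len = 5)
  for (i in seq_len(nrow(igr))) {
    gi <- genes[genes$gene_id == igr$gene_id[i], ]
    span <- if (gi$strand == "+")
      c(gi$start - igr$length[i], gi$start - 1)
    else c(gi$end + 1, gi$end + igr$length[i])
    overlaps <- genes$start <= span[2] & genes$end >= span[1]
    expect_false(any(overlaps), label = igr$gene_id[i])
  }
})

test_that("footprinting groups require >= 4 IGRs and a target member", {
  igrs <- data.frame(
    gene_id = paste0("gene", 1:7),
    genome_id = c("t", "a", "b", "c", "t", "a", "b"),
    replicon_id = "chr",
    sequence = random_dna(7, 60), length = 60, upstream_of_strand = "+")
  groups <- list(
    og1 = list(t = "gene1", a = "gene2", b = "gene3", c = "gene4"),
    og2 = list(t = "gene5", a = "gene6", b = "gene7"),          # only 3 IGRs
    og3 = list(a = "gene2", b = "gene3", c = "gene4"))          # no target
  out <- assemble_footprinting_groups(groups, igrs, min_seqs = 4,
                                      target_genome = "t")
  expect_equal(names(out), "og1")
  expect_length(out$og1, 4)
  expect_length(assemble_footprinting_groups(list(), igrs, 4, "t"), 0)
  ## deduplication by (genome, gene)
  groups_dup <- list(og = list(t = c("gene1", "gene1"), a = "gene2",
                               b = "gene3", c = "gene4"))
  out2 <- assemble_footprinting_groups(groups_dup, igrs, 4, "t")
  expect_length(out2$og, 4)
})

test_that("TF presence matrix matches a manual tally", {
  groups <- list(og1 = list(t = "tf1", a = "x1", b = "x2"),
                 og2 = list(t = "tf2", c = "y1"))
  m <- tf_presence_matrix(c("tf1", "tf2", "tf3"), groups,
                          genome_ids = c("t", "a", "b", "c"),
                          target_genome = "t")
  expect_equal(m["tf1", ], c(t = 1L, a = 1L, b = 1L, c = 0L))
  expect_equal(m["tf2", ], c(t = 1L, a = 0L, b = 0L, c = 1L))
  ## TF with no group: target-only
  expect_equal(m["tf3", ], c(t = 1L, a = 0L, b = 0L, c = 0L))
  ## group spanning all genomes -> row of ones
  g4 <- list(og = list(t = "tf4", a = "p", b = "q", c = "r"))
  m4 <- tf_presence_matrix("tf4", g4, c("t", "a", "b", "c"), "t")
  expect_true(all(m4 == 1))
})
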