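test_that("PSSM self-comparison and reverse-complement behave as expected", {
  set.seed(41)
  a <- build_pssm(c("TGTAACGCAA", "TGTAACGCAA", "TGAAACGCTA",
                    "TGTAACGCAA", "CGTAACGCAA"), motif_id = "a")
  self <- compare_pssms(a, a, seed = 1)
  expect_equal(self$stat, 1, tolerance = 1e-9)
  expect_equal(self$offset, 0)
  expect_equal(self$orientation, "+")
  expect_lt(self$p_value, 0.05)

  rc <- compare_pssms(a, pssm_revcomp(a), seed = 1)
  expect_equal(rc$stat, 1, tolerance = 1e-9)
  expect_equal(rc$orientation, "-")
})

test_that("a one-hot PSSM is not significantly similar to a uniform PSSM", {
  onehot <- build_pssm("ACGTACGT", pseudocount = 0.05, motif_id = "oh")
  unif <- pssm_from_freq(matrix(0.25, 4, 8), motif_id = "u")
  cmp <- compare_pssms(onehot, unif, seed = 2)
  expect_gte(cmp$p_value, 0.3)
})

test_that("comparison is invariant under joint reverse complement", {
  set.seed(42)
  a <- build_pssm(random_dna(6, 10), motif_id = "a")
  b <- build_pssm(random_dna(6, 12), motif_id = "b")
  s1 <- compare_pssms(a, b, seed = 3)$stat
  s2 <- compare_pssms(pssm_revcomp(a), pssm_revcomp(b), seed = 3)$stat
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("BH q-values match hand computation and dominate p-values", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(qvalues(rep(0, 4)), rep(0, 4))
  set.seed(43)
  p <- runif(50)
  q <- qvalues(p)
  expect_true(all(q >= p - 1e-12))
  expect_equal(q, p.adjust(p, "BH"))
})

mk_hit_df <- function(motif_id, genes, offsets, strand = "+", width = 8) {
  data.frame(motif_id = motif_id, genome_id = "t", gene_id = genes,
             offset = offsets, strand = strand, width = width,
             score = 10, p_value = 1e-6, stringsAsFactors = FALSE)
}

test_that("motif clustering follows the overlap AND q-value rule", {
  set.seed(44)
  sites <- random_dna(6, 8)
  m1 <- build_pssm(sites, motif_id = "m1")
  m2 <- build_pssm(sites, motif_id = "m2")
  m3 <- build_pssm(random_dna(6, 8), motif_id = "m3")
  genes <- sprintf("g%02d", 1:6)
  hits <- rbind(mk_hit_df("m1", genes, rep(50, 6)),
                mk_hit_df("m2", genes, rep(51, 6)),      # same sites
                mk_hit_df("m3", genes[1], 200))          # disjoint site
  qmap <- c("m1||m2" = 0.001, "m1||m3" = 0.001, "m2||m3" = 0.001)
  cl <- cluster_motifs(list(m1, m2, m3), hits, pair_q = qmap)
  sizes <- sort(vapply(cl, function(c) length(c$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))
  big <- cl[[which.max(sizes == 2)]]
  expect_setequal(cl[[1]]$members, c("m1", "m2"))

  ## identical hits but non-significant q: two singletons
  cl2 <- cluster_motifs(list(m1, m2), hits[hits$motif_id != "m3", ],
                        pair_q = c("m1||m2" = 0.5))
  expect_equal(length(cl2), 2)

  ## overlap 0.2 (1 of 5 shared) with strong q: still singletons
  h3 <- rbind(mk_hit_df("m1", genes[1:5], rep(50, 5)),
              mk_hit_df("m2", c(genes[1], sprintf("x%d", 1:4)), rep(50, 5)))
  cl3 <- cluster_motifs(list(m1, m2), h3, pair_q = c("m1||m2" = 0.001))
  expect_equal(length(cl3), 2)

  ## single motif: one singleton cluster
  cl4 <- cluster_motifs(list(m1), mk_hit_df("m1", genes, rep(10, 6)))
  expect_equal(length(cl4), 1)
  expect_equal(cl4[[1]]$members, "m1")
})

test_that("clustering is invariant to input order and bounded by motif count", {
  set.seed(45)
  sites <- random_dna(6, 8)
  ms <- list(build_pssm(sites, motif_id = "a"),
             build_pssm(sites, motif_id = "b"),
             build_pssm(random_dna(6, 8), motif_id = "c"))
  genes <- sprintf("g%02d", 1:6)
  hits <- rbind(mk_hit_df("a", genes, rep(50, 6)),
                mk_hit_df("b", genes, rep(50, 6)),
                mk_hit_df("c", rev(genes), rep(200, 6)))
  qmap <- c("a||b" = 1e-4, "a||c" = 1, "b||c" = 1)
  cl_fwd <- cluster_motifs(ms, hits, pair_q = qmap)
  cl_rev <- cluster_motifs(rev(ms), hits, pair_q = qmap)
  memb <- function(cl) sort(vapply(cl, function(c)
    paste(sort(c$members), collapse = "+"), character(1)))
  expect_equal(memb(cl_fwd), memb(cl_rev))
  expect_lte(length(cl_fwd), 3)
})
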