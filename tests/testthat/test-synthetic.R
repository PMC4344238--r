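test_that("generation is deterministic under a fixed seed", {
  sc <- trn_scenario("easy", n_ortholog_groups = 25, n_tfs = 2, seed = 5)
  d1 <- simulate_trn_data(sc)
  d2 <- simulate_trn_data(sc)
  expect_identical(d1$genomes, d2$genomes)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$gold$interactions, d2$gold$interactions)
  ## a different seed changes the sequences
  d3 <- simulate_trn_data(trn_scenario("easy", n_ortholog_groups = 25,
                                       n_tfs = 2, seed = 6))
  expect_false(identical(d1$genomes, d3$genomes))
})

test_that("gold size equals the summed regulon sizes including operon genes", {
  sc <- trn_scenario("easy", n_ortholog_groups = 40, n_tfs = 3, seed = 7)
  d <- simulate_trn_data(sc)
  expected <- 0
  for (tg in d$truth$tf_groups) {
    for (grp in d$truth$regulons[[tg]]) {
      expected <- expected + 1
      if (!is.null(d$truth$operons[[grp]]))
        expected <- expected + d$truth$operons[[grp]]
    }
  }
  expect_equal(length(d$gold$interactions), expected)
})

test_that("without mutations every regulon IGR carries an exact site", {
  sc <- trn_scenario("easy", n_ortholog_groups = 30, n_tfs = 2,
                     mutation_rate = 0, loss_prob = 0, seed = 8)
  d <- simulate_trn_data(sc)
  igrs <- do.call(rbind, lapply(d$genome_ids[1:3], function(g)
    extract_upstream_igrs(d$annotations[d$annotations$genome_id == g, ],
                          d$genomes[[g]])))
  sites <- d$truth$sites
  checked <- 0
  for (i in sample(nrow(sites), 20)) {
    seq <- igrs$sequence[igrs$gene_id == sites$gene_id[i] &
                         igrs$genome_id == sites$genome_id[i]]
    if (!length(seq)) next
    expect_true(grepl(sites$site[i], seq, fixed = TRUE),
                label = sites$gene_id[i])
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("complete ortholog loss outside the target defeats footprinting", {
  sc <- trn_scenario("easy", n_ortholog_groups = 20, n_tfs = 2,
                     loss_prob = 1, seed = 9)
  d <- simulate_trn_data(sc)
  igrs <- do.call(rbind, lapply(d$genome_ids, function(g)
    extract_upstream_igrs(d$annotations[d$annotations$genome_id == g, ],
                          d$genomes[[g]])))
  fp <- assemble_footprinting_groups(d$groups, igrs, min_seqs = 4,
                                     target_genome = d$target_genome)
  expect_length(fp, 0)
})

test_that("expression encodes regulons, operons and regulation mode", {
  sc <- trn_scenario("easy", n_ortholog_groups = 40, n_tfs = 3,
                     noise_sd = 0.01, seed = 10)
  d <- simulate_trn_data(sc)
  tg <- d$truth$tf_groups[1]
  memb <- paste0(d$target_genome, "_", d$truth$regulons[[tg]][1:2])
  active <- d$truth$expression$active_conditions[[tg]]
  r <- cor(d$expression[memb[1], active], d$expression[memb[2], active])
  expect_gt(abs(r), 0.99)

  ## operon pairs correlate over all conditions above the extension rule
  ops <- names(d$truth$operons)
  if (length(ops)) {
    head_gene <- paste0(d$target_genome, "_", ops[1])
    op_gene <- paste0(d$target_genome, "_", ops[1], "_op1")
    expect_gte(cor(d$expression[head_gene, ], d$expression[op_gene, ]), 0.8)
  }

  ## post-transcriptional TFs are uncorrelated with their targets
  sp <- trn_scenario("post_transcriptional", n_ortholog_groups = 40,
                     n_tfs = 3, seed = 11)
  dp <- simulate_trn_data(sp)
  rs <- unlist(lapply(dp$truth$tf_groups, function(tg) {
    tf <- dp$truth$tf_ids[[tg]]
    vapply(dp$truth$regulons[[tg]][1:3], function(grp)
      abs(cor(dp$expression[tf, ],
              dp$expression[paste0(dp$target_genome, "_", grp), ])),
      numeric(1))
  }))
  expect_lt(mean(rs), 0.2)
})

test_that("emitted files round-trip the dataset", {
  sc <- trn_scenario("easy", n_ortholog_groups = 20, n_tfs = 2, seed = 12)
  dir <- tempfile("trnsim")
  d <- simulate_trn_data(sc, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_trn_data(dir)
  expect_identical(sort(back$gold$interactions), sort(d$gold$interactions))
  expect_equal(back$expression, d$expression, tolerance = 1e-6)
  expect_identical(back$genomes[[d$target_genome]],
                   d$genomes[[d$target_genome]])
  expect_equal(length(back$library), length(d$library))
  pl <- back$truth$planted_pssms[[1]]
  orig <- d$truth$planted_pssms[[sub("planted_", "", pl$motif_id)]]
  expect_equal(pl$freq, orig$freq, tolerance = 1e-5)
  g1 <- load_annotations(file.path(dir, paste0(d$target_genome,
                                               "_genes.tsv")),
                         d$target_genome)
  expect_equal(nrow(g1),
               sum(d$annotations$genome_id == d$target_genome))
})
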