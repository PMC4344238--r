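test_that("corr_mean averages absolute correlations on the condition subset", {
  conds <- sprintf("C%d", 1:4)
  m <- rbind(tf = c(1, 2, 3, 4),
             g1 = c(2, 4, 6, 8),
             g2 = c(-1, -2, -3, -4),
             g3 = c(1, 3, 2, 4))
  colnames(m) <- conds
  bic <- list(genes = c("g1", "g2"), conditions = conds)
  expect_equal(corr_mean("tf", bic, m), 1)     # identical and negated profiles
  ## hand-computed Pearson for a 4-condition pair
  r <- cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  bic2 <- list(genes = "g3", conditions = conds)
  expect_equal(corr_mean("tf", bic2, m), abs(r))
  ## TF itself excluded from the member list
  bic3 <- list(genes = c("tf", "g1"), conditions = conds)
  expect_equal(corr_mean("tf", bic3, m), 1)
  ## TF absent from the array -> undefined
  expect_true(is.na(corr_mean("nope", bic, m)))
})

test_that("prox_min measures gene-rank distance on the shared replicon", {
  genes <- load_annotations(data.frame(
    gene_id = c("tf", "a", "b", "far"),
    replicon_id = c("chr", "chr", "chr", "plasmid"),
    start = c(100, 300, 900, 50), end = c(200, 400, 1000, 80),
    strand = "+"), "g1")
  expect_equal(prox_min("tf", c("tf", "a"), genes), 0L)
  expect_equal(prox_min("tf", "a", genes), 1L)
  expect_equal(prox_min("tf", "b", genes), 2L)
  expect_true(is.na(prox_min("tf", "far", genes)))
})

test_that("dbd_score picks the most significant family match", {
  set.seed(61)
  sites <- random_dna(8, 10)
  cl_pssm <- build_pssm(sites, motif_id = "mc001")
  lib <- list(
    list(pssm = build_pssm(sites, motif_id = "L1"), tf_name = "L1",
         dbd_family = "Crp"),
    list(pssm = build_pssm(random_dna(8, 10), motif_id = "L2"),
         tf_name = "L2", dbd_family = "Crp"),
    list(pssm = build_pssm(random_dna(8, 10), motif_id = "L3"),
         tf_name = "L3", dbd_family = "LacI"))
  qtab <- dbd_q_table(list(mc001 = cl_pssm), lib, seed = 6)
  ## brute force: the reported score is -log10 of the family minimum q
  crp_q <- qtab$q_value[qtab$dbd_family == "Crp"]
  expect_equal(dbd_score("Crp", "mc001", qtab), -log10(min(crp_q)))
  ## the identical library PSSM should be the family's best match
  expect_equal(min(crp_q), qtab$q_value[qtab$tf_name == "L1"])
  expect_gt(dbd_score("Crp", "mc001", qtab), dbd_score("LacI", "mc001", qtab))
  expect_true(is.na(dbd_score("Zn2Cys6", "mc001", qtab)))
  expect_true(is.na(dbd_score("", "mc001", qtab)))
})

test_that("phylogenetic correlation matches a hand computation", {
  mocc <- c(t = 1, a = 0.9, b = 0.1, c = 0.05)
  pres_match <- c(t = 1, a = 1, b = 0, c = 0)
  expect_equal(phylo_corr(pres_match, mocc), cor(mocc, pres_match))
  expect_gt(phylo_corr(pres_match, mocc), 0.9)
  ## K = 4 hand-built toy, compared against cor()
  mocc2 <- c(t = 1, a = 0.3, b = 0.7, c = 0.2)
  pres2 <- c(t = 1, a = 0, b = 1, c = 1)
  expect_equal(phylo_corr(pres2, mocc2), cor(mocc2, pres2))
  ## TF present everywhere: zero variance -> undefined
  expect_true(is.na(phylo_corr(c(t = 1, a = 1, b = 1, c = 1), mocc)))
})

test_that("permutation p-values use the count/1000 rule with a floor", {
  null <- 1:1000 / 1000
  expect_equal(permutation_pvalue(2, null, "ge"), 1 / 1001)
  expect_equal(permutation_pvalue(-1, null, "ge"), 1)
  expect_equal(permutation_pvalue(0.5, null, "ge"), 0.501, tolerance = 2e-3)
  expect_equal(permutation_pvalue(0, null, "le"), 1 / 1001)
  expect_equal(permutation_pvalue(NA, null, "ge"), 1)
})

test_that("the combined score is -log10 of the p-value product", {
  expect_equal(r_score(0.1, 0.1, 0.1, 0.1), 4)
  expect_equal(r_score(0.01, 1, 1, 1), 2)
  expect_equal(r_score(0.5, NA, NA, NA), -log10(0.5))
  expect_error(r_score(0, 1, 1, 1))
  expect_error(r_score(0.5, 1.2, 1, 1))
  ## strictly decreasing in each argument over a seeded grid
  set.seed(62)
  for (i in 1:20) {
    p <- runif(4, 0.01, 1)
    j <- sample(4, 1)
    p2 <- p; p2[j] <- p[j] * 0.5
    expect_gt(do.call(r_score, as.list(p2)), do.call(r_score, as.list(p)))
  }
})

test_that("TF ranking orders by r_score with documented tie-breaks", {
  sc <- data.frame(
    tf_id = c("tfA", "tfB", "tfC"), cluster_id = "c1",
    corr_mean = 0.5, p_corr = c(0.2, 0.1, 0.1),
    prox_min = 1L, p_prox = 1,
    dbd_score = 1, p_dbd = c(0.5, 0.05, 0.5),
    phylo_corr = 0, p_pc = 1,
    r_score = c(5.2, 3.1, 3.1), stringsAsFactors = FALSE)
  rk <- rank_tfs_for_cluster(sc)
  expect_equal(rk$tf_id, c("tfA", "tfB", "tfC"))  # tie broken by p_dbd
  expect_true(rk$network_tf[1] && !any(rk$network_tf[-1]))
  one <- rank_tfs_for_cluster(sc[1, ])
  expect_equal(one$rank, 1L)
})

test_that("null generation is reproducible and roughly centered", {
  set.seed(63)
  m <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("C%02d", 1:60)))
  genes <- load_annotations(data.frame(
    gene_id = rownames(m), replicon_id = "chr",
    start = seq(1, by = 500, length.out = 40),
    end = seq(400, by = 500, length.out = 40), strand = "+"), "t")
  tf_table <- data.frame(tf_id = c("g01", "g02"), dbd_family = "Crp")
  bics <- list(c1 = list(genes = sprintf("g%02d", 10:15),
                         conditions = sprintf("C%02d", 1:40)))
  n1 <- build_nulls(tf_table, bics, m, genes, n = 300, seed = 7)
  n2 <- build_nulls(tf_table, bics, m, genes, n = 300, seed = 7)
  expect_identical(n1$corr, n2$corr)
  ## E|r| for n conditions is about sqrt(2 / (pi (n - 1)))
  expect_lt(abs(mean(n1$corr) - sqrt(2 / (pi * 39))), 0.02)
})

test_that("removing a criterion never increases any combined score", {
  set.seed(64)
  for (i in 1:20) {
    p <- runif(4, 1e-3, 1)
    full <- r_score(p[1], p[2], p[3], p[4])
    drop1 <- r_score(p[1], 1, p[3], p[4])
    expect_lte(drop1, full + 1e-12)
  }
})
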