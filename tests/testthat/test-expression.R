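test_that("row standardization gives z-scores and drops constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 0))
  expect_warning(s <- standardize_rows(m), "constant")
  expect_equal(unname(s["a", ]), c(-1, 0, 1))
  expect_false("b" %in% rownames(s))
  expect_true(all(abs(rowMeans(s)) < 1e-9))
  expect_true(all(abs(apply(s, 1, sd) - 1) < 1e-9))
  ## idempotent on already standardized rows
  expect_equal(standardize_rows(s), s)
})

planted_matrix <- function(seed = 3, n_bg = 200, n_cond = 100, k = 5,
                           n_active = 40, noise = 0.3) {
  set.seed(seed)
  m <- matrix(rnorm(n_bg * n_cond), n_bg, n_cond,
              dimnames = list(sprintf("g%03d", 1:n_bg),
                              sprintf("C%03d", 1:n_cond)))
  act <- rnorm(n_cond)
  active <- sort(sample(seq_len(n_cond), n_active))
  for (g in seq_len(k)) m[g, active] <- act[active] + rnorm(n_active, sd = noise)
  list(m = suppressWarnings(standardize_rows(m)), active = active)
}

test_that("bicluster refinement recovers a planted condition subset", {
  px <- planted_matrix()
  bic <- refine_coexpression(sprintf("g%03d", 1:5), px$m, seed = 42)
  expect_s3_class(bic, "bicluster")
  expect_setequal(bic$genes, sprintf("g%03d", 1:5))
  kept <- sum(sprintf("C%03d", px$active) %in% bic$conditions)
  expect_gte(kept, 0.9 * length(px$active))
  expect_lte(bic$p_value, 0.001)
  ## refined score is at least the all-condition score of the input set
  base <- trninfer:::cpp_mean_abs_cor(px$m[sprintf("g%03d", 1:5), ])
  expect_gte(bic$mean_abs_pairwise_corr, base)
})

test_that("an unrelated gene is removed and tiny modules are rejected", {
  px <- planted_matrix()
  bic <- refine_coexpression(sprintf("g%03d", c(1:5, 50)), px$m, seed = 42)
  expect_false("g050" %in% bic$genes)
  expect_setequal(bic$genes, sprintf("g%03d", 1:5))
  expect_null(refine_coexpression(sprintf("g%03d", 1:2), px$m, seed = 1))
})

test_that("pure-noise gene sets are not accepted", {
  px <- planted_matrix()
  hits <- vapply(1:25, function(i) {
    gs <- sample(rownames(px$m)[6:200], 5)
    !is.null(refine_coexpression(gs, px$m, seed = i, n_perm = 400))
  }, logical(1))
  expect_equal(sum(hits), 0)
})

operon_fixture <- function() {
  set.seed(51)
  n <- 100
  shared <- rnorm(n)
  m <- rbind(seed1 = shared + rnorm(n, sd = 0.2),
             down1 = shared + rnorm(n, sd = 0.2),     # r ~ 0.96
             down2 = shared + rnorm(n, sd = 2.5),     # r ~ 0.4
             down3 = shared + rnorm(n, sd = 0.2),
             chain2 = shared + rnorm(n, sd = 0.25))
  preds <- data.frame(upstream_gene = c("seed1", "seed1", "down1"),
                      downstream_gene = c("down1", "down2", "chain2"))
  list(m = m, preds = preds)
}

test_that("operon extension requires both the prediction and r >= 0.8", {
  fx <- operon_fixture()
  out <- operon_extend("seed1", fx$preds, fx$m, r_min = 0.8)
  expect_true("down1" %in% out)           # predicted, r ~ 0.96
  expect_false("down2" %in% out)          # predicted, r ~ 0.4
  expect_false("down3" %in% out)          # r ~ 0.96 but no prediction
  expect_true("chain2" %in% out)          # transitive through down1
  ## monotone and idempotent
  expect_true(all(c("seed1") %in% out))
  expect_setequal(operon_extend(out, fx$preds, fx$m), out)
})

test_that("distance-based operon prediction pairs adjacent co-strand genes", {
  genes <- load_annotations(data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    replicon_id = "chr",
    start = c(1, 121, 431, 551, 951),
    end = c(100, 400, 530, 750, 1200),
    strand = c("+", "+", "-", "-", "-")), "g1")
  preds <- predict_operons_by_distance(genes, max_gap = 50)
  key <- paste(preds$upstream_gene, preds$downstream_gene, sep = ">")
  expect_true("a>b" %in% key)     # gap 20, co-strand +
  expect_true("d>c" %in% key)     # gap 20, co-strand -, transcription order
  expect_false(any(grepl("b", key) & grepl("c", key)))  # strand switch
  expect_false("d>e" %in% key | "e>d" %in% key)          # gap 200
})
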