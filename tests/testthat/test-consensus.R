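test_that("CLR ranks a duplicated profile as its TF's top edge", {
  set.seed(71)
  m <- matrix(rnorm(30 * 60), 30, 60,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("C%02d", 1:60)))
  m["g02", ] <- m["g01", ] + rnorm(60, sd = 0.05)
  edges <- clr_scores(m, tf_ids = c("g01", "g05"))
  g1 <- edges[edges$tf == "g01", ]
  expect_equal(g1$target[1], "g02")
  expect_false(any(edges$tf == edges$target))
  ## a noise TF's top score stays below the duplicated pair's score
  expect_gt(max(g1$score), max(edges$score[edges$tf == "g05"]))
})

test_that("tree-ensemble importances identify the predictive TF", {
  set.seed(72)
  m <- matrix(rnorm(20 * 80), 20, 80,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("C%02d", 1:80)))
  m["g10", ] <- m["g01", ] + rnorm(80, sd = 0.2)
  edges <- tree_importance_scores(m, tf_ids = c("g01", "g02", "g03"),
                                  seed = 72)
  to_g10 <- edges[edges$target == "g10", ]
  expect_equal(to_g10$tf[which.max(to_g10$score)], "g01")
  ## constant target is skipped
  m2 <- m; m2["g15", ] <- 1
  e2 <- tree_importance_scores(m2, tf_ids = c("g01", "g02", "g03"), seed = 72)
  expect_false("g15" %in% e2$target)
})

test_that("imported ranked lists are validated, deduplicated and truncated", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(tf = "t1", target = sprintf("g%05d", 1:60000),
                   score = rev(seq_len(60000)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- import_ranked_list(path, "anova")
  expect_equal(nrow(out), 50000)
  expect_equal(out$rank, seq_len(50000))
  expect_true(all(diff(out$score) <= 0))

  small <- data.frame(tf = c("a", "a", "b"), target = c("x", "x", "y"),
                      score = c(1, 3, 2))
  write.table(small, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(out2 <- import_ranked_list(path, "anova"), "duplicate")
  expect_equal(nrow(out2), 2)
  expect_equal(out2$score[out2$tf == "a"], 3)

  bad <- data.frame(tf = c("a", "b"), target = c("x", "y"),
                    score = c(1, NA))
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(import_ranked_list(path, "anova"), "line")
})

test_that("score-to-p conversion uses the floored empirical rule", {
  edges <- data.frame(approach_id = "x", tf = "t", target = c("a", "b", "c"),
                      score = c(100, 0.5, -5), rank = 1:3)
  null <- seq(0, 1, length.out = 1000)
  out <- scores_to_pvalues(edges, null_scores = null)
  expect_equal(out$p_value[1], 1 / 1001)
  expect_equal(out$p_value[2], 0.5, tolerance = 2e-3)
  expect_equal(out$p_value[3], 1)
})

test_that("consensus combination follows the fixed-divisor averaging rule", {
  e1 <- data.frame(approach_id = "clr", tf = "t1", target = c("a", "b"),
                   score = 2:1, rank = 1:2, p_value = c(0.01, 0.001))
  e2 <- data.frame(approach_id = "tree", tf = "t1", target = "a",
                   score = 5, rank = 1, p_value = 0.01)
  e3 <- data.frame(approach_id = "anova", tf = "t1", target = "a",
                   score = 5, rank = 1, p_value = 0.01)
  out <- combine_rexp(list(e1, e2, e3))
  a <- out[out$target == "a", ]
  expect_equal(a$r_exp, 2)                       # three p = 0.01
  b <- out[out$target == "b", ]
  expect_equal(b$r_exp, 1)                       # 0.001 + two missing slots
  expect_false(any(out$target == "zzz"))         # never-listed edges absent
  ## two-approach support at p = 0.01 outranks one-approach support
  expect_gt(combine_rexp(list(e1, e2))[1, "r_exp"],
            combine_rexp(list(e1))[
              combine_rexp(list(e1))$target == "a", "r_exp"])
  ## single-approach input reduces to (1/3) * (-log10 p), order preserved
  solo <- combine_rexp(list(e1))
  expect_equal(solo$r_exp, -log10(c(0.001, 0.01)) / 3)
  expect_true(all(solo$r_exp >= 0))
})

test_that("precision-targeted thresholding picks the right prefix boundary", {
  gold <- gold_standard(data.frame(tf = "t", target = sprintf("g%03d", 1:220)))
  ## first 200 predictions correct, next 100 wrong
  edges <- data.frame(tf = "t",
                      target = c(sprintf("g%03d", 1:200),
                                 sprintf("bad%03d", 1:100)),
                      r_exp = seq(3, 1, length.out = 300))
  cut <- threshold_by_precision(edges, gold, target_precision = 0.95,
                                interval = 100)
  expect_equal(cut, edges$r_exp[200])
  ## all-correct predictions keep everything
  all_ok <- edges[1:200, ]
  expect_equal(threshold_by_precision(all_ok, gold, 0.95, 100),
               all_ok$r_exp[200])
  ## all-wrong predictions yield no cutoff
  all_bad <- edges[201:300, ]
  expect_true(is.na(threshold_by_precision(all_bad, gold, 0.95, 100)))
})
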