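mk_gold <- function(n_targets = 15, tf = "tfX") {
  gold_standard(data.frame(tf = tf, target = sprintf("t%03d", 1:n_targets)))
}

test_that("precision and recall follow the TP arithmetic", {
  gold <- mk_gold(15)
  preds <- data.frame(tf = "tfX",
                      target = c(sprintf("t%03d", 1:12), "wrong1"))
  expect_equal(precision(preds, gold), 12 / 13)
  expect_equal(recall(preds, gold), 12 / 15)
  all_in <- data.frame(tf = "tfX", target = sprintf("t%03d", 1:15))
  expect_equal(precision(all_in, gold), 1)
  expect_equal(recall(rbind(all_in,
                            data.frame(tf = "tfX", target = "extra")),
                      gold), 1)
  ## brute-force set arithmetic on random small sets
  set.seed(91)
  for (i in 1:10) {
    gset <- sample(letters, 8)
    pset <- sample(letters, 6)
    g <- gold_standard(data.frame(tf = "z", target = gset))
    p <- data.frame(tf = "z", target = pset)
    expect_equal(precision(p, g), length(intersect(pset, gset)) / 6)
    expect_equal(recall(p, g), length(intersect(pset, gset)) / 8)
  }
})

test_that("restricted precision discards TFs without experimental data", {
  gold <- gold_standard(data.frame(tf = c("a", "a", "b"),
                                   target = c("x", "y", "z")),
                        tfs_with_data = c("a", "b"))
  preds <- data.frame(tf = c("a", "a", "c", "c"),
                      target = c("x", "q", "r", "s"))
  expect_equal(restricted_precision(preds, gold), 1 / 2)
  expect_equal(precision(preds, gold), 1 / 4)
  only_unassayed <- data.frame(tf = "c", target = "r")
  expect_true(is.na(restricted_precision(only_unassayed, gold)))
  ## reduces to plain precision when every predicted TF is assayed
  p2 <- preds[preds$tf == "a", ]
  expect_equal(restricted_precision(p2, gold), precision(p2, gold))
})

test_that("PR curves are evaluated at fixed prediction intervals", {
  gold <- mk_gold(250)
  preds <- data.frame(tf = "tfX", target = sprintf("t%03d", 1:250))
  cur <- pr_curve(preds, gold, interval = 100)
  expect_equal(cur$n_predictions, c(100, 200, 250))
  expect_true(all(cur$precision == 1))
  expect_true(all(diff(cur$recall) > 0))
  ## constructed fixture: 200 correct then 100 wrong
  mixed <- data.frame(tf = "tfX", target = c(sprintf("t%03d", 1:200),
                                             sprintf("w%03d", 1:100)))
  cm <- pr_curve(mixed, gold, interval = 100)
  expect_equal(cm$precision, c(1, 1, 200 / 300))
  expect_equal(cm$recall, c(100 / 250, 200 / 250, 200 / 250))
})

test_that("AUPR integrates precision over recall with a left anchor", {
  flat <- structure(data.frame(n_predictions = c(10, 20),
                               precision = c(0.8, 0.8),
                               recall = c(0.3, 0.6)),
                    class = c("trn_pr", "data.frame"))
  expect_equal(aupr(flat), 0.8 * 0.6)
  two <- structure(data.frame(n_predictions = c(10, 20),
                              precision = c(1, 0.5),
                              recall = c(0.2, 0.4)),
                   class = c("trn_pr", "data.frame"))
  expect_equal(aupr(two), 1 * 0.2 + (1 + 0.5) / 2 * 0.2)
  set.seed(92)
  rnd <- structure(data.frame(n_predictions = 1:5,
                              precision = runif(5),
                              recall = sort(runif(5))),
                   class = c("trn_pr", "data.frame"))
  expect_gte(aupr(rnd), 0)
  expect_lte(aupr(rnd), 1)
})

test_that("per-TF reports use the NA / 0 / average conventions", {
  gold <- gold_standard(data.frame(tf = c("a", "a", "b", "c"),
                                   target = c("x", "y", "z", "w")))
  preds <- data.frame(tf = c("a", "a", "b"), target = c("x", "q", "nope"))
  rep <- per_tf_report(preds, gold)
  expect_equal(rep$precision_pct[rep$tf == "a"], 50)
  expect_equal(rep$precision_pct[rep$tf == "b"], 0)    # all wrong -> 0
  expect_true(is.na(rep$precision_pct[rep$tf == "c"])) # no predictions -> NA
  avg <- rep[rep$tf == "Average", ]
  expect_equal(avg$precision_pct, round_half_up(mean(c(50, 0)), 1))
})

test_that("the averaging convention reproduces the published benchmark row", {
  tab <- read.delim(system.file("extdata", "ecoli_tf_benchmark.tsv",
                                package = "trninfer"))
  expect_equal(sum(!is.na(tab$integrated_prec)), 33)
  expect_equal(report_average(tab$integrated_prec), 40.7)
  expect_equal(report_average(tab$integrated_rec), 28.6)
  expect_equal(report_average(tab$clr_prec), 23.2)
  expect_equal(report_average(tab$clr_rec), 12.5)
  expect_equal(report_average(tab$genie3_prec), 34.6)
  expect_equal(report_average(tab$genie3_rec), 14.6)
})
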