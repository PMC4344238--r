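#' Construct a gold standard of verified interactions
#'
#' @param interactions data frame with columns `tf`, `target` (or a
#'   two-column matrix/data frame).
#' @param tfs_with_data TFs for which experimental data exist; defaults to
#'   the TFs appearing in `interactions`.
#' @return an object of class `gold_standard`.
#' @export
gold_standard <- function(interactions, tfs_with_data = NULL) {
  df <- as.data.frame(interactions, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("tf", "target")
  if (is.null(tfs_with_data)) tfs_with_data <- unique(df$tf)
  stopifnot(all(df$tf %in% tfs_with_data))
  structure(list(interactions = unique(paste(df$tf, df$target, sep = "->")),
                 pairs = unique(df[, c("tf", "target")]),
                 tfs_with_data = unique(tfs_with_data)),
            class = "gold_standard")
}

#' Read a gold standard from TSV files
#' @param path interactions TSV (`tf`, `target`).
#' @param assayed_path optional one-column TSV of assayed TFs.
#' @return a `gold_standard`.
#' @export
read_gold_standard <- function(path, assayed_path = NULL) {
  df <- read_tsv(path)
  tfs <- if (!is.null(assayed_path)) read_tsv(assayed_path)[[1]] else NULL
  gold_standard(df, tfs)
}

pred_keys <- function(preds) {
  if (is.character(preds)) return(unique(preds))
  df <- as.data.frame(preds)
  unique(paste(df$tf, df$target, sep = "->"))
}

pred_tfs <- function(keys) vapply(strsplit(keys, "->", fixed = TRUE),
                                  `[`, "", 1)

#' Precision of a prediction set
#'
#' True positive predictions over all predictions made.
#'
#' @param preds predicted interactions: a data frame with `tf`, `target`
#'   columns or a character vector of `"tf->target"` keys.
#' @param gold a `gold_standard`.
#' @return precision in `[0, 1]`; `NA` for an empty prediction set.
#' @export
precision <- function(preds, gold) {
  keys <- pred_keys(preds)
  if (!length(keys)) return(NA_real_)
  sum(keys %in% gold$interactions) / length(keys)
}

#' Precision restricted to assayed TFs
#'
#' Precision computed after discarding predictions whose TF has no
#' experimental data in the gold standard; `NA` when no predictions
#' survive. Reduces to [precision()] when every predicted TF is assayed.
#'
#' @inheritParams precision
#' @return restricted precision or `NA`.
#' @export
restricted_precision <- function(preds, gold) {
  keys <- pred_keys(preds)
  keys <- keys[pred_tfs(keys) %in% gold$tfs_with_data]
  if (!length(keys)) return(NA_real_)
  sum(keys %in% gold$interactions) / length(keys)
}

#' Recall of a prediction set
#'
#' True positive predictions over all known true positives.
#'
#' @inheritParams precision
#' @return recall in `[0, 1]`.
#' @export
recall <- function(preds, gold) {
  stopifnot(length(gold$interactions) > 0)
  keys <- pred_keys(preds)
  sum(gold$interactions %in% keys) / length(gold$interactions)
}

#' Precision-recall curve at fixed prediction intervals
#'
#' Evaluates precision and recall on ranked-prefixes of `interval`
#' predictions (the final partial prefix included).
#'
#' @param ranked_preds ranked predictions (best first): data frame with
#'   `tf`, `target`.
#' @param gold a `gold_standard`.
#' @param interval prefix step (default 100).
#' @param restricted use [restricted_precision()] instead of [precision()].
#' @return a data frame of class `trn_pr` with `n_predictions`, `precision`,
#'   `recall`.
#' @export
pr_curve <- function(ranked_preds, gold, interval = 100, restricted = FALSE) {
  df <- as.data.frame(ranked_preds)
  n <- nrow(df)
  stops <- unique(c(seq(min(interval, n), n, by = interval), n))
  pf <- if (restricted) restricted_precision else precision
  out <- do.call(rbind, lapply(stops, function(s) {
    pre <- df[seq_len(s), , drop = FALSE]
    data.frame(n_predictions = s, precision = pf(pre, gold),
               recall = recall(pre, gold))
  }))
  class(out) <- c("trn_pr", "data.frame")
  out
}

#' @export
plot.trn_pr <- function(x, ...) {
  plot(x$recall, x$precision, type = "b", pch = 16,
       xlab = "Recall", ylab = "Precision",
       xlim = c(0, max(x$recall, 0.01)), ylim = c(0, 1), ...)
  invisible(x)
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integration over the recall axis, anchored on the left at
#' (recall 0, precision of the first point).
#'
#' @param curve a `trn_pr` data frame (>= 2 rows, or 1 row plus the anchor).
#' @return the area, in `[0, 1]`.
#' @export
aupr <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  keep <- !is.na(p)
  r <- r[keep]; p <- p[keep]
  if (length(r) < 2) return(NA_real_)
  sum(diff(r) * (head(p, -1) + p[-1]) / 2)
}

#' Per-TF precision/recall report
#'
#' One row per gold-standard TF with precision and recall in percent
#' (rounded half-up to one decimal). A TF with no predictions gets `NA`; a
#' TF whose predictions are all wrong gets 0. The bottom `Average` row is
#' the arithmetic mean over non-`NA` entries (zeros included).
#'
#' @param preds predicted interactions (data frame with `tf`, `target`).
#' @param gold a `gold_standard`.
#' @return data frame with `tf`, `n_predictions`, `precision_pct`,
#'   `recall_pct`; the final row is the Average.
#' @export
per_tf_report <- function(preds, gold) {
  keys <- pred_keys(preds)
  ptf <- pred_tfs(keys)
  rows <- lapply(sort(gold$tfs_with_data), function(tf) {
    pk <- keys[ptf == tf]
    gk <- gold$interactions[pred_tfs(gold$interactions) == tf]
    if (!length(pk))
      return(data.frame(tf = tf, n_predictions = 0L,
                        precision_pct = NA_real_, recall_pct = NA_real_))
    prec <- 100 * sum(pk %in% gk) / length(pk)
    rec <- if (length(gk)) 100 * sum(gk %in% pk) / length(gk) else NA_real_
    data.frame(tf = tf, n_predictions = length(pk),
               precision_pct = round_half_up(prec, 1),
               recall_pct = round_half_up(rec, 1))
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(tf = "Average", n_predictions = sum(out$n_predictions),
                    precision_pct = report_average(out$precision_pct),
                    recall_pct = report_average(out$recall_pct))
  rbind(out, avg)
}

#' Averaging convention for per-TF report columns
#'
#' Arithmetic mean over non-`NA` entries (zeros included), rounded half-up
#' to one decimal: `NA` marks TFs with no predictions and is excluded; 0
#' marks TFs whose predictions were all wrong and is included.
#'
#' @param x numeric vector of per-TF percentages with `NA`s.
#' @return the rounded average.
#' @export
report_average <- function(x) {
  round_half_up(mean(x[!is.na(x)]), 1)
}
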