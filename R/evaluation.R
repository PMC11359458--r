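#' Match detections to ground truth
#'
#' Greedy one-to-one matching by ascending detection-to-target distance:
#' pairs within `tol` pixels become true positives, each target and each
#' detection being used at most once. Duplicate detections near an
#' already-matched target therefore count as false positives, and a single
#' merged detection spanning several targets matches only the nearest one,
#' leaving the rest as false negatives. Unmatched detections are false
#' positives; unmatched targets false negatives.
#'
#' @param dets a [detection_set()].
#' @param truth ground-truth rows for the same frame (a [ground_truth()]
#'   table or any data frame with `row` and `col` columns).
#' @param tol matching tolerance in pixels (> 0).
#' @return a [confusion_counts()].
#' @export
match_detections <- function(dets, truth, tol = 3) {
  stopifnot(inherits(dets, "detection_set"))
  if (!(tol > 0)) stopf("tol must be > 0")
  truth <- as.data.frame(truth)
  nd <- nrow(dets$detections)
  nt <- nrow(truth)
  if (nd == 0L || nt == 0L) return(confusion_counts(0L, nd, nt))
  d <- outer(dets$detections$row, truth$row, "-")^2 +
    outer(dets$detections$col, truth$col, "-")^2
  d <- sqrt(d)
  tp <- 0L
  repeat {
    best <- which.min(d)
    if (length(best) == 0L || d[best] > tol) break
    i <- ((best - 1L) %% nd) + 1L
    j <- ((best - 1L) %/% nd) + 1L
    tp <- tp + 1L
    d[i, ] <- Inf
    d[, j] <- Inf
    if (all(is.infinite(d))) break
  }
  confusion_counts(tp, nd - tp, nt - tp)
}

#' Detection metrics: Precision, Recall, F-measure, TCR
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, `f_measure`
#' their harmonic mean, and `tcr = DT / (DT + MT + FA)`, the
#' target-to-clutter ratio that penalizes misses and false alarms in a
#' single score. Degenerate 0/0 cases of precision, recall and F-measure
#' return 0 (the conservative convention); `tcr` on all-zero counts is
#' undefined and raises an error, since its denominator vanishes only when
#' nothing exists and nothing was predicted.
#'
#' @param c a [confusion_counts()].
#' @return a value in `[0, 1]`.
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0L) return(0)
  c$tp / (c$tp + c$fp)
}

#' @rdname precision
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0L) return(0)
  c$tp / (c$tp + c$fn)
}

#' @rdname precision
#' @export
f_measure <- function(c) {
  p <- precision(c)
  r <- recall(c)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' @rdname precision
#' @export
tcr <- function(c) {
  denom <- c$dt + c$mt + c$fa
  if (denom == 0L) stopf("TCR undefined: DT + MT + FA = 0")
  c$dt / denom
}

#' Aggregate per-frame metrics into a mean (+/- sd) report
#'
#' Metrics are computed per frame first and then averaged; the spread is
#' the population standard deviation (denominator `n`). Input is a long
#' data frame with one row per `(frame, method)` as produced by
#' [run_benchmark()].
#'
#' @param per_frame data frame with columns `method`, `frame`, and one
#'   column per metric (`precision`, `recall`, `f_measure`, `tcr`).
#' @return a `metrics_report`: data frame with one row per method and
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
aggregate_metrics <- function(per_frame) {
  metrics <- intersect(c("precision", "recall", "f_measure", "tcr"), names(per_frame))
  if (length(metrics) == 0L || nrow(per_frame) == 0L) stopf("no metric columns to aggregate")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  methods <- unique(per_frame$method)
  out <- data.frame(method = methods)
  for (m in metrics) {
    vals <- lapply(methods, function(meth) per_frame[[m]][per_frame$method == meth])
    out[[paste0(m, "_mean")]] <- vapply(vals, mean, numeric(1))
    out[[paste0(m, "_sd")]] <- vapply(vals, pop_sd, numeric(1))
  }
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  metrics <- unique(sub("_(mean|sd)$", "", setdiff(names(x), "method")))
  cat(sprintf("%-12s", "method"))
  for (m in metrics) cat(sprintf("  %-18s", m))
  cat("\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-12s", x$method[i]))
    for (m in metrics) {
      cat(sprintf("  %.4f (+/-%.3f)  ", x[[paste0(m, "_mean")]][i], x[[paste0(m, "_sd")]][i]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Friedman rank test across matched frames
#'
#' Ranks the methods within every frame (rank 1 = best = highest score,
#' average ranks on ties), and tests the null hypothesis that all methods
#' perform equally with the tie-corrected Friedman chi-square statistic on
#' `k - 1` degrees of freedom.
#'
#' @param scores numeric matrix, frames in rows, methods in columns
#'   (column names label the methods).
#' @return a `friedman_ranks` object: list with `mean_ranks`, `statistic`,
#'   `df`, `p_value`, `n_blocks`, `k`, and the full `rank_matrix`.
#' @export
friedman_rank_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  if (n < 2L || k < 2L) stopf("need at least 2 frames and 2 methods")
  if (is.null(colnames(scores))) colnames(scores) <- paste0("method", seq_len(k))
  ranks <- t(apply(scores, 1L, function(row) rank(-row, ties.method = "average")))
  colnames(ranks) <- colnames(scores)
  rj <- colSums(ranks)
  # tie-corrected chi-square (reduces to the classic 12/(nk(k+1)) form
  # without ties)
  num <- (k - 1) * sum((rj - n * (k + 1) / 2)^2)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  stat <- if (den > 0) num / den else 0
  structure(list(mean_ranks = rj / n, statistic = stat, df = k - 1,
                 p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
                 n_blocks = n, k = k, rank_matrix = ranks),
            class = "friedman_ranks")
}

#' @export
print.friedman_ranks <- function(x, ...) {
  cat(sprintf("Friedman test: chi-square = %.4f, df = %d, p = %.4g (%d frames)\n",
              x$statistic, x$df, x$p_value, x$n_blocks))
  mr <- sort(x$mean_ranks)
  for (m in names(mr)) cat(sprintf("  %-12s %.3f\n", m, mr[[m]]))
  invisible(x)
}

#' Holm step-down adjustment of p-values
#'
#' Sorts the raw p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity and caps at 1; hypotheses with
#' adjusted p at or below `alpha` are rejected.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha significance level.
#' @return list with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
holm_adjust <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stopf("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvalues, method = "holm")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Pairwise post hoc comparisons after a Friedman test
#'
#' For every pair of methods, the standard Friedman rank-difference z
#' statistic
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{k(k+1)/(6N)}}
#' gives a two-sided normal p-value, and the whole family of
#' `k(k-1)/2` comparisons is Holm-adjusted.
#'
#' @param fr a [friedman_rank_test()] result.
#' @param alpha significance level.
#' @return a `rank_table` data frame with columns `method_i`, `method_j`,
#'   `z`, `p_value`, `p_holm`, `reject`, sorted by ascending `p_value`,
#'   with attribute `alpha`.
#' @export
pairwise_holm <- function(fr, alpha = 0.05) {
  stopifnot(inherits(fr, "friedman_ranks"))
  k <- fr$k
  se <- sqrt(k * (k + 1) / (6 * fr$n_blocks))
  pairs <- utils::combn(names(fr$mean_ranks), 2L)
  z <- (fr$mean_ranks[pairs[1L, ]] - fr$mean_ranks[pairs[2L, ]]) / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(method_i = pairs[1L, ], method_j = pairs[2L, ],
                    z = as.numeric(z), p_value = as.numeric(p))
  hh <- holm_adjust(out$p_value, alpha)
  out$p_holm <- hh$adjusted
  out$reject <- hh$reject
  out <- out[order(out$p_value, out$method_i, out$method_j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("rank_table", "data.frame")
  out
}
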