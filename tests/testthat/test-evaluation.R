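cc_of <- function(tp, fp, fn) confusion_counts(tp, fp, fn)

test_that("matching applies the one-detection-per-target rules", {
  tru <- data.frame(row = c(5, 20, 40), col = c(5, 20, 40))
  exact <- detection_set(0, "m", data.frame(row = tru$row, col = tru$col, area = 1))
  cc <- match_detections(exact, tru, 3)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(3, 0, 0))

  # duplicate detections near one target: extras become false alarms
  dup <- detection_set(0, "m", data.frame(row = c(5, 6), col = c(5, 6), area = 1))
  cc2 <- match_detections(dup, data.frame(row = 5, col = 5), 3)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(1, 1, 0))

  # one merged detection spanning two targets: one TP, the rest missed
  merged <- detection_set(0, "m", data.frame(row = 10, col = 11, area = 12))
  cc3 <- match_detections(merged, data.frame(row = c(10, 10), col = c(10, 13)), 3)
  expect_equal(c(cc3$tp, cc3$fp, cc3$fn), c(1, 0, 1))

  expect_error(match_detections(exact, tru, 0), "tol")
})

test_that("greedy matching attains the exhaustive optimum on separated instances", {
  set.seed(11)
  for (rep in 1:12) {
    nt <- sample(2:8, 1)
    tru <- data.frame(row = runif(nt, 0, 60), col = runif(nt, 0, 60))
    nd <- sample(0:8, 1)
    det <- data.frame(row = runif(nd, 0, 60), col = runif(nd, 0, 60),
                      area = rep(1, nd))
    got <- match_detections(detection_set(0, "m", det), tru, tol = 6)
    want_tp <- oracle_max_matching(det, tru, 6)
    expect_identical(got$tp, as.integer(want_tp))
    # conservation laws
    expect_identical(got$tp + got$fp, nrow(det))
    expect_identical(got$tp + got$fn, nt)
  }
})

test_that("precision, recall, F-measure and TCR follow their definitions", {
  c1 <- cc_of(1, 0, 0)
  expect_equal(c(precision(c1), recall(c1), f_measure(c1), tcr(c1)), c(1, 1, 1, 1))

  c2 <- cc_of(1, 0, 1)  # P = 1, R = 0.5
  expect_equal(f_measure(c2), 2 / 3)

  c3 <- cc_of(0, 0, 5)
  expect_equal(c(precision(c3), recall(c3), f_measure(c3)), c(0, 0, 0))
  expect_equal(tcr(c3), 0)

  expect_equal(tcr(cc_of(81, 0, 0)), 1)
  expect_equal(tcr(cc_of(0, 2, 3)), 0)
  expect_error(tcr(cc_of(0, 0, 0)), "undefined")

  set.seed(19)
  for (rep in 1:20) {
    cc <- cc_of(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    if (cc$tp + cc$fp + cc$fn == 0) next
    expect_lte(tcr(cc), min(precision(cc), recall(cc)) + 1e-12)
    expect_lte(f_measure(cc), 1)
    # swapping FP and FN swaps P and R, leaving F unchanged
    expect_equal(f_measure(cc_of(cc$tp, cc$fn, cc$fp)), f_measure(cc))
    # F = 1 iff P = R = 1
    expect_identical(f_measure(cc) == 1,
                     precision(cc) == 1 && recall(cc) == 1)
  }
})

test_that("aggregation averages per-frame metrics with population sd", {
  pf <- data.frame(method = "m", frame = 0, precision = 0.9, recall = 1,
                   f_measure = 0.95, tcr = 0.9)
  rep1 <- aggregate_metrics(pf)
  expect_equal(rep1$f_measure_mean, 0.95)
  expect_equal(rep1$f_measure_sd, 0)

  pf2 <- data.frame(method = "m", frame = 0:1, precision = 1, recall = 1,
                    f_measure = c(0.8, 1.0), tcr = 1)
  rep2 <- aggregate_metrics(pf2)
  expect_equal(rep2$f_measure_mean, 0.9)
  expect_equal(rep2$f_measure_sd, 0.1)

  # per-frame averaging: mean F need not equal the harmonic mean of mean P/R
  pf3 <- data.frame(method = "m", frame = 0:1,
                    precision = c(1, 0.8), recall = c(0.6, 1))
  pf3$f_measure <- 2 * pf3$precision * pf3$recall / (pf3$precision + pf3$recall)
  pf3$tcr <- 0.5
  rep3 <- aggregate_metrics(pf3)
  hm <- 2 * rep3$precision_mean * rep3$recall_mean /
    (rep3$precision_mean + rep3$recall_mean)
  expect_false(isTRUE(all.equal(rep3$f_measure_mean, hm)))
})

test_that("the Friedman test ranks methods and matches the closed form", {
  flat <- matrix(0.5, 6, 4)
  fr <- friedman_rank_test(flat)
  expect_true(all(fr$mean_ranks == 2.5))  # (k+1)/2 under full ties

  ordered <- matrix(rep(c(0.9, 0.6, 0.3), each = 4), 4, 3)
  colnames(ordered) <- c("A", "B", "C")
  fr2 <- friedman_rank_test(ordered)
  expect_equal(unname(fr2$mean_ranks), c(1, 2, 3))
  expect_equal(fr2$statistic, 8)  # 12*4/(3*4) * sum((Rj - 2)^2) = 8
  expect_equal(fr2$p_value, pchisq(8, 2, lower.tail = FALSE))

  # per-frame ranks always sum to k(k+1)/2
  set.seed(23)
  sc <- matrix(runif(40), 8, 5)
  fr3 <- friedman_rank_test(sc)
  expect_true(all(abs(rowSums(fr3$rank_matrix) - 15) < 1e-12))
  expect_error(friedman_rank_test(matrix(1, 1, 3)), "at least 2")
})

test_that("the Friedman statistic agrees with the reference implementation", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:12, 1); k <- sample(3:6, 1)
    sc <- matrix(runif(n * k), n, k)
    fr <- friedman_rank_test(sc)
    ref <- stats::friedman.test(sc)
    expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(fr$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
  # and under ties
  sc <- matrix(sample(1:3, 40, TRUE), 10, 4)
  expect_equal(friedman_rank_test(sc)$statistic,
               unname(stats::friedman.test(sc)$statistic), tolerance = 1e-9)
})

test_that("Holm adjustment is the step-down procedure", {
  expect_equal(holm_adjust(0.03)$adjusted, 0.03)

  hh <- holm_adjust(c(0.01, 0.04), alpha = 0.05)
  expect_equal(hh$adjusted, c(0.02, 0.04))
  expect_true(all(hh$reject))

  set.seed(5)
  for (rep in 1:10) {
    p <- runif(sample(3:10, 1))
    adj <- holm_adjust(p)$adjusted
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone after sorting
    expect_true(all(adj <= 1))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise post hoc comparisons cover every method pair", {
  set.seed(13)
  sc <- matrix(runif(25 * 8), 25, 8)
  colnames(sc) <- paste0("m", 1:8)
  fr <- friedman_rank_test(sc)
  tab <- pairwise_holm(fr, alpha = 0.05)
  expect_equal(nrow(tab), 28)  # 8 choose 2
  expect_true(all(tab$p_holm >= tab$p_value))
  se <- sqrt(8 * 9 / (6 * 25))
  i <- which(tab$method_i == "m1" & tab$method_j == "m2" |
               tab$method_i == "m2" & tab$method_j == "m1")
  expect_equal(abs(tab$z[i]), abs(fr$mean_ranks[["m1"]] - fr$mean_ranks[["m2"]]) / se)
})
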