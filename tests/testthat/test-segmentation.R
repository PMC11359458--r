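# exhaustive enumeration of contiguous k-partitions of the sorted values;
# in one dimension the optimal clustering is contiguous, so this is a
# global-optimum oracle
oracle_kmeans_sse <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  sse_range <- function(i, j) {
    x <- v[i:j]
    sum((x - mean(x))^2)
  }
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  for (cut in cuts) {
    bounds <- c(0, cut, n)
    s <- sum(vapply(seq_len(k), function(g) sse_range(bounds[g] + 1, bounds[g + 1]),
                    numeric(1)))
    best <- min(best, s)
  }
  best
}

test_that("k-means reaches the global 1-D optimum on small inputs", {
  m <- kmeans_fit(c(0, 0, 0, 255, 255, 255), k = 2, seed = 1)
  expect_equal(m$centers, c(0, 255))
  expect_equal(m$sse, 0)

  m1 <- kmeans_fit(c(3, 7, 100, 40), k = 1, seed = 1)
  expect_equal(m1$centers, mean(c(3, 7, 100, 40)))

  vals <- c(0, 40, 50, 90, 200, 210)
  m3 <- kmeans_fit(vals, k = 3, seed = 2, restarts = 20)
  expect_equal(m3$sse, oracle_kmeans_sse(vals, 3), tolerance = 1e-9)
})

test_that("k-means enforces the partition invariants and is deterministic", {
  set.seed(10)
  vals <- sample(0:255, 400, replace = TRUE)
  m <- kmeans_fit(vals, k = 3, seed = 5)
  expect_length(m$labels, length(vals))
  expect_true(all(m$labels %in% 1:3))
  expect_true(all(tabulate(m$labels, 3) > 0))              # non-empty clusters
  d <- abs(outer(vals, m$centers, "-"))
  expect_equal(m$labels, max.col(-d, ties.method = "first"))  # nearest center
  m2 <- kmeans_fit(vals, k = 3, seed = 5)
  expect_identical(m, m2)                                   # fixed seed, same model

  expect_error(kmeans_fit(rep(7, 10), k = 3), "degenerate")
  expect_error(kmeans_fit(1:10, k = 0), "positive")
})

test_that("k-means detection isolates the brightest cluster", {
  f <- three_level_frame()
  mask <- kmeans_detect(f, k = 3, seed = 0)
  expect_identical(unclass(mask) == 255, unclass(f) == 250)
  expect_error(kmeans_detect(gray_frame(matrix(9, 4, 4))), "degenerate")
})

test_that("Otsu's threshold equals the exhaustive inter-class variance argmax", {
  # independent scalar evaluation of the variance formula for every T
  oracle_otsu <- function(m) {
    m <- unclass(m)
    n <- length(m)
    h <- tabulate(as.vector(m) + 1, 256)
    v <- numeric(256)
    for (T in 0:255) {
      p0 <- sum(h[seq_len(T)]) / n          # intensities < T
      p1 <- 1 - p0
      if (p0 > 0 && p1 > 0) {
        m0 <- sum((0:(T - 1)) * h[seq_len(T)]) / (n * p0)
        m1 <- sum((T:255) * h[(T + 1):256]) / (n * p1)
        v[T + 1] <- p0 * p1 * (m0 - m1)^2
      }
    }
    list(threshold = as.integer(which.max(v) - 1), curve = v)
  }

  f <- gray_frame(matrix(c(0, 0, 0, 0, 200, 200, 255, 255), 2, 4))
  res <- otsu_threshold(f)
  orc <- oracle_otsu(f)
  expect_identical(res$threshold, orc$threshold)
  expect_equal(unname(res$variance_curve), orc$curve, tolerance = 1e-12)

  for (seed in 1:5) {
    f <- rand_frame(8, 8, seed)
    res <- otsu_threshold(f)
    orc <- oracle_otsu(f)
    expect_identical(res$threshold, orc$threshold)
    expect_equal(unname(res$variance_curve), orc$curve, tolerance = 1e-9)
  }
})

test_that("Otsu histogram bookkeeping and tie-breaking behave", {
  f <- gray_frame(matrix(c(rep(0, 8), rep(255, 8)), 4, 4))
  res <- otsu_threshold(f)
  expect_identical(res$threshold, 1L)  # flat maximal curve, smallest T wins
  expect_equal(max(res$variance_curve), res$variance_curve[["1"]])

  f2 <- rand_frame(12, 9, 42)
  res2 <- otsu_threshold(f2)
  expect_equal(sum(res2$histogram), 12 * 9)
  expect_true(all(diff(res2$cdf) >= 0))
  expect_equal(res2$cdf[256], 1, tolerance = 1e-12)
  # inter-class variance never exceeds the global intensity variance
  global_var <- mean((unclass(f2) - mean(unclass(f2)))^2)
  expect_true(all(res2$variance_curve <= global_var + 1e-9))

  expect_error(otsu_threshold(gray_frame(matrix(7, 3, 3))), "degenerate")
})

test_that("Otsu detection keeps every pixel at or above the threshold", {
  f <- gray_frame(matrix(c(rep(10, 12), rep(240, 4)), 4, 4))
  mask <- otsu_detect(f)
  expect_identical(unclass(mask) == 255, unclass(f) == 240)

  f2 <- three_level_frame()
  res <- otsu_threshold(f2)
  mask2 <- otsu_detect(f2)
  expect_true(all(unclass(mask2) %in% c(0, 255)))
  expect_equal(sum(unclass(mask2) == 255),
               sum(res$histogram[(res$threshold + 1):256]))
  # foreground is a superset of the colloid pixels
  expect_true(all(unclass(mask2)[unclass(f2) == 250] == 255))
})
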