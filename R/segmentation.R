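#' Lloyd's k-means on a one-dimensional set of intensities
#'
#' Clusters pixel intensities into `k` groups by iterating nearest-center
#' assignment and center recomputation until the largest center movement
#' falls below `epsilon`. Initial centers are `k` distinct values sampled
#' uniformly without replacement; the fit is repeated `restarts` times and
#' the model with the lowest within-cluster sum of squares (SSE) is
#' returned. Because the feature is one-dimensional and 8-bit, the
#' computation collapses the input to unique values with multiplicities,
#' which is exact and makes the cost independent of image size.
#'
#' @param values numeric vector of intensities (any length).
#' @param k number of clusters; must not exceed the number of distinct
#'   values.
#' @param epsilon convergence tolerance on the maximum center movement.
#' @param seed optional RNG seed for reproducible initialization.
#' @param restarts number of random restarts.
#' @param max_iter iteration cap per restart.
#' @return a `cluster_model`: list with `k`, `centers` (sorted ascending),
#'   `labels` (per-input cluster index into `centers`), `sse`, and
#'   `iterations`.
#' @examples
#' m <- kmeans_fit(c(0, 0, 0, 255, 255, 255), k = 2, seed = 1)
#' m$centers
#' @export
kmeans_fit <- function(values, k, epsilon = 1e-4, seed = NULL, restarts = 10,
                       max_iter = 300) {
  values <- as.numeric(values)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (epsilon <= 0) stopf("epsilon must be > 0")
  uv <- sort(unique(values))
  if (length(uv) < k) {
    stopf("degenerate input: %d distinct values < k = %d", length(uv), k)
  }
  w <- tabulate(match(values, uv), nbins = length(uv))
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- sort(sample(uv, k))
    iter <- 0L
    repeat {
      iter <- iter + 1L
      lab <- assign_nearest(uv, centers)
      # empty-cluster repair: re-seed at the point farthest from its center
      for (j in seq_len(k)) {
        if (!any(lab == j)) {
          d <- abs(uv - centers[lab])
          centers[j] <- uv[which.max(d)]
          lab <- assign_nearest(uv, centers)
        }
      }
      newc <- vapply(seq_len(k), function(j) {
        sel <- lab == j
        sum(uv[sel] * w[sel]) / sum(w[sel])
      }, numeric(1))
      moved <- max(abs(newc - centers))
      centers <- newc
      if (moved < epsilon || iter >= max_iter) break
    }
    lab <- assign_nearest(uv, centers)
    sse <- sum(w * (uv - centers[lab])^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(centers = centers, sse = sse, iterations = iter)
    }
  }

  ord <- order(best$centers)
  centers <- best$centers[ord]
  lab_uv <- order(ord)[assign_nearest(uv, best$centers)]
  structure(list(k = k, centers = centers, labels = lab_uv[match(values, uv)],
                 sse = best$sse, iterations = best$iterations),
            class = "cluster_model")
}

# nearest center, ties broken by the lowest cluster index
assign_nearest <- function(v, centers) {
  d <- abs(outer(v, centers, "-"))
  max.col(-d, ties.method = "first")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, centers (%s), sse=%.4g\n",
              x$k, paste(sprintf("%.2f", x$centers), collapse = ", "), x$sse))
  invisible(x)
}

#' Detect colloids by k-means intensity clustering
#'
#' Clusters the pixel intensities of one frame into `k` groups (default 3,
#' one per micromodel region: solid grains, pore space, colloids) and
#' declares the cluster with the highest center the colloid cluster: in
#' fluorescence micromodel imagery the colloids are the brightest objects.
#'
#' @param frame a [gray_frame()].
#' @param k number of intensity clusters.
#' @param seed RNG seed for the clustering initialization.
#' @param restarts passed to [kmeans_fit()].
#' @return a [binary_mask()] that is 255 exactly on the pixels of the
#'   highest-center cluster.
#' @export
kmeans_detect <- function(frame, k = 3, seed = NULL, restarts = 10) {
  m <- px(frame)
  fit <- kmeans_fit(as.vector(m), k = k, seed = seed, restarts = restarts)
  top <- which.max(fit$centers)
  binary_mask(matrix(ifelse(fit$labels == top, 255, 0), nrow(m), ncol(m)))
}

#' Otsu's threshold: exhaustive inter-class variance maximization
#'
#' Computes the 256-bin histogram `H`, its normalized CDF `C`, the global
#' mean, and for every threshold `T` in `0..255` the inter-class variance
#' \deqn{Var(T) = P_0(T) P_1(T) (m_0(T) - m_1(T))^2,}
#' where class 0 holds intensities `< T` and class 1 intensities `>= T`.
#' Thresholds with an empty class get `Var = 0`. The optimum is the
#' smallest `T` maximizing `Var(T)`.
#'
#' @param frame a [gray_frame()] with at least two distinct intensities.
#' @return an `otsu_result`: list with `threshold`, `variance_curve`
#'   (length 256, named "0".."255"), `histogram`, `cdf`, and `mean`.
#' @export
otsu_threshold <- function(frame) {
  m <- px(frame)
  h <- tabulate(as.vector(m) + 1L, nbins = 256L)
  n <- sum(h)
  if (sum(h > 0L) < 2L) stopf("degenerate input: frame has fewer than 2 distinct intensities")
  lev <- 0:255
  cdf <- cumsum(h) / n
  mu <- sum(lev * h) / n
  # P0(T) = mass strictly below T; cumulative sums give all 256 thresholds
  p0 <- c(0, cdf[-256L])
  s0 <- c(0, cumsum(lev * h)[-256L]) / n
  p1 <- 1 - p0
  m0 <- ifelse(p0 > 0, s0 / p0, 0)
  m1 <- ifelse(p1 > 0, (mu - s0) / p1, 0)
  v <- ifelse(p0 * p1 > 0, p0 * p1 * (m0 - m1)^2, 0)
  names(v) <- lev
  structure(list(threshold = lev[which.max(v)], variance_curve = v,
                 histogram = h, cdf = cdf, mean = mu),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> T_opt=%d, mean=%.2f, max Var=%.4g\n",
              x$threshold, x$mean, max(x$variance_curve)))
  invisible(x)
}

#' Detect colloids by Otsu thresholding
#'
#' Binarizes the frame at the optimal inter-class variance threshold;
#' pixels with intensity `>= T_opt` become foreground (so intensities
#' sitting exactly at the threshold are kept with the bright class).
#'
#' @param frame a [gray_frame()].
#' @return a [binary_mask()].
#' @export
otsu_detect <- function(frame) {
  t_opt <- otsu_threshold(frame)$threshold
  binary_mask((px(frame) >= t_opt) * 255)
}
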