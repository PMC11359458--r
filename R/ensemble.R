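#' Object-level majority vote across three detectors
#'
#' The ensemble's decision rule: a colloid is reported when at least two of
#' the three constituent detectors found it. Detections from the three
#' input sets are greedily clustered across methods -- repeatedly take the
#' unclustered cross-method pair with the smallest centroid distance within
#' `vote_radius`, then grow the cluster with the nearest detection of the
#' remaining third method within `vote_radius` of the cluster centroid.
#' Every cluster supported by >= 2 methods is emitted as one fused
#' detection (unweighted mean of the member centroids, summed area);
#' singletons are dropped, i.e. "not to detect" wins the 2-to-1 vote. Ties
#' are broken by distance, then method name, then centroid position, which
#' makes the output invariant to the order of the input sets.
#'
#' @param sets list of exactly 3 [detection_set()]s sharing one frame
#'   index.
#' @param vote_radius maximum centroid distance (pixels) for two
#'   detections to count as the same colloid.
#' @return a [detection_set()] with method `"ensemble"`.
#' @export
majority_vote <- function(sets, vote_radius = 5) {
  if (!is.list(sets) || length(sets) != 3L) stopf("majority_vote needs exactly 3 detection sets")
  for (s in sets) stopifnot(inherits(s, "detection_set"))
  fi <- unique(vapply(sets, function(s) s$frame_index, integer(1)))
  if (length(fi) != 1L) stopf("detection sets must share one frame index")
  if (!(vote_radius > 0)) stopf("vote_radius must be > 0")

  cand <- do.call(rbind, lapply(sets, function(s) {
    if (nrow(s$detections) == 0L) return(NULL)
    data.frame(method = s$method, s$detections)
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(detection_set(fi, "ensemble"))
  # canonical ordering so the greedy pass is permutation-invariant
  cand <- cand[order(cand$method, cand$row, cand$col), , drop = FALSE]
  n <- nrow(cand)
  d <- as.matrix(stats::dist(cand[, c("row", "col")]))
  cross <- outer(cand$method, cand$method, "!=")
  free <- rep(TRUE, n)
  clusters <- list()

  repeat {
    ok <- cross & outer(free, free, "&") & d <= vote_radius
    ok[lower.tri(ok, diag = TRUE)] <- FALSE
    if (!any(ok)) break
    hits <- which(ok, arr.ind = TRUE)
    best <- hits[order(d[hits], hits[, 1L], hits[, 2L])[1L], ]
    members <- as.integer(best)
    free[members] <- FALSE
    # a third-method member within vote_radius of the pair's centroid
    third <- free & !(cand$method %in% cand$method[members])
    if (any(third)) {
      cen <- colMeans(cand[members, c("row", "col")])
      d3 <- sqrt((cand$row - cen[1L])^2 + (cand$col - cen[2L])^2)
      d3[!third] <- Inf
      if (min(d3) <= vote_radius) {
        add <- which.min(d3)
        members <- c(members, add)
        free[add] <- FALSE
      }
    }
    clusters[[length(clusters) + 1L]] <- members
  }

  if (length(clusters) == 0L) return(detection_set(fi, "ensemble"))
  fused <- do.call(rbind, lapply(clusters, function(ix) {
    data.frame(row = mean(cand$row[ix]), col = mean(cand$col[ix]),
               area = sum(cand$area[ix]), support = length(ix))
  }))
  fused <- fused[fused$support >= 2L, c("row", "col", "area"), drop = FALSE]
  fused <- fused[order(fused$row, fused$col), , drop = FALSE]
  detection_set(fi, "ensemble", fused)
}

#' Pixel-level majority vote across three masks
#'
#' The alternative voting mode: a pixel is foreground when at least two of
#' the three detector masks mark it.
#'
#' @param masks list of exactly 3 [binary_mask()]s of one shape.
#' @return a [binary_mask()].
#' @export
majority_vote_pixel <- function(masks) {
  if (!is.list(masks) || length(masks) != 3L) stopf("majority_vote_pixel needs exactly 3 masks")
  ms <- lapply(masks, function(m) px(m) == 255)
  if (!all(dim(ms[[1L]]) == dim(ms[[2L]])) || !all(dim(ms[[2L]]) == dim(ms[[3L]]))) {
    stopf("mask shape mismatch")
  }
  votes <- ms[[1L]] + ms[[2L]] + ms[[3L]]
  binary_mask((votes >= 2L) * 255)
}
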