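#' Detector parameter defaults for benchmark runs
#'
#' One flat list mirroring the configuration keys of every detector, with
#' the defaults used throughout: `k = 3` intensity clusters, motion
#' threshold 25, Laplacian response threshold 40, DoG `sigma1 = 0.5`,
#' `sigma2 = 2` on a 3x3 support with response threshold 10, dilation and
#' top-hat disk radii 4 and 2 with Otsu post-binarization, component areas
#' 1--200 px under 8-connectivity, and an object-level majority vote of
#' top-hat, DoG and k-means within a 5 px radius.
#'
#' @param ... named overrides of any default.
#' @return a named list of parameters.
#' @export
benchmark_params <- function(...) {
  p <- list(
    motion_threshold = 25,
    kmeans_k = 3, kmeans_seed = 0, kmeans_restarts = 10,
    laplacian_threshold = 40,
    dog_sigma1 = 0.5, dog_sigma2 = 2, dog_size = 3, dog_threshold = 10,
    dilation_radius = 4, tophat_radius = 2, post_threshold = "otsu",
    min_area = 1, max_area = 200, connectivity = 8,
    vote_radius = 5, ensemble_methods = c("tophat", "dog", "kmeans")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L) stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Names of the available single detectors
#' @return character vector of method names.
#' @export
detector_methods <- function() {
  c("kmeans", "otsu", "fdbs", "mfd", "laplacian", "dog", "dilation", "tophat")
}

#' Run one detector on one frame of a sequence
#'
#' Dispatches by method name. Motion-based methods (`fd2`, `fd3`, `fdbs`,
#' `mfd`) need neighbouring frames and return `NULL` on boundary frames
#' instead of padding; `fdbs` additionally needs a background model.
#'
#' @param seq a [frame_sequence()].
#' @param index 0-based frame index.
#' @param method one of [detector_methods()] plus `"fd2"`, `"fd3"`.
#' @param params a [benchmark_params()] list.
#' @param bg a [build_background()] model (required for `"fdbs"`).
#' @return a [binary_mask()], or `NULL` for a boundary frame of a motion
#'   method.
#' @export
detect_frame <- function(seq, index, method, params = benchmark_params(), bg = NULL) {
  f <- get_frame(seq, index)
  n <- length(seq)
  first <- index == 0L
  last <- index == n - 1L
  switch(method,
    kmeans = kmeans_detect(f, k = params$kmeans_k,
                           seed = params$kmeans_seed + index,
                           restarts = params$kmeans_restarts),
    otsu = otsu_detect(f),
    fd2 = if (first) NULL else
      two_frame_diff(f, get_frame(seq, index - 1L), params$motion_threshold),
    fd3 = if (first || last) NULL else
      three_frame_diff(get_frame(seq, index - 1L), f, get_frame(seq, index + 1L),
                       params$motion_threshold),
    fdbs = {
      if (is.null(bg)) stopf("fdbs needs a background model")
      if (first) NULL else
        fdbs_detect(f, get_frame(seq, index - 1L), bg, params$motion_threshold)
    },
    mfd = if (first || last) NULL else
      mfd_detect(get_frame(seq, index - 1L), f, get_frame(seq, index + 1L),
                 params$motion_threshold),
    laplacian = laplacian_detect(f, params$laplacian_threshold),
    dog = dog_detect(f, params$dog_sigma1, params$dog_sigma2, params$dog_size,
                     params$dog_threshold),
    dilation = dilation_detect(f, params$dilation_radius, params$post_threshold),
    tophat = tophat_detect(f, params$tophat_radius, params$post_threshold),
    stopf("unknown method '%s'", method)
  )
}

#' Benchmark detectors on a sequence with ground truth
#'
#' Runs every requested detector over the interior frames of the sequence
#' (frames with both neighbours, so motion methods are comparable with the
#' rest), extracts object-level detections, matches them to ground truth,
#' and aggregates per-frame Precision / Recall / F-measure / TCR into a
#' mean (+/- sd) report. When at least two single methods are present, the
#' per-frame F-measures additionally feed a Friedman rank test and a
#' Holm-adjusted table of all pairwise comparisons; the ensemble row is
#' excluded from the ranking. The run is deterministic given the
#' parameters.
#'
#' @param scene a `colloid_scene` from [generate_scene()], or a
#'   [frame_sequence()] (then `truth` is required).
#' @param truth a [ground_truth()] table (taken from `scene` if omitted).
#' @param methods detector names; `"ensemble"` adds the majority vote of
#'   `params$ensemble_methods`.
#' @param params a [benchmark_params()] list.
#' @param tol ground-truth matching tolerance in pixels.
#' @param alpha significance level of the post hoc table.
#' @return a `colloid_benchmark`: list with `metrics` (the
#'   [aggregate_metrics()] report), `per_frame` (long data frame),
#'   `friedman`, `holm`, `frames_evaluated`, `params`, `tol`.
#' @export
run_benchmark <- function(scene, truth = NULL,
                          methods = c(detector_methods(), "ensemble"),
                          params = benchmark_params(), tol = 3, alpha = 0.05) {
  if (inherits(scene, "colloid_scene")) {
    seq <- scene$frames
    if (is.null(truth)) truth <- scene$truth
  } else {
    seq <- scene
  }
  stopifnot(inherits(seq, "frame_sequence"))
  if (is.null(truth)) stopf("ground truth is required")
  n <- length(seq)
  if (n < 3L) stopf("benchmark needs at least 3 frames")
  eval_frames <- seq_len(n - 2L)  # 0-based interior: 1 .. n-2
  # a frame with zero colloids legitimately has no truth rows, but a truth
  # table that stops short of the evaluated range is an input error
  if (nrow(truth) > 0L && max(eval_frames) > max(truth$frame)) {
    stopf("ground truth covers frames up to %d but frame %d is evaluated",
          max(truth$frame), max(eval_frames))
  }

  single <- setdiff(methods, "ensemble")
  ens_needed <- "ensemble" %in% methods
  ens_members <- params$ensemble_methods
  if (ens_needed && length(ens_members) != 3L) stopf("ensemble needs exactly 3 methods")
  run_methods <- union(single, if (ens_needed) ens_members else character(0))
  bg <- if ("fdbs" %in% run_methods) build_background(seq) else NULL

  rows <- list()
  for (i in eval_frames) {
    tf <- truth_frame(truth, i)
    dets <- list()
    for (m in run_methods) {
      mask <- detect_frame(seq, i, m, params, bg)
      if (is.null(mask)) next
      dets[[m]] <- extract_detections(mask, i, m, params$min_area, params$max_area,
                                      params$connectivity)
    }
    if (ens_needed) {
      dets$ensemble <- majority_vote(dets[ens_members], params$vote_radius)
    }
    for (m in intersect(c(single, if (ens_needed) "ensemble"), names(dets))) {
      cc <- match_detections(dets[[m]], tf, tol)
      total <- cc$tp + cc$fp + cc$fn
      rows[[length(rows) + 1L]] <- data.frame(
        frame = i, method = m, tp = cc$tp, fp = cc$fp, fn = cc$fn,
        precision = precision(cc), recall = recall(cc), f_measure = f_measure(cc),
        tcr = if (total > 0L) tcr(cc) else NA_real_
      )
    }
  }
  per_frame <- do.call(rbind, rows)
  metrics <- aggregate_metrics(per_frame)
  metrics <- metrics[match(intersect(c(single, "ensemble"), metrics$method),
                           metrics$method), , drop = FALSE]
  rownames(metrics) <- NULL

  friedman <- NULL
  holm <- NULL
  rank_single <- intersect(single, unique(per_frame$method))
  if (length(rank_single) >= 2L) {
    fmat <- sapply(rank_single, function(m) {
      per_frame$f_measure[per_frame$method == m][order(per_frame$frame[per_frame$method == m])]
    })
    friedman <- friedman_rank_test(fmat)
    holm <- pairwise_holm(friedman, alpha)
  }

  structure(list(metrics = metrics, per_frame = per_frame, friedman = friedman,
                 holm = holm, frames_evaluated = eval_frames, params = params,
                 tol = tol),
            class = "colloid_benchmark")
}

#' @export
print.colloid_benchmark <- function(x, ...) {
  cat(sprintf("Colloid detection benchmark over %d frames (matching tol %g px)\n\n",
              length(x$frames_evaluated), x$tol))
  print(x$metrics)
  if (!is.null(x$friedman)) {
    cat("\n")
    print(x$friedman)
  }
  invisible(x)
}

#' Write benchmark reports to a directory
#'
#' Emits `metrics.csv` (mean +/- sd per method), `per_frame.csv`,
#' `ranks.csv` and `holm.csv` (when a ranking was computed), and a plain
#' text `report.txt` mirroring the printed tables.
#'
#' @param bm a [run_benchmark()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bm, dir) {
  stopifnot(inherits(bm, "colloid_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(bm$metrics), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(bm$per_frame, file.path(dir, "per_frame.csv"), row.names = FALSE)
  if (!is.null(bm$friedman)) {
    utils::write.csv(data.frame(method = names(bm$friedman$mean_ranks),
                                mean_rank = as.numeric(bm$friedman$mean_ranks)),
                     file.path(dir, "ranks.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(bm$holm), file.path(dir, "holm.csv"),
                     row.names = FALSE)
  }
  txt <- utils::capture.output(print(bm))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
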