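#' Two-frame differencing
#'
#' Marks a pixel foreground when the absolute intensity difference between
#' the current and previous frame strictly exceeds the motion threshold
#' `T`. The threshold suppresses sensor noise at the cost of missing slow
#' targets.
#'
#' @param fn current frame.
#' @param fprev previous frame.
#' @param T motion threshold (>= 0); strict inequality.
#' @return a [binary_mask()].
#' @export
two_frame_diff <- function(fn, fprev, T = 25) {
  check_same_shape(fn, fprev)
  if (T < 0) stopf("motion threshold must be >= 0")
  binary_mask((abs(px(fn) - px(fprev)) > T) * 255)
}

#' Three-frame differencing
#'
#' The logical AND of two successive two-frame differences: foreground
#' where the center frame differs from both its predecessor and successor.
#'
#' @param fprev,fn,fnext three consecutive frames.
#' @param T motion threshold.
#' @return a [binary_mask()].
#' @export
three_frame_diff <- function(fprev, fn, fnext, T = 25) {
  check_same_shape(fprev, fn)
  check_same_shape(fn, fnext)
  d1 <- abs(px(fn) - px(fprev)) > T
  d2 <- abs(px(fnext) - px(fn)) > T
  binary_mask((d1 & d2) * 255)
}

#' Temporal-median background model
#'
#' With a fixed camera and static grain geometry, the per-pixel temporal
#' median over the sequence recovers the background: a moving colloid
#' occupies any one pixel in only a few frames, so the median ignores it,
#' while permanently attached colloids become part of the background (which
#' is exactly why motion-based detectors cannot see them).
#'
#' @param seq a [frame_sequence()] with at least 3 frames.
#' @return a `background_model`: list with `pixels` (intensity matrix,
#'   rounded to integers) and `source_frames` (0-based indices used).
#' @export
build_background <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (length(seq) < 3L) stopf("background model needs at least 3 frames")
  arr <- vapply(seq$frames, px, matrix(0, seq$height, seq$width))
  med <- apply(arr, c(1L, 2L), stats::median)
  structure(list(pixels = round(med), source_frames = seq_len(length(seq)) - 1L),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %d x %d px from %d frames\n",
              nrow(x$pixels), ncol(x$pixels), length(x$source_frames)))
  invisible(x)
}

#' Frame differencing plus background subtraction (FDBS)
#'
#' Conjoins two motion cues: `C`, the two-frame difference between the
#' current frame `A` and the previous frame `B`, and `D`, the difference of
#' `A` against a static background model. The AND keeps only pixels that
#' both changed since the last frame and differ from the background, which
#' suppresses the trailing "ghost" at the particle's previous position.
#'
#' @param A current frame.
#' @param B previous frame.
#' @param bg a [build_background()] model (or an intensity matrix).
#' @param T motion threshold.
#' @return a [binary_mask()].
#' @export
fdbs_detect <- function(A, B, bg, T = 25) {
  bgm <- if (inherits(bg, "background_model")) bg$pixels else as.matrix(bg)
  check_same_shape(A, B)
  if (!all(dim(bgm) == dim(px(A)))) stopf("background shape mismatch")
  C <- abs(px(A) - px(B)) > T
  D <- abs(px(A) - bgm) > T
  binary_mask((C & D) * 255)
}

#' Multi-frame differencing (MFD)
#'
#' Averages the three absolute pairwise differences of a consecutive frame
#' triplet and binarizes the mean response at the motion threshold
#' (strictly greater). Averaging reinforces consistent motion but also
#' leaves responses at the particle's previous and next positions, making
#' this the noisiest of the motion detectors.
#'
#' @param fprev,ft,fnext three consecutive frames.
#' @param T motion threshold.
#' @return a [binary_mask()].
#' @export
mfd_detect <- function(fprev, ft, fnext, T = 25) {
  check_same_shape(fprev, ft)
  check_same_shape(ft, fnext)
  dt1 <- abs(px(ft) - px(fprev))
  dt2 <- abs(px(fnext) - px(fprev))
  dt3 <- abs(px(fnext) - px(ft))
  fd <- (dt1 + dt2 + dt3) / 3
  binary_mask((fd > T) * 255)
}

check_same_shape <- function(a, b) {
  if (!all(dim(px(a)) == dim(px(b)))) stopf("frame shape mismatch")
  invisible(TRUE)
}
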