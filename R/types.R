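#' Construct a grayscale frame
#'
#' A `gray_frame` is a 2-D grid of 8-bit intensities (integers in
#' `[0, 255]`) with an optional 0-based frame index recording its position
#' within a sequence. It is stored as a plain numeric matrix carrying the
#' class attribute, so all matrix operations apply.
#'
#' @param pixels numeric matrix of intensities; every value must be an
#'   integer in `[0, 255]`.
#' @param index 0-based frame number within a sequence.
#' @return a `gray_frame` object.
#' @examples
#' f <- gray_frame(matrix(0:255, 16, 16))
#' dim(f)
#' @export
gray_frame <- function(pixels, index = 0L) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stopf("frame pixels must be numeric")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stopf("frame must be at least 1x1")
  if (anyNA(pixels)) stopf("frame contains missing values")
  if (any(pixels < 0 | pixels > 255)) stopf("intensities must lie in [0, 255]")
  if (any(pixels != round(pixels))) stopf("intensities must be integers")
  structure(pixels, class = "gray_frame", index = as.integer(index))
}

#' @export
print.gray_frame <- function(x, ...) {
  cat(sprintf("<gray_frame> %d x %d px, frame %d, intensities [%d, %d]\n",
              nrow(x), ncol(x), frame_index(x), min(x), max(x)))
  invisible(x)
}

#' Frame index of a frame or detection set
#'
#' @param x a `gray_frame` or `detection_set`.
#' @return the 0-based frame index.
#' @export
frame_index <- function(x) {
  if (inherits(x, "detection_set")) return(x$frame_index)
  idx <- attr(x, "index")
  if (is.null(idx)) 0L else idx
}

# strip class/attrs for raw matrix arithmetic
px <- function(x) {
  x <- unclass(x)
  attr(x, "index") <- NULL
  x
}

#' Construct a binary mask
#'
#' The raw output of every detector: a matrix over exactly `{0, 255}` with
#' 255 marking foreground (candidate colloid) pixels.
#'
#' @param pixels numeric matrix with values 0 or 255.
#' @return a `binary_mask` object.
#' @export
binary_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (is.logical(pixels)) pixels <- pixels * 255
  if (!all(pixels %in% c(0, 255))) stopf("mask values must be exactly 0 or 255")
  structure(pixels, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px\n",
              nrow(x), ncol(x), sum(unclass(x) == 255)))
  invisible(x)
}

is_binary <- function(x) inherits(x, "binary_mask") || all(x %in% c(0, 255))

#' Construct an ordered sequence of frames
#'
#' All frames must share one shape; indices are (re)assigned consecutively
#' from 0 in list order.
#'
#' @param frames list of `gray_frame` objects (or plain matrices).
#' @param frame_rate frames per second; metadata only.
#' @return a `frame_sequence` object.
#' @export
frame_sequence <- function(frames, frame_rate = 10) {
  if (!is.list(frames) || length(frames) == 0L) stopf("frames must be a non-empty list")
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (!inherits(f, "gray_frame")) f <- gray_frame(f)
    attr(f, "index") <- i - 1L
    f
  })
  h <- nrow(frames[[1L]])
  w <- ncol(frames[[1L]])
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != h || ncol(frames[[i]]) != w) {
      stopf("frame %d has shape %dx%d, expected %dx%d",
            i - 1L, nrow(frames[[i]]), ncol(frames[[i]]), h, w)
    }
  }
  structure(list(frames = frames, frame_rate = frame_rate, height = h, width = w),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Extract one frame (by 0-based index) from a sequence
#' @param seq a `frame_sequence`.
#' @param index 0-based frame index.
#' @return a `gray_frame`.
#' @export
get_frame <- function(seq, index) {
  if (index < 0L || index >= length(seq)) stopf("frame index %d out of range", index)
  seq$frames[[index + 1L]]
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %d x %d px at %g fps\n",
              length(x), x$height, x$width, x$frame_rate))
  invisible(x)
}

#' Construct an object-level detection set
#'
#' One row per detected particle: sub-pixel centroid `(row, col)` in 0-based
#' coordinates and the pixel area of its connected component.
#'
#' @param frame_index 0-based frame number.
#' @param method detector name string.
#' @param detections data frame with columns `row`, `col`, `area`.
#' @return a `detection_set` object.
#' @export
detection_set <- function(frame_index, method,
                          detections = data.frame(row = numeric(0), col = numeric(0),
                                                  area = numeric(0))) {
  detections <- as.data.frame(detections)
  need <- c("row", "col", "area")
  if (!all(need %in% names(detections))) stopf("detections need columns row, col, area")
  detections <- detections[, need, drop = FALSE]
  for (col in need) detections[[col]] <- as.numeric(detections[[col]])
  if (nrow(detections) > 0L) {
    if (any(detections$area < 1)) stopf("detection areas must be >= 1")
    if (anyDuplicated(detections[, c("row", "col")])) {
      stopf("two detections share an identical centroid")
    }
  }
  rownames(detections) <- NULL
  structure(list(frame_index = as.integer(frame_index), method = as.character(method),
                 detections = detections),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> frame %d, method '%s', %d detections\n",
              x$frame_index, x$method, nrow(x$detections)))
  invisible(x)
}

#' Number of detections in a detection set
#' @param x a `detection_set`.
#' @export
n_detections <- function(x) nrow(x$detections)

#' Construct a ground-truth table
#'
#' True particle centers per frame, with unique particle ids within each
#' frame and a logical moving/attached flag. Coordinates are 0-based.
#'
#' @param df data frame with columns `frame`, `particle_id`, `row`, `col`,
#'   `attached`.
#' @return a `ground_truth` data frame.
#' @export
ground_truth <- function(df) {
  df <- as.data.frame(df)
  need <- c("frame", "particle_id", "row", "col", "attached")
  if (!all(need %in% names(df))) {
    stopf("ground truth needs columns %s", paste(need, collapse = ", "))
  }
  df <- df[, need, drop = FALSE]
  df$attached <- as.logical(df$attached)
  if (nrow(df) > 0L) {
    dup <- stats::aggregate(particle_id ~ frame, df, function(v) anyDuplicated(v) > 0L)
    if (any(dup$particle_id)) stopf("particle ids must be unique within a frame")
  }
  rownames(df) <- NULL
  class(df) <- c("ground_truth", "data.frame")
  df
}

#' Ground-truth rows for one frame
#' @param truth a `ground_truth` table.
#' @param frame 0-based frame index.
#' @return data frame of the matching rows.
#' @export
truth_frame <- function(truth, frame) {
  out <- truth[truth$frame == frame, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct confusion counts from detection/ground-truth matching
#'
#' `tp`/`fp`/`fn` follow the usual definitions; in the target-detection
#' vocabulary they are the detected targets (DT), false alarms (FA) and
#' missed targets (MT).
#'
#' @param tp,fp,fn non-negative integers.
#' @return a `confusion_counts` object with fields `tp`, `fp`, `fn` and
#'   aliases `dt`, `fa`, `mt`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  for (v in c(tp, fp, fn)) if (!is_count(v) || v < 0) stopf("counts must be non-negative integers")
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 dt = as.integer(tp), fa = as.integer(fp), mt = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}
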