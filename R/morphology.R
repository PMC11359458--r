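#' Structuring elements
#'
#' A structuring element is the binary probe of a morphological operation:
#' a small set of `(dr, dc)` offsets around an origin at `(0, 0)`.
#' `disk_se(r)` contains every offset with `dr^2 + dc^2 <= r^2`
#' (inclusive), `square_se(n)` the full `n x n` block, and `cross_se()`
#' the 4-neighbour cross.
#'
#' @param r disk radius in pixels.
#' @return a `structuring_element`: list with `offsets` (2-column matrix)
#'   and `kind`.
#' @export
disk_se <- function(r) {
  if (r < 0) stopf("radius must be >= 0")
  structure(list(offsets = disk_offsets(r), kind = sprintf("disk(%g)", r)),
            class = "structuring_element")
}

#' @rdname disk_se
#' @param n odd side length of the square.
#' @export
square_se <- function(n = 3) {
  if (n %% 2L == 0L || n < 1L) stopf("square side must be odd and positive")
  h <- (n - 1L) / 2L
  structure(list(offsets = as.matrix(expand.grid(dr = -h:h, dc = -h:h)),
                 kind = sprintf("square(%d)", n)),
            class = "structuring_element")
}

#' @rdname disk_se
#' @export
cross_se <- function() {
  structure(list(offsets = cbind(dr = c(-1L, 0L, 0L, 0L, 1L),
                                 dc = c(0L, -1L, 0L, 1L, 0L)),
                 kind = "cross"),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> %s, %d offsets\n", x$kind, nrow(x$offsets)))
  invisible(x)
}

as_se <- function(se) {
  if (!inherits(se, "structuring_element")) stopf("se must be a structuring_element")
  if (nrow(se$offsets) == 0L) stopf("structuring element has an empty footprint")
  se
}

#' Morphological erosion and dilation
#'
#' For a binary mask, erosion keeps a pixel when the translated footprint
#' fits entirely inside the foreground, and dilation sets a pixel when the
#' reflected footprint hits the foreground; out-of-bounds cells count as
#' background, so erosion shrinks at the frame border. For a grayscale
#' image the operations are the local minimum over the footprint and the
#' local maximum over the reflected footprint, with out-of-bounds cells
#' taking the identity element of the reduction (so the border does not
#' bias the result).
#'
#' @param image a [binary_mask()], [gray_frame()] or numeric matrix.
#' @param se a structuring element, e.g. [disk_se()].
#' @return same type as `image`.
#' @export
erode <- function(image, se) {
  se <- as_se(se)
  morph_reduce(image, se$offsets, op = "min")
}

#' @rdname erode
#' @export
dilate <- function(image, se) {
  se <- as_se(se)
  morph_reduce(image, -se$offsets, op = "max")
}

# shared min/max reduction over footprint offsets; binary masks pad with
# background (0), grayscale pads with the identity of the reduction
morph_reduce <- function(image, offsets, op) {
  binary <- inherits(image, "binary_mask")
  gray <- inherits(image, "gray_frame")
  m <- px(image)
  pad_val <- if (binary) 0 else if (op == "min") Inf else -Inf
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_pad(m, offsets[i, 1L], offsets[i, 2L], pad = "value", value = pad_val)
    out <- if (is.null(out)) s else if (op == "min") pmin(out, s) else pmax(out, s)
  }
  if (binary) binary_mask(out) else if (gray) gray_frame(out, frame_index(image)) else out
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same element; removes bright
#' structures smaller than the element and is idempotent.
#'
#' @inheritParams erode
#' @return same type as `image`.
#' @export
opening <- function(image, se) {
  dilate(erode(image, se), se)
}

#' White top-hat transform
#'
#' The difference between a grayscale image and its opening. Only bright
#' structures too small to survive the opening remain, which makes the
#' top-hat a background-flattening spot enhancer: a 1--2 px colloid on any
#' slowly varying background keeps its full contrast while wide structures
#' vanish. All values are >= 0.
#'
#' @param image a [gray_frame()] or numeric matrix.
#' @param se a structuring element.
#' @return a numeric response matrix (same shape, non-negative).
#' @export
top_hat <- function(image, se) {
  if (inherits(image, "binary_mask")) stopf("top_hat expects a grayscale image")
  px(image) - px(opening(image, se))
}

#' Detect colloids by grayscale dilation
#'
#' Grayscale dilation with a disk (default radius 4) expands every bright
#' spot to the disk's size, enhancing the otherwise 1--2 px colloids, and
#' the result is binarized -- by Otsu's threshold by default, or at a
#' fixed intensity. Note that on strongly three-modal images the global
#' Otsu threshold separates the dominant grain/pore split rather than the
#' tiny colloid class, a failure mode of global thresholding that the
#' evaluation records as missed detections rather than an error.
#'
#' @param frame a [gray_frame()].
#' @param r dilation disk radius in pixels.
#' @param post_threshold `"otsu"` or a fixed numeric threshold
#'   (foreground where the dilated intensity is `>=` the value).
#' @return a [binary_mask()].
#' @export
dilation_detect <- function(frame, r = 4, post_threshold = "otsu") {
  d <- dilate(frame, disk_se(r))
  binarize_response(px(d), post_threshold)
}

#' Detect colloids by the top-hat transform
#'
#' White top-hat with a disk (default radius 2) removes everything wider
#' than the disk, leaving only small bright spots; the non-negative
#' response is then binarized (Otsu by default). On micromodel imagery
#' whose pore geometry is everywhere wider than the disk, the response is
#' nonzero only at the colloids, which is what makes this the strongest
#' single detector.
#'
#' @param frame a [gray_frame()].
#' @param r top-hat disk radius in pixels.
#' @param post_threshold `"otsu"` or a fixed numeric threshold.
#' @return a [binary_mask()].
#' @export
tophat_detect <- function(frame, r = 2, post_threshold = "otsu") {
  th <- top_hat(frame, disk_se(r))
  binarize_response(th, post_threshold)
}

binarize_response <- function(resp, post_threshold) {
  resp <- round(pmin(pmax(resp, 0), 255))
  if (identical(post_threshold, "otsu")) {
    otsu_detect(gray_frame(resp))
  } else if (is.numeric(post_threshold) && length(post_threshold) == 1L) {
    binary_mask((resp >= post_threshold) * 255)
  } else {
    stopf("post_threshold must be \"otsu\" or a single number")
  }
}
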