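#' Construct a small convolution kernel
#'
#' @param weights numeric matrix with odd side lengths; the origin is the
#'   geometric center.
#' @return a `filter_kernel` object.
#' @export
filter_kernel <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) %% 2L == 0L || ncol(weights) %% 2L == 0L) {
    stopf("kernel side lengths must be odd")
  }
  structure(weights, class = "filter_kernel")
}

#' @export
print.filter_kernel <- function(x, ...) {
  cat(sprintf("<filter_kernel> %d x %d, sum %.3g\n", nrow(x), ncol(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Correlate a frame with a small kernel
#'
#' Discrete correlation (the kernel is not flipped): the output pixel is
#' the dot product of the kernel with the neighbourhood of the input pixel.
#' Out-of-bounds neighbours are handled by replicate-edge padding.
#'
#' @param frame a [gray_frame()] or numeric matrix.
#' @param kernel a [filter_kernel()] or odd-sized numeric matrix.
#' @param border border policy; only `"replicate"` is provided.
#' @return a numeric response matrix of the same shape (signed reals).
#' @export
convolve_frame <- function(frame, kernel, border = "replicate") {
  if (!identical(border, "replicate")) stopf("unsupported border policy: %s", border)
  k <- unclass(filter_kernel(kernel))
  m <- px(frame)
  hr <- (nrow(k) - 1L) %/% 2L
  hc <- (ncol(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      w <- k[i, j]
      if (w != 0) out <- out + w * shift_pad(m, i - 1L - hr, j - 1L - hc)
    }
  }
  out
}

#' Detect colloids with a negated-Laplacian spot filter
#'
#' Correlates the frame with the 4-neighbour stencil of the negated
#' Laplacian (center +4, edge neighbours -1), which estimates the second
#' derivative of intensity. A bright single-pixel spot on a flat
#' background yields a strong positive central response ringed by four
#' negative lobes; thresholding the response isolates such spots, while
#' linear intensity ramps give zero response in the interior.
#'
#' @param frame a [gray_frame()].
#' @param response_threshold minimum (strict) response for foreground, on
#'   the 0--255 intensity scale.
#' @return a [binary_mask()].
#' @export
laplacian_detect <- function(frame, response_threshold = 40) {
  k <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3L, 3L)
  resp <- convolve_frame(frame, k)
  binary_mask((resp > response_threshold) * 255)
}

#' Difference-of-Gaussians kernel
#'
#' Evaluates two isotropic Gaussians on the `size x size` lattice,
#' normalizes each truncated Gaussian to unit sum over that support, and
#' subtracts the wide one from the narrow one. The per-support
#' normalization guarantees an exactly zero-sum band-pass kernel even at
#' aggressive truncation (e.g. a 3x3 support for sigma 2).
#'
#' @param sigma1 narrow standard deviation; must satisfy
#'   `0 < sigma1 < sigma2`.
#' @param sigma2 wide standard deviation.
#' @param size odd side length of the kernel support.
#' @return a [filter_kernel()] with `sum(weights) == 0` to within 1e-12.
#' @export
dog_kernel <- function(sigma1 = 0.5, sigma2 = 2, size = 3) {
  if (!(sigma1 > 0) || sigma1 >= sigma2) stopf("need 0 < sigma1 < sigma2")
  if (size %% 2L == 0L) stopf("kernel size must be odd")
  h <- (size - 1L) / 2L
  g <- function(s) {
    x <- outer((-h:h)^2, (-h:h)^2, "+")
    w <- exp(-x / (2 * s^2))
    w / sum(w)
  }
  filter_kernel(g(sigma1) - g(sigma2))
}

#' Detect colloids with a Difference-of-Gaussians filter
#'
#' Correlates the frame with [dog_kernel()] and marks a pixel foreground
#' when its band-pass response exceeds `response_threshold` and at least
#' one 8-neighbour has a response of the opposite sign -- the
#' zero-crossing condition that characterizes an extreme local change in
#' brightness. A constant frame yields an empty mask (zero-sum kernel);
#' an isolated bright pixel is detected exactly at its location.
#'
#' @param frame a [gray_frame()].
#' @param sigma1,sigma2,size passed to [dog_kernel()].
#' @param response_threshold minimum (strict) response for foreground.
#' @return a [binary_mask()].
#' @export
dog_detect <- function(frame, sigma1 = 0.5, sigma2 = 2, size = 3,
                       response_threshold = 10) {
  resp <- convolve_frame(frame, dog_kernel(sigma1, sigma2, size))
  neg <- resp < 0
  opp <- matrix(FALSE, nrow(resp), ncol(resp))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      opp <- opp | shift_pad(neg, dr, dc, pad = "value", value = FALSE)
    }
  }
  binary_mask(((resp > response_threshold) & opp) * 255)
}
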