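# Shared internal helpers. The index-shift below is the workhorse behind
# convolution, morphology and the frame-differencing neighbourhood tests:
# out[z] = m[z + (dr, dc)], with out-of-bounds cells either clamped to the
# nearest edge pixel ("replicate") or filled with a constant.

shift_pad <- function(m, dr, dc, pad = c("replicate", "value"), value = 0) {
  pad <- match.arg(pad)
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  if (pad == "replicate") {
    m[pmin(pmax(ri, 1L), nr), pmin(pmax(ci, 1L), nc), drop = FALSE]
  } else {
    out <- matrix(value, nr, nc)
    rok <- ri >= 1L & ri <= nr
    cok <- ci >= 1L & ci <= nc
    if (any(rok) && any(cok)) {
      out[which(rok), which(cok)] <- m[ri[rok], ci[cok], drop = FALSE]
    }
    out
  }
}

# logical-matrix erosion/dilation used by the scene generator and mask
# regularization; offsets is a 2-column matrix of (dr, dc) probe offsets
lmask_erode <- function(mask, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_pad(mask, offsets[i, 1L], offsets[i, 2L], pad = "value", value = FALSE)
    out <- if (is.null(out)) s else out & s
  }
  out
}

lmask_dilate <- function(mask, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_pad(mask, -offsets[i, 1L], -offsets[i, 2L], pad = "value", value = FALSE)
    out <- if (is.null(out)) s else out | s
  }
  out
}

# offsets (dr, dc) with dr^2 + dc^2 <= r^2, inclusive
disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE])
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
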