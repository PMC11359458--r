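#' Connected components of a binary mask
#'
#' Maximal connected foreground components under 4- or 8-connectivity.
#' Pixel adjacency is assembled with vectorized index arithmetic and the
#' components are taken from the resulting adjacency graph
#' (igraph); the listing is deterministic: components are ordered by their
#' first pixel in row-major scan order, and pixels within a component
#' likewise.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 4 or 8 (default 8: 1--2 px spots may touch
#'   diagonally).
#' @return a list of 2-column matrices of 1-based `(row, col)` pixel
#'   indices, one per component.
#' @export
connected_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  m <- px(mask) == 255
  nr <- nrow(m)
  nc <- ncol(m)
  idx <- which(m)
  if (length(idx) == 0L) return(list())
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)

  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    rn <- r + o[1L]
    cn <- c + o[2L]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nidx <- (cn[ok] - 1L) * nr + rn[ok]
    hit <- m[nidx]
    if (any(hit)) {
      edges <- c(edges, rbind(pos[idx[ok][hit]], pos[nidx[hit]]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership

  scan_key <- (r - 1L) * nc + (c - 1L)  # row-major order
  comp_first <- tapply(scan_key, memb, min)
  comp_order <- order(comp_first)
  ord <- order(memb, scan_key)
  split_r <- split(r[ord], memb[ord])
  split_c <- split(c[ord], memb[ord])
  lapply(comp_order, function(k) cbind(row = split_r[[k]], col = split_c[[k]]))
}

#' Turn a detector mask into object-level detections
#'
#' Labels the mask's connected components, filters them by area, and
#' summarizes each surviving component by its unweighted centroid (mean of
#' pixel coordinates, reported 0-based) and pixel area. The area filter
#' rejects both sub-particle speckle (`min_area`) and large false blobs
#' such as pore-space regions passing a global threshold (`max_area`).
#'
#' @param mask a [binary_mask()].
#' @param frame_index 0-based frame number recorded in the output.
#' @param method detector name recorded in the output.
#' @param min_area,max_area inclusive component-area bounds in pixels.
#' @param connectivity passed to [connected_components()].
#' @return a [detection_set()].
#' @export
extract_detections <- function(mask, frame_index = 0L, method = "unknown",
                               min_area = 1, max_area = Inf, connectivity = 8) {
  if (min_area < 1) stopf("min_area must be >= 1")
  if (min_area > max_area) stopf("min_area must not exceed max_area")
  comps <- connected_components(mask, connectivity)
  keep <- Filter(function(p) nrow(p) >= min_area && nrow(p) <= max_area, comps)
  if (length(keep) == 0L) return(detection_set(frame_index, method))
  det <- data.frame(
    row = vapply(keep, function(p) mean(p[, 1L]) - 1, numeric(1)),
    col = vapply(keep, function(p) mean(p[, 2L]) - 1, numeric(1)),
    area = vapply(keep, nrow, numeric(1))
  )
  detection_set(frame_index, method, det)
}
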