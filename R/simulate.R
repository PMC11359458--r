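#' Configuration of a synthetic micromodel scene
#'
#' Describes the three-region micromodel geometry the generator renders:
#' dark solid grains, lighter pore fluid, and bright point-like colloids, a
#' mix of which move with the flow while the rest are attached to grain
#' surfaces. Defaults emulate the imaging design the detectors were built
#' for: 1684 x 1688 px frames at 2.9 um/px, porosity 0.42, 81 colloids of
#' 4.3 um diameter (about 1.5 px, rendered as radius-1 disks) in the first
#' frame, and a mean pore-water drift of about 2 px/frame at 10 frames/s.
#'
#' @param height,width frame size in pixels.
#' @param grain_intensity,pore_intensity,colloid_intensity the three 8-bit
#'   levels; must be strictly increasing.
#' @param porosity_target pore-space fraction of the domain, in (0, 1).
#' @param n_colloids number of colloids placed in frame 0.
#' @param frac_attached fraction of colloids that are stationary
#'   ("attached"); the rest move with the flow.
#' @param colloid_radius_px radius of the rendered colloid disk.
#' @param speed_px_per_frame mean per-frame displacement of moving
#'   colloids, along the flow (left to right).
#' @param noise_sigma additive Gaussian sensor-noise standard deviation
#'   (0 disables noise).
#' @param n_frames number of frames to render.
#' @param seed RNG seed; the scene is a deterministic function of the
#'   configuration.
#' @param wall_margin minimum distance (px) kept between a colloid center
#'   and the nearest grain pixel or frame border.
#' @param min_separation minimum center-to-center distance (px) between
#'   any two colloids, maintained in every frame.
#' @param blob_scale characteristic grain-feature size (px) of the
#'   generated geometry.
#' @param frame_rate frames per second, metadata only.
#' @return a `scene_config` list.
#' @export
scene_config <- function(height = 1684, width = 1688,
                         grain_intensity = 10, pore_intensity = 150,
                         colloid_intensity = 250,
                         porosity_target = 0.42, n_colloids = 81,
                         frac_attached = 0.3, colloid_radius_px = 1,
                         speed_px_per_frame = 2, noise_sigma = 0,
                         n_frames = 27, seed = 42,
                         wall_margin = 6, min_separation = 10,
                         blob_scale = 24, frame_rate = 10) {
  cfg <- list(height = height, width = width, grain_intensity = grain_intensity,
              pore_intensity = pore_intensity, colloid_intensity = colloid_intensity,
              porosity_target = porosity_target, n_colloids = n_colloids,
              frac_attached = frac_attached, colloid_radius_px = colloid_radius_px,
              speed_px_per_frame = speed_px_per_frame, noise_sigma = noise_sigma,
              n_frames = n_frames, seed = seed, wall_margin = wall_margin,
              min_separation = min_separation, blob_scale = blob_scale,
              frame_rate = frame_rate)
  if (!(grain_intensity < pore_intensity && pore_intensity < colloid_intensity)) {
    stopf("need grain < pore < colloid intensity")
  }
  for (v in c(grain_intensity, pore_intensity, colloid_intensity)) {
    if (v < 0 || v > 255 || v != round(v)) stopf("intensity levels must be integers in [0, 255]")
  }
  if (!(porosity_target > 0 && porosity_target < 1)) stopf("porosity_target must be in (0, 1)")
  if (frac_attached < 0 || frac_attached > 1) stopf("frac_attached must be in [0, 1]")
  if (n_colloids < 0) stopf("n_colloids must be >= 0")
  if (n_frames < 1) stopf("n_frames must be >= 1")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  class(cfg) <- "scene_config"
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0("<scene_config> %d x %d px, %d frames, porosity %.2f, ",
                     "%d colloids (%.0f%% attached), noise sigma %g, seed %d\n"),
              x$height, x$width, x$n_frames, x$porosity_target, x$n_colloids,
              100 * x$frac_attached, x$noise_sigma, x$seed))
  invisible(x)
}

# bilinear upscaling of a coarse field; the two interpolation-weight
# matrices turn it into two small matrix products
upscale_bilinear <- function(coarse, nr, nc) {
  wmat <- function(n_out, n_in) {
    pos <- seq(1, n_in, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 1)
    frac <- pos - lo
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo)] <- 1 - frac
    W[cbind(seq_len(n_out), lo + 1)] <- frac
    W
  }
  wmat(nr, nrow(coarse)) %*% coarse %*% t(wmat(nc, ncol(coarse)))
}

# Pore geometry from a thresholded smoothed random field, regularized so
# that (a) grain slivers thinner than ~7 px are closed away and (b) the
# pore space is open with respect to disk(2) -- every pore pixel is covered
# by a disk(2) lying fully in pore space. (b) guarantees that a disk(2)
# grayscale opening reconstructs the colloid-free image exactly, so the
# top-hat response of the background is identically zero. The threshold is
# iterated until the realized pore fraction is within tolerance of target.
make_pore_mask <- function(height, width, porosity, blob_scale, tol = 0.02,
                           max_iter = 15) {
  ncr <- max(4L, ceiling(height / blob_scale) + 1L)
  ncc <- max(4L, ceiling(width / blob_scale) + 1L)
  field <- upscale_bilinear(matrix(stats::rnorm(ncr * ncc), ncr, ncc), height, width)
  close_off <- disk_offsets(3)
  open_off <- disk_offsets(2)
  p_eff <- porosity
  pore <- NULL
  frac <- NA_real_
  for (it in seq_len(max_iter)) {
    thr <- stats::quantile(field, 1 - p_eff, names = FALSE)
    pore <- field >= thr
    pore <- lmask_erode(lmask_dilate(pore, close_off), close_off)  # close grain slivers
    pore <- lmask_dilate(lmask_erode(pore, open_off), open_off)    # open: disk(2)-regular
    frac <- mean(pore)
    if (abs(frac - porosity) <= 0.5 * tol) break
    p_eff <- min(0.95, max(0.05, p_eff + (porosity - frac)))
  }
  if (abs(frac - porosity) > tol) {
    stopf("could not reach pore fraction %.2f (+/-%.2f); achieved %.3f",
          porosity, tol, frac)
  }
  pore
}

#' Generate a synthetic micromodel image sequence with ground truth
#'
#' Renders `n_frames` three-level frames: a static grain/pore geometry
#' drawn from a thresholded smoothed random field (iterated to the target
#' porosity), with `n_colloids` bright colloid disks placed in the pore
#' space at a minimum pairwise separation and a minimum clearance from
#' grain walls. A fixed fraction of the colloids is attached (identical
#' coordinates in every frame); the rest advance each frame by a random
#' displacement with mean `speed_px_per_frame` along the flow direction,
#' re-drawing the step on collision with grains or other colloids.
#' Colloids drifting past the outlet edge are removed and replacements may
#' enter at the inlet. Optional Gaussian sensor noise is added per frame
#' and clipped to `[0, 255]`. The result is a deterministic function of
#' the configuration (including its `seed`).
#'
#' @param cfg a [scene_config()].
#' @return a `colloid_scene`: list with `frames` (a [frame_sequence()]),
#'   `truth` (a [ground_truth()] with every colloid center per frame),
#'   `pore_mask` (logical matrix, `TRUE` on pore space) and `config`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  pore <- make_pore_mask(cfg$height, cfg$width, cfg$porosity_target, cfg$blob_scale)

  margin <- cfg$wall_margin
  allowed <- lmask_erode(pore, disk_offsets(margin))
  # keep clear of the frame border as well
  allowed[c(seq_len(margin), cfg$height - seq_len(margin) + 1L), ] <- FALSE
  allowed[, c(seq_len(margin), cfg$width - seq_len(margin) + 1L)] <- FALSE
  allowed_idx <- which(allowed)
  if (length(allowed_idx) < cfg$n_colloids * ceiling(cfg$min_separation^2)) {
    stopf("pore space too small for %d colloids", cfg$n_colloids)
  }

  nr <- cfg$height
  sep2 <- cfg$min_separation^2
  sep_ok <- function(r, c, rows, cols) {
    length(rows) == 0L || all((rows - r)^2 + (cols - c)^2 >= sep2)
  }

  # initial placement by rejection sampling
  pos <- matrix(numeric(0), 0L, 2L)
  if (cfg$n_colloids > 0L) {
    cand <- sample(allowed_idx)
    rows <- integer(0)
    cols <- integer(0)
    for (ix in cand) {
      r <- ((ix - 1L) %% nr) + 1L
      c <- ((ix - 1L) %/% nr) + 1L
      if (sep_ok(r, c, rows, cols)) {
        rows <- c(rows, r)
        cols <- c(cols, c)
        if (length(rows) == cfg$n_colloids) break
      }
    }
    if (length(rows) < cfg$n_colloids) {
      stopf("pore space too small for %d colloids at separation %g",
            cfg$n_colloids, cfg$min_separation)
    }
    pos <- cbind(rows, cols)
  }

  n0 <- nrow(pos)
  n_attached <- round(cfg$frac_attached * n0)
  attached <- rep(FALSE, n0)
  if (n_attached > 0L) attached[sample.int(n0, n_attached)] <- TRUE
  ids <- seq_len(n0)
  next_id <- n0 + 1L

  inlet_cols <- (margin + 1L):min(cfg$width, margin + 26L)
  inlet_idx <- which(allowed[, inlet_cols, drop = FALSE])
  exit_col <- cfg$width - margin - 2L

  base <- matrix(cfg$grain_intensity, cfg$height, cfg$width)
  base[pore] <- cfg$pore_intensity
  spot <- disk_offsets(cfg$colloid_radius_px)

  frames <- vector("list", cfg$n_frames)
  truth_rows <- vector("list", cfg$n_frames)
  speed <- cfg$speed_px_per_frame

  for (f in seq_len(cfg$n_frames) - 1L) {
    if (f > 0L && nrow(pos) > 0L) {
      # advance moving colloids; attached ones keep their coordinates
      exited <- integer(0)
      for (i in seq_len(nrow(pos))) {
        if (attached[i]) next
        moved <- FALSE
        for (try in seq_len(30L)) {
          dr <- round(stats::rnorm(1, 0, speed / 2))
          dc <- round(stats::rnorm(1, speed, speed / 2))
          r2 <- pos[i, 1L] + dr
          c2 <- pos[i, 2L] + dc
          if (c2 >= exit_col) {
            exited <- c(exited, i)
            moved <- TRUE
            break
          }
          if (r2 < 1L || r2 > cfg$height || c2 < 1L || c2 > cfg$width) next
          if (!allowed[r2, c2]) next
          if (!sep_ok(r2, c2, pos[-i, 1L], pos[-i, 2L])) next
          pos[i, ] <- c(r2, c2)
          moved <- TRUE
          break
        }
        if (!moved) next  # blocked: behaves as a slow colloid this frame
      }
      if (length(exited) > 0L) {
        n_exit <- length(exited)
        pos <- pos[-exited, , drop = FALSE]
        ids <- ids[-exited]
        attached <- attached[-exited]
        # replacements enter at the inlet edge
        for (e in seq_len(n_exit)) {
          for (try in seq_len(50L)) {
            ix <- inlet_idx[sample.int(length(inlet_idx), 1L)]
            r2 <- ((ix - 1L) %% nr) + 1L
            c2 <- inlet_cols[((ix - 1L) %/% nr) + 1L]
            if (sep_ok(r2, c2, pos[, 1L], pos[, 2L])) {
              pos <- rbind(pos, c(r2, c2))
              ids <- c(ids, next_id)
              attached <- c(attached, FALSE)
              next_id <- next_id + 1L
              break
            }
          }
        }
      }
    }

    img <- base
    if (nrow(pos) > 0L) {
      for (i in seq_len(nrow(pos))) {
        pxs <- cbind(pos[i, 1L] + spot[, 1L], pos[i, 2L] + spot[, 2L])
        img[pxs] <- cfg$colloid_intensity
      }
    }
    if (cfg$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, cfg$noise_sigma)
      img <- round(pmin(pmax(img, 0), 255))
    }
    frames[[f + 1L]] <- gray_frame(img, f)
    truth_rows[[f + 1L]] <- if (nrow(pos) > 0L) {
      data.frame(frame = f, particle_id = ids,
                 row = pos[, 1L] - 1, col = pos[, 2L] - 1, attached = attached)
    } else {
      data.frame(frame = integer(0), particle_id = integer(0),
                 row = numeric(0), col = numeric(0), attached = logical(0))
    }
  }

  truth <- ground_truth(do.call(rbind, truth_rows))
  structure(list(frames = frame_sequence(frames, frame_rate = cfg$frame_rate),
                 truth = truth, pore_mask = pore, config = cfg),
            class = "colloid_scene")
}

#' @export
print.colloid_scene <- function(x, ...) {
  cat(sprintf("<colloid_scene> %d frames of %d x %d px, %d ground-truth records\n",
              length(x$frames), x$config$height, x$config$width, nrow(x$truth)))
  invisible(x)
}

#' Render the reference frame of a scene
#'
#' Frame 0 of [generate_scene()] under the same configuration (the RNG
#' consumes geometry and placement before any motion, so the single frame
#' is bit-identical to frame 0 of the full sequence), together with its
#' ground-truth rows.
#'
#' @param cfg a [scene_config()].
#' @return list with `frame` (a [gray_frame()]), `truth` (frame-0 rows)
#'   and `pore_mask`.
#' @export
render_reference_frame <- function(cfg) {
  one <- cfg
  one$n_frames <- 1L
  scene <- generate_scene(one)
  list(frame = get_frame(scene$frames, 0L), truth = truth_frame(scene$truth, 0L),
       pore_mask = scene$pore_mask)
}
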