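# Fixtures and independent oracles shared across the test files. Every
# oracle here is a deliberately naive re-statement of the defining
# equations (scalar loops, exhaustive enumeration), kept independent of the
# package internals it checks.

# small-scale scene standing in for the full 1684x1688 study geometry
ci_scene_config <- function(...) {
  base <- list(height = 256, width = 256, n_colloids = 20, n_frames = 9, seed = 1)
  do.call(scene_config, utils::modifyList(base, list(...)))
}

rand_frame <- function(nr, nc, seed) {
  set.seed(seed)
  gray_frame(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc))
}

rand_mask <- function(nr, nc, seed, p = 0.4) {
  set.seed(seed)
  binary_mask(matrix(ifelse(runif(nr * nc) < p, 255, 0), nr, nc))
}

# three-level frame with known colloid positions (1-px colloids), no noise
three_level_frame <- function(nr = 24, nc = 24, grain = 10, pore = 150,
                              colloid = 250, centers = rbind(c(6, 6), c(15, 18))) {
  m <- matrix(pore, nr, nc)
  m[, 1:3] <- grain
  for (i in seq_len(nrow(centers))) m[centers[i, 1], centers[i, 2]] <- colloid
  gray_frame(m)
}

# --- independent oracles ---------------------------------------------------

# scalar-loop two-frame difference
oracle_two_frame <- function(a, b, T) {
  a <- unclass(a); b <- unclass(b)
  out <- matrix(0, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (abs(a[i, j] - b[i, j]) > T) out[i, j] <- 255
  }
  out
}

# scalar-loop multi-frame difference (mean of three absolute differences)
oracle_mfd <- function(fp, ft, fn, T) {
  fp <- unclass(fp); ft <- unclass(ft); fn <- unclass(fn)
  out <- matrix(0, nrow(ft), ncol(ft))
  for (i in seq_len(nrow(ft))) for (j in seq_len(ncol(ft))) {
    fd <- (abs(ft[i, j] - fp[i, j]) + abs(fn[i, j] - fp[i, j]) +
             abs(fn[i, j] - ft[i, j])) / 3
    if (fd > T) out[i, j] <- 255
  }
  out
}

# triple-loop correlation with replicate padding
oracle_convolve <- function(m, k) {
  m <- unclass(m)
  hr <- (nrow(k) - 1) / 2; hc <- (ncol(k) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
      ri <- min(max(i + a - 1 - hr, 1), nrow(m))
      ci <- min(max(j + b - 1 - hc, 1), ncol(m))
      acc <- acc + k[a, b] * m[ri, ci]
    }
    out[i, j] <- acc
  }
  out
}

# set-definition binary erosion/dilation (out-of-bounds = background)
oracle_bin_erode <- function(mask, offsets) {
  m <- unclass(mask) == 255
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    fits <- TRUE
    for (t in seq_len(nrow(offsets))) {
      ri <- i + offsets[t, 1]; ci <- j + offsets[t, 2]
      if (ri < 1 || ri > nrow(m) || ci < 1 || ci > ncol(m) || !m[ri, ci]) {
        fits <- FALSE; break
      }
    }
    if (fits) out[i, j] <- 255
  }
  out
}

oracle_bin_dilate <- function(mask, offsets) {
  m <- unclass(mask) == 255
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    hit <- FALSE
    for (t in seq_len(nrow(offsets))) {
      ri <- i - offsets[t, 1]; ci <- j - offsets[t, 2]  # reflected probe
      if (ri >= 1 && ri <= nrow(m) && ci >= 1 && ci <= ncol(m) && m[ri, ci]) {
        hit <- TRUE; break
      }
    }
    if (hit) out[i, j] <- 255
  }
  out
}

# scalar-loop grayscale erosion/dilation ignoring out-of-bounds cells
oracle_gray_erode <- function(m, offsets) {
  m <- unclass(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- Inf
    for (t in seq_len(nrow(offsets))) {
      ri <- i + offsets[t, 1]; ci <- j + offsets[t, 2]
      if (ri >= 1 && ri <= nrow(m) && ci >= 1 && ci <= ncol(m)) v <- min(v, m[ri, ci])
    }
    out[i, j] <- v
  }
  out
}

# recursive flood fill, independent of the graph-based implementation
oracle_components <- function(mask, connectivity = 8) {
  m <- unclass(mask) == 255
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  comps <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE; pix <- NULL
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      pix <- rbind(pix, p)
      for (t in seq_len(nrow(offs))) {
        ri <- p[1] + offs[t, 1]; ci <- p[2] + offs[t, 2]
        if (ri >= 1 && ri <= nr && ci >= 1 && ci <= nc && m[ri, ci] && !seen[ri, ci]) {
          seen[ri, ci] <- TRUE
          stack[[length(stack) + 1]] <- c(ri, ci)
        }
      }
    }
    comps[[length(comps) + 1]] <- pix
  }
  comps
}

# canonical form of a component list for order-free comparison
canon_components <- function(comps) {
  keys <- lapply(comps, function(p) {
    p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
    paste(p[, 1], p[, 2], sep = ",", collapse = ";")
  })
  sort(unlist(keys))
}

# exhaustive maximum-cardinality matching within tolerance (<= 8 points)
oracle_max_matching <- function(det, tru, tol) {
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0 || nt == 0) return(0L)
  d <- sqrt(outer(det$row, tru$row, "-")^2 + outer(det$col, tru$col, "-")^2)
  best <- 0L
  rec <- function(i, used, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    for (j in seq_len(nt)) {
      if (!used[j] && d[i, j] <= tol) {
        used[j] <- TRUE
        rec(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
    rec(i + 1, used, count)
  }
  rec(1L, rep(FALSE, nt), 0L)
  best
}

# exhaustive search over cross-method groupings maximizing total support;
# returns the multiset of support counts (clusters of size >= 2)
oracle_vote_supports <- function(cand, radius) {
  n <- nrow(cand)
  d <- as.matrix(dist(cand[, c("row", "col")]))
  feasible <- function(ix) {
    if (length(unique(cand$method[ix])) != length(ix)) return(FALSE)
    all(d[ix, ix][upper.tri(matrix(0, length(ix), length(ix)))] <= radius)
  }
  groups <- list()
  for (size in 2:3) {
    for (ix in utils::combn(n, size, simplify = FALSE)) {
      if (feasible(ix)) groups[[length(groups) + 1]] <- ix
    }
  }
  best <- list(support = 0L, sizes = integer(0))
  search <- function(avail, chosen, total) {
    better <- total > best$support
    if (better) best <<- list(support = total, sizes = sort(vapply(chosen, length, 1L)))
    for (g in groups) {
      if (all(g %in% avail)) {
        search(setdiff(avail, g), c(chosen, list(g)), total + length(g))
      }
    }
  }
  search(seq_len(n), list(), 0L)
  best$sizes
}
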