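#' Read an image sequence from a TIFF stack or an image directory
#'
#' Frames are ordered by stack index (multi-page TIFF) or lexicographic
#' filename (directory of PNG/TIFF images). Multi-channel images are
#' converted to grayscale by luminance averaging and rounding; sample values
#' are max-normalized to the 8-bit range, so 16-bit inputs are rescaled.
#'
#' @param path a TIFF file or a directory containing PNG/TIFF frames.
#' @param format `"auto"` (decide from `path`), `"tiff-stack"` or
#'   `"image-directory"`.
#' @param frame_rate frames per second recorded as sequence metadata.
#' @return a [frame_sequence()].
#' @export
read_sequence <- function(path, format = c("auto", "tiff-stack", "image-directory"),
                          frame_rate = 10) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "image-directory" else "tiff-stack"
  }
  if (format == "tiff-stack") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- lapply(pages, decode_image)
    names(mats) <- sprintf("%s[page %d]", basename(path), seq_along(mats))
  } else {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stopf("no PNG/TIFF images found in %s", path)
    mats <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f) else tiff::readTIFF(f)
      decode_image(img)
    })
    names(mats) <- basename(files)
  }
  h <- nrow(mats[[1L]])
  w <- ncol(mats[[1L]])
  for (i in seq_along(mats)) {
    if (nrow(mats[[i]]) != h || ncol(mats[[i]]) != w) {
      stopf("frame '%s' has shape %dx%d, expected %dx%d",
            names(mats)[i], nrow(mats[[i]]), ncol(mats[[i]]), h, w)
    }
  }
  frame_sequence(mats, frame_rate = frame_rate)
}

# readTIFF/readPNG return values in [0, 1]; collapse channels by luminance
# averaging, rescale to 8 bits and round
decode_image <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  round(img * 255)
}

#' Write an image sequence as an 8-bit multi-page TIFF
#'
#' @param seq a [frame_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  tiff::writeTIFF(lapply(seq$frames, function(f) px(f) / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Write / read object-level detections as CSV
#'
#' One file per run with header `frame, method, row, col, area`; centroids
#' round-trip to at least 1e-6. `read_detections()` returns one
#' [detection_set()] per `(frame, method)` pair, ordered by frame then
#' method.
#'
#' @param sets a list of [detection_set()] objects (or a single one).
#' @param path CSV file path.
#' @return `write_detections()` returns `path` invisibly;
#'   `read_detections()` returns a list of `detection_set`s.
#' @export
write_detections <- function(sets, path) {
  if (inherits(sets, "detection_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    stopifnot(inherits(s, "detection_set"))
    if (nrow(s$detections) == 0L) return(NULL)
    data.frame(frame = s$frame_index, method = s$method, s$detections)
  })
  df <- do.call(rbind, c(rows, list(data.frame(frame = integer(0), method = character(0),
                                               row = numeric(0), col = numeric(0),
                                               area = numeric(0)))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("cannot parse %s: %s", path, conditionMessage(e)))
  need <- c("frame", "method", "row", "col", "area")
  if (!all(need %in% names(df))) {
    stopf("%s: expected header %s", path, paste(need, collapse = ", "))
  }
  for (col in c("frame", "row", "col", "area")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0L) {
      stopf("%s: malformed value in column '%s' at data line %d", path, col, bad[1L])
    }
  }
  if (nrow(df) == 0L) return(list())
  keys <- unique(df[, c("frame", "method")])
  keys <- keys[order(keys$frame, keys$method), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$frame == keys$frame[i] & df$method == keys$method[i]
    detection_set(keys$frame[i], keys$method[i], df[sel, c("row", "col", "area")])
  })
}

#' Write / read ground truth as CSV
#'
#' Columns: `frame, particle_id, row, col, attached`.
#'
#' @param truth a [ground_truth()] table.
#' @param path CSV file path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a `ground_truth` table.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  ground_truth(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read / write a flat key-value configuration file
#'
#' The configuration format is plain text, one `key = value` per line;
#' blank lines and `#` comments are ignored. Values that parse as numbers
#' are returned numeric, `TRUE`/`FALSE` as logical, everything else as
#' character.
#'
#' @param path file path.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE)) {
      stopf("%s: line %d is not 'key = value'", path, i)
    }
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (val %in% c("TRUE", "FALSE", "true", "false")) {
      toupper(val) == "TRUE"
    } else {
      val
    }
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar values.
#' @export
write_config <- function(config, path) {
  writeLines(vapply(names(config), function(k) {
    sprintf("%s = %s", k, format(config[[k]], digits = 15))
  }, character(1)), path)
  invisible(path)
}
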