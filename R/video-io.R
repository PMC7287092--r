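# Clip I/O, chamber localization and per-chamber cropping.

#' Construct a frame stack (one clip)
#'
#' @param frames list of grayscale matrices, all the same shape.
#' @param fps acquisition rate in Hz (> 0).
#' @param acquired_at POSIXct acquisition time or NULL.
#' @param device_id,chamber_id identifiers.
#' @export
frame_stack <- function(frames, fps, acquired_at = NULL,
                        device_id = NA_character_,
                        chamber_id = NA_character_) {
  stopifnot(is.list(frames), length(frames) >= 2, fps > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame shapes in stack")
  structure(list(frames = frames, fps = fps, acquired_at = acquired_at,
                 device_id = device_id, chamber_id = chamber_id),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack: %d frames of %d x %d @ %g fps (%.1f s)",
              length(x$frames), d[1], d[2], x$fps,
              length(x$frames) / x$fps))
  if (!is.na(x$chamber_id)) cat(sprintf(" [%s/%s]", x$device_id, x$chamber_id))
  cat("\n")
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack].
#' @export
n_frames <- function(stack) length(stack$frames)

#' Parse acquisition metadata from a clip filename
#'
#' Filenames follow `<device>_<YYYY-MM-DDTHH-MM-SS>.tif` (colons replaced
#' by dashes in the time field).
#' @param path file path.
#' @return list(device_id, acquired_at) with NULL timestamp when the
#'   pattern does not match.
#' @export
parse_clip_filename <- function(path) {
  b <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(b, regexec(
    "^(.+)_(\\d{4}-\\d{2}-\\d{2}T\\d{2}-\\d{2}-\\d{2})$", b))[[1]]
  if (length(m) == 3) {
    ts <- as.POSIXct(m[3], format = "%Y-%m-%dT%H-%M-%S", tz = "UTC")
    list(device_id = m[2], acquired_at = ts)
  } else list(device_id = b, acquired_at = NULL)
}

#' Load a clip from a multi-page TIFF
#'
#' AVI containers are not supported by the installed image stack; convert
#' to TIFF upstream.
#'
#' @param path TIFF path.
#' @param fps acquisition rate in Hz.
#' @param acquired_at override for the filename-derived timestamp.
#' @param chamber_id chamber identifier.
#' @return a [frame_stack] with frames in acquisition order.
#' @export
load_stack <- function(path, fps = 14, acquired_at = NULL,
                       chamber_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.avi$", path, ignore.case = TRUE))
    stop("AVI input is not supported; supply a multi-page TIFF")
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) stop("unreadable TIFF '", path,
                                              "': ", conditionMessage(e)))
  if (!is.list(frames)) frames <- list(frames)
  # collapse any RGB pages to their first channel
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  if (length(frames) < 2) stop("clip must contain at least 2 frames: ", path)
  meta <- parse_clip_filename(path)
  if (is.null(acquired_at)) acquired_at <- meta$acquired_at
  frame_stack(frames, fps = fps, acquired_at = acquired_at,
              device_id = meta$device_id, chamber_id = chamber_id)
}

# --- chamber detection ------------------------------------------------------

#' Detect bright circular chambers by ring accumulation
#'
#' A circular-edge accumulator (gradient magnitude convolved with an
#' annulus of the expected radius) locates chamber centers; candidate
#' peaks must additionally be brighter inside the circle than in the
#' surrounding annulus. Chambers are ordered row-major by center so IDs
#' are stable across clips of the same device.
#'
#' @param image grayscale matrix.
#' @param expected_radius_px prior chamber radius in pixels.
#' @param tolerance relative radius tolerance (accumulator annulus
#'   half-width), default 0.15.
#' @param max_chambers upper bound on detections (device holds <= 60).
#' @param min_score accumulator acceptance threshold relative to the
#'   theoretical single-circle response (0--1).
#' @return object of class `chamber_map`: data.frame `chambers`
#'   (chamber_id, center_row, center_col, radius_px) and `image_shape`.
#' @export
detect_chambers <- function(image, expected_radius_px, tolerance = 0.15,
                            max_chambers = 60, min_score = 0.35) {
  stopifnot(is.matrix(image), expected_radius_px > 0)
  r <- expected_radius_px
  if (2 * r > min(dim(image)))
    stop("expected radius ", r, " exceeds image size ",
         paste(dim(image), collapse = "x"))
  # central-difference gradient (no half-pixel bias)
  nr <- nrow(image); nc <- ncol(image)
  gx <- image * 0; gy <- image * 0
  gx[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / 2
  gy[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
  grad <- sqrt(gx^2 + gy^2)
  w <- max(1.5, tolerance * r)
  ring <- annulus_kernel(r, w)
  # accumulator: mean gradient magnitude along the candidate circle; the
  # peak value approximates the circle's edge contrast
  acc <- EBImage::filter2(grad, ring, boundary = 0) / (2 * pi * r)
  peaks <- find_peaks(acc, min_dist = 1.6 * r, min_value = min_score *
                        max(stats::quantile(abs(image), 0.98), 1e-3))
  # contrast check: interior brighter than exterior annulus
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    circle_contrast(image, peaks[i, 1], peaks[i, 2], r) > 0.03
  }, logical(1))
  peaks <- peaks[keep, , drop = FALSE]
  # drop circles extending outside the image
  inb <- peaks[, 1] - r >= 0.5 & peaks[, 1] + r <= nrow(image) + 0.5 &
         peaks[, 2] - r >= 0.5 & peaks[, 2] + r <= ncol(image) + 0.5
  peaks <- peaks[inb, , drop = FALSE]
  if (nrow(peaks) == 0)
    stop(sprintf(paste0("no chambers detected (expected radius %.1f px, ",
                        "accumulator max %.3f, threshold %.3f); check the ",
                        "radius prior and image contrast"),
                 r, max(acc), min_score * max(stats::quantile(abs(image), 0.98), 1e-3)))
  if (nrow(peaks) > max_chambers)
    peaks <- peaks[order(-peaks[, 3]), , drop = FALSE][seq_len(max_chambers), ]
  # row-major ordering: bucket rows by radius, then sort by column
  ord <- order(round(peaks[, 1] / r), peaks[, 2])
  peaks <- peaks[ord, , drop = FALSE]
  chambers <- data.frame(chamber_id = sprintf("c%02d", seq_len(nrow(peaks))),
                         center_row = peaks[, 1], center_col = peaks[, 2],
                         radius_px = r, stringsAsFactors = FALSE)
  structure(list(chambers = chambers, image_shape = dim(image)),
            class = "chamber_map")
}

annulus_kernel <- function(r, w) {
  k <- 2 * ceiling(r + w) + 1
  c0 <- (k + 1) / 2
  d <- sqrt((matrix(seq_len(k), k, k) - c0)^2 +
            (matrix(seq_len(k), k, k, byrow = TRUE) - c0)^2)
  ring <- as.numeric(abs(d - r) <= w)
  matrix(ring, k, k)
}

find_peaks <- function(acc, min_dist, min_value) {
  mx <- EBImage::filter2(acc, disc_kernel(3), boundary = 0) # light smoothing
  ord <- order(-mx)
  out <- matrix(numeric(0), 0, 3)
  for (idx in ord) {
    v <- mx[idx]
    if (v < min_value) break
    rc <- arrayInd(idx, dim(mx))
    if (nrow(out) == 0 ||
        all(sqrt((out[, 1] - rc[1])^2 + (out[, 2] - rc[2])^2) >= min_dist)) {
      rc <- refine_peak(mx, rc[1], rc[2])
      out <- rbind(out, c(rc[1], rc[2], v))
    }
    if (nrow(out) >= 200) break
  }
  out
}

# sub-pixel peak refinement: accumulator-weighted centroid over a small
# neighborhood around the integer peak
refine_peak <- function(acc, r, c, half = 3) {
  rs <- max(1, r - half):min(nrow(acc), r + half)
  cs <- max(1, c - half):min(ncol(acc), c + half)
  w <- acc[rs, cs, drop = FALSE]
  w <- pmax(w - min(w), 0)
  if (sum(w) <= 0) return(c(r, c))
  c(sum(outer(rs, rep(1, length(cs))) * w) / sum(w),
    sum(outer(rep(1, length(rs)), cs) * w) / sum(w))
}

disc_kernel <- function(d) {
  c0 <- (d + 1) / 2
  m <- (matrix(seq_len(d), d, d) - c0)^2 +
       (matrix(seq_len(d), d, d, byrow = TRUE) - c0)^2 <= (d / 2)^2
  k <- matrix(as.numeric(m), d, d)
  k / sum(k)
}

circle_contrast <- function(image, cr, cc, r) {
  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  d <- sqrt((rows - cr)^2 + (cols - cc)^2)
  inside <- d <= 0.9 * r
  outside <- d > 1.1 * r & d <= 1.5 * r
  if (!any(inside) || !any(outside)) return(0)
  mean(image[inside]) - mean(image[outside])
}

#' @export
print.chamber_map <- function(x, ...) {
  cat(sprintf("chamber_map: %d chambers in %d x %d image\n",
              nrow(x$chambers), x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Serialize / load a chamber map as CSV
#' @param map a `chamber_map`.
#' @param path CSV path.
#' @export
write_chamber_map <- function(map, path) {
  write.csv(map$chambers, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chamber_map
#' @param image_shape c(rows, cols) recorded with the loaded map.
#' @export
read_chamber_map <- function(path, image_shape = c(NA_integer_, NA_integer_)) {
  ch <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chamber_id", "center_row", "center_col", "radius_px") %in%
                names(ch)))
  structure(list(chambers = ch, image_shape = image_shape),
            class = "chamber_map")
}

#' Crop one chamber from a stack
#'
#' Produces the square crop circumscribing the chamber circle plus
#' `margin` pixels; pixels outside the circle are masked to the chamber's
#' background value (median interior intensity of the first frame) so
#' frame differencing outside the chamber is exactly zero.
#'
#' @param stack a [frame_stack] of the whole device.
#' @param chamber one row of a `chamber_map$chambers` data.frame (or a
#'   list with center_row, center_col, radius_px, chamber_id).
#' @param margin extra pixels around the circle (default 2).
#' @return a [frame_stack] for the chamber, with `chamber` geometry
#'   attached (center in crop coordinates, radius).
#' @export
crop_chamber <- function(stack, chamber, margin = 2) {
  cr <- chamber$center_row; cc <- chamber$center_col; r <- chamber$radius_px
  d <- dim(stack$frames[[1]])
  r0 <- round(cr - r - margin); r1 <- round(cr + r + margin)
  c0 <- round(cc - r - margin); c1 <- round(cc + r + margin)
  if (r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2])
    stop(sprintf("chamber %s circle (+margin) extends outside frame bounds",
                 chamber$chamber_id))
  rows <- matrix(seq(r0, r1), r1 - r0 + 1, c1 - c0 + 1)
  cols <- matrix(seq(c0, c1), r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  inside <- (rows - cr)^2 + (cols - cc)^2 <= r^2
  bg <- median(stack$frames[[1]][r0:r1, c0:c1][inside])
  frames <- lapply(stack$frames, function(f) {
    cropped <- f[r0:r1, c0:c1]
    cropped[!inside] <- bg
    cropped
  })
  out <- frame_stack(frames, fps = stack$fps, acquired_at = stack$acquired_at,
                     device_id = stack$device_id,
                     chamber_id = chamber$chamber_id)
  out$chamber_geom <- list(center = c(cr - r0 + 1, cc - c0 + 1), radius = r,
                           inside = inside)
  out
}
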