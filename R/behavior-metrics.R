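# Per-clip behavioral metrics: raw movement (frame-difference pixel
# fraction), centroid speed, body-bend amplitude, swimming frequency;
# assembly of longitudinal per-individual traces.

#' Raw movement: fraction of chamber pixels changing between frames
#'
#' For each valid consecutive frame pair, the fraction of chamber pixels
#' whose absolute intensity difference exceeds `diff_threshold`; the clip
#' value is the mean over valid pairs. Raw movement is computed on the
#' full chamber crop, not the segmentation mask, so it stays defined when
#' segmentation fails (death calling relies on this).
#'
#' @param stack a [frame_stack] (chamber crop).
#' @param diff_threshold per-pixel change threshold in gray levels
#'   (0--255 scale), default 10.
#' @param valid_frames logical vector marking usable frames; pairs
#'   containing an invalid frame are excluded.
#' @return fraction in \[0, 1\], or NA with a `reason` attribute when no
#'   valid pair exists.
#' @export
raw_movement <- function(stack, diff_threshold = 10, valid_frames = NULL) {
  nf <- n_frames(stack)
  if (is.null(valid_frames)) valid_frames <- rep(TRUE, nf)
  geom <- stack$chamber_geom
  inside <- if (!is.null(geom) && !is.null(geom$inside)) geom$inside else
    matrix(TRUE, nrow(stack$frames[[1]]), ncol(stack$frames[[1]]))
  npx <- sum(inside)
  # on 8-bit data "difference > t gray levels" means >= t+1 levels; the
  # half-level margin also keeps the comparison stable under float jitter
  thr <- (diff_threshold + 0.5) / 255
  fracs <- numeric(0)
  for (i in seq_len(nf - 1)) {
    if (!valid_frames[i] || !valid_frames[i + 1]) next
    d <- abs(stack$frames[[i + 1]] - stack$frames[[i]])
    fracs <- c(fracs, sum(d[inside] > thr) / npx)
  }
  if (!length(fracs))
    return(structure(NA_real_, reason = "no valid consecutive frame pair"))
  mean(fracs)
}

#' Centroid speed from accepted per-frame centroids
#'
#' Mean displacement between consecutive accepted centroids times fps;
#' pairs spanning missing frames are excluded.
#'
#' @param obs a `worm_observation`.
#' @param fps frames per second; defaults to the observation's fps.
#' @param um_per_px optional pixel size; when given the speed is um/s,
#'   otherwise px/s.
#' @return speed, or NA with reason when < 2 accepted centroids.
#' @export
centroid_speed <- function(obs, fps = obs$fps, um_per_px = NULL) {
  ok <- obs$flags != "missing" & !is.na(obs$centroids[, 1])
  if (sum(ok) < 2)
    return(structure(NA_real_, reason = "fewer than 2 accepted centroids"))
  idx <- which(ok)
  pairs <- idx[-length(idx)][diff(idx) == 1]   # adjacent-frame pairs only
  if (!length(pairs))
    return(structure(NA_real_, reason = "no adjacent accepted frame pair"))
  d <- sqrt((obs$centroids[pairs + 1, 1] - obs$centroids[pairs, 1])^2 +
            (obs$centroids[pairs + 1, 2] - obs$centroids[pairs, 2])^2)
  v <- mean(d) * fps
  if (!is.null(um_per_px)) v <- v * um_per_px
  v
}

#' Body-bend amplitude: chord deviation over arc length
#'
#' Per frame with a valid centerline, the maximum perpendicular deviation
#' of the centerline from its endpoint chord divided by the centerline
#' arc length; the clip value is the mean over valid frames.
#'
#' @param obs a `worm_observation`.
#' @return dimensionless amplitude, or NA with reason.
#' @export
body_amplitude <- function(obs) {
  vals <- numeric(0)
  for (cl in obs$centerlines) {
    if (is.null(cl) || nrow(cl) < 3) next
    len <- polyline_length(cl)
    if (len <= 0) next
    vals <- c(vals, chord_deviation(cl) / len)
  }
  if (!length(vals))
    return(structure(NA_real_, reason = "no valid centerline"))
  mean(vals)
}

# mid-body bend angle: signed angle between the anterior and posterior
# half chords of the centerline
bend_angle <- function(cl) {
  n <- nrow(cl)
  mid <- resample_polyline(cl, 3)   # endpoints + arc-length midpoint
  va <- mid[2, ] - mid[1, ]
  vp <- mid[3, ] - mid[2, ]
  atan2(va[1] * vp[2] - va[2] * vp[1], sum(va * vp))
}

#' Swimming frequency: dominant bend-angle oscillation
#'
#' The mid-body bend angle (angle between anterior and posterior half
#' chords) is tracked over the longest contiguous run of frames with
#' valid centerlines; after mean removal, the peak of the magnitude
#' spectrum gives the dominant frequency (resolution ~ 1/run duration,
#' capped at Nyquist). Flat series return 0.
#'
#' @param obs a `worm_observation`.
#' @param fps frames per second.
#' @param min_frames minimum contiguous valid frames (default 28, i.e.
#'   2 s at 14 fps).
#' @param noise_floor minimum bend-angle SD (radians) below which the
#'   series is considered flat.
#' @return frequency in Hz, NA with reason when the run is too short.
#' @export
swim_frequency <- function(obs, fps = obs$fps, min_frames = 28,
                           noise_floor = 0.02) {
  valid <- vapply(obs$centerlines, function(cl)
    !is.null(cl) && nrow(cl) >= 5, logical(1))
  if (length(valid) < length(obs$flags)) valid <- c(valid, rep(FALSE, length(obs$flags) - length(valid)))
  runs <- rle(valid)
  if (!any(runs$values & runs$lengths >= min_frames))
    return(structure(NA_real_, reason = sprintf(
      "no contiguous run of >= %d frames with valid centerlines", min_frames)))
  ends <- cumsum(runs$lengths)
  k <- which(runs$values & runs$lengths >= max(runs$lengths[runs$values]))[1]
  idx <- seq(ends[k] - runs$lengths[k] + 1, ends[k])
  ang <- vapply(obs$centerlines[idx], bend_angle, 0)
  if (sd(ang) < noise_floor) return(0)
  x <- ang - mean(ang)
  n <- length(x)
  mag <- Mod(fft(x))[2:floor(n / 2 + 1)]
  freqs <- (seq_along(mag)) * fps / n
  f <- freqs[which.max(mag)]
  min(f, fps / 2)
}

#' Compute all four clip metrics
#'
#' @param stack chamber-clip [frame_stack].
#' @param obs matching `worm_observation` (run [consensus_segment] first).
#' @param diff_threshold raw-movement pixel threshold (gray levels).
#' @param um_per_px optional pixel size for speed units.
#' @return one-row data.frame: raw_movement, centroid_speed,
#'   body_amplitude, swim_frequency, valid_frame_pairs.
#' @export
clip_metrics <- function(stack, obs, diff_threshold = 10, um_per_px = NULL) {
  ok <- obs$flags != "missing"
  data.frame(
    raw_movement = as.numeric(raw_movement(stack, diff_threshold)),
    centroid_speed = as.numeric(centroid_speed(obs, stack$fps, um_per_px)),
    body_amplitude = as.numeric(body_amplitude(obs)),
    swim_frequency = as.numeric(swim_frequency(obs, stack$fps)),
    valid_frame_pairs = sum(ok[-length(ok)] & ok[-1]))
}

#' Assemble longitudinal per-individual activity traces
#'
#' Joins per-clip metrics to the individual registry, converts timestamps
#' to days since adulthood day 0, applies analysis subsampling (default
#' one timepoint per 12 h, nearest clip within half an interval), and
#' drops censored individuals.
#'
#' @param metrics data.frame with columns chamber_id, time_hours (hours
#'   since adulthood day 0), one column per metric, optionally clip_label.
#' @param registry data.frame mapping chamber_id to individual_id with a
#'   logical `censored` column and optional condition columns.
#' @param subsample_hours analysis sampling interval (default 12 h);
#'   NULL keeps every clip.
#' @return long data.frame: individual_id, metric, time_days, value,
#'   clip_label and condition columns.
#' @export
assemble_traces <- function(metrics, registry, subsample_hours = 12) {
  stopifnot(all(c("chamber_id", "time_hours") %in% names(metrics)),
            all(c("chamber_id", "individual_id") %in% names(registry)))
  if (!"clip_label" %in% names(metrics)) metrics$clip_label <- "constant"
  key <- paste(metrics$chamber_id, metrics$time_hours, metrics$clip_label)
  if (anyDuplicated(key))
    stop("duplicate (chamber_id, timestamp, clip_label): ",
         key[duplicated(key)][1])
  if (!"censored" %in% names(registry)) registry$censored <- FALSE
  reg <- registry[!registry$censored, , drop = FALSE]
  merged <- merge(metrics, reg, by = "chamber_id")
  if (!is.null(subsample_hours)) {
    merged <- do.call(rbind, lapply(
      split(merged, list(merged$individual_id, merged$clip_label),
            drop = TRUE),
      function(df) {
        grid <- seq(0, max(df$time_hours), by = subsample_hours)
        picks <- vapply(grid, function(g) {
          d <- abs(df$time_hours - g)
          i <- order(d, df$time_hours)[1]
          if (d[i] <= subsample_hours / 2) i else NA_integer_
        }, integer(1))
        df[unique(picks[!is.na(picks)]), , drop = FALSE]
      }))
    rownames(merged) <- NULL
  }
  metric_cols <- intersect(c("raw_movement", "centroid_speed",
                             "body_amplitude", "swim_frequency"),
                           names(merged))
  cond_cols <- setdiff(names(registry),
                       c("chamber_id", "individual_id", "censored"))
  out <- do.call(rbind, lapply(metric_cols, function(mc) {
    df <- data.frame(individual_id = merged$individual_id, metric = mc,
                     time_days = merged$time_hours / HOURS_PER_DAY,
                     value = merged[[mc]], clip_label = merged$clip_label,
                     stringsAsFactors = FALSE)
    for (cc in cond_cols) df[[cc]] <- merged[[cc]]
    df
  }))
  out <- out[order(out$individual_id, out$metric, out$clip_label,
                   out$time_days), ]
  rownames(out) <- NULL
  out
}
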