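# Synthetic ground-truth generation: rendered worm clips and aging cohorts.
# Every artifact carries its generating parameters so downstream stages can
# be tested against truth rather than re-derived values.

#' Construct a sinusoidal worm pose
#'
#' The centerline is a single-wavelength sinusoid of lateral amplitude
#' `amplitude * body_length`, rescaled so its arc length equals
#' `body_length` and resampled to uniform point spacing.
#'
#' @param center (row, col) body midpoint in pixels.
#' @param orientation axis angle in radians (0 = along columns).
#' @param body_length worm arc length in pixels.
#' @param body_width worm width in pixels (must be < body_length).
#' @param phase undulation phase in radians.
#' @param amplitude undulation amplitude as a fraction of body length.
#' @param frequency undulation frequency in Hz (carried as ground truth).
#' @param n_points number of centerline points (>= 5).
#' @param wavelength_frac undulation wavelength as a fraction of body length.
#' @return object of class `worm_pose` with fields `centerline`,
#'   `body_length`, `body_width`, `phase`, `undulation_amplitude`,
#'   `undulation_frequency`.
#' @export
worm_pose <- function(center, orientation = 0, body_length = 40,
                      body_width = 6, phase = 0, amplitude = 0.1,
                      frequency = 0.5, n_points = 51, wavelength_frac = 1) {
  stopifnot(length(center) == 2, body_length > 0, body_width > 0,
            body_length > body_width, amplitude >= 0, n_points >= 5,
            wavelength_frac > 0)
  # dense axial parameterization, then arc-length normalization
  s <- seq(-0.5, 0.5, length.out = 20 * n_points)
  lateral <- amplitude * sin(2 * pi * s / wavelength_frac + phase)
  d <- c(sin(orientation), cos(orientation))    # (row, col) axis direction
  nrm <- c(d[2], -d[1])                         # unit normal
  raw <- cbind(s * d[1] + lateral * nrm[1], s * d[2] + lateral * nrm[2])
  raw <- raw * body_length / polyline_length(raw)
  cl <- resample_polyline(raw, n_points)
  # chord shortening from resampling: rescale so arc length is exact
  cl <- cl * body_length / polyline_length(cl)
  cl[, 1] <- cl[, 1] - mean(cl[, 1]) + center[1]
  cl[, 2] <- cl[, 2] - mean(cl[, 2]) + center[2]
  structure(list(centerline = cl, body_length = body_length,
                 body_width = body_width, phase = phase,
                 undulation_amplitude = amplitude,
                 undulation_frequency = frequency,
                 center = as.numeric(center), orientation = orientation,
                 wavelength_frac = wavelength_frac, n_points = n_points),
            class = "worm_pose")
}

#' Construct a circular chamber specification
#'
#' Describes one bright circular culture chamber (physical analogue
#' 1.5 mm diameter) on a dark field, with a background gray level that
#' stands in for food turbidity and additive sensor noise.
#'
#' @param diameter chamber diameter in pixels.
#' @param center (row, col) chamber center; default image center.
#' @param background_intensity interior gray level, 0--255.
#' @param noise_sd additive Gaussian noise SD in gray levels (>= 0).
#' @param image_shape c(rows, cols) of rendered frames; default square
#'   circumscribing the chamber with an 8 px margin.
#' @param outside_intensity gray level outside the chamber circle.
#' @return object of class `chamber_spec`.
#' @export
chamber_spec <- function(diameter, center = NULL, background_intensity = 200,
                         noise_sd = 0, image_shape = NULL,
                         outside_intensity = 20) {
  stopifnot(diameter > 0, noise_sd >= 0,
            background_intensity >= 0, background_intensity <= 255)
  if (is.null(image_shape)) image_shape <- rep(ceiling(diameter) + 16, 2)
  if (is.null(center)) center <- (image_shape + 1) / 2
  structure(list(center = as.numeric(center), diameter = diameter,
                 radius = diameter / 2,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, image_shape = as.integer(image_shape),
                 outside_intensity = outside_intensity),
            class = "chamber_spec")
}

quantize8 <- function(img) round(pmin(pmax(img, 0), 1) * 255) / 255

#' Render one grayscale frame of a worm in a chamber
#'
#' The worm is drawn as a stadium-shaped band of half-width
#' `body_width / 2` around the pose centerline, darker than the chamber
#' background, with a 1 px anti-aliased edge. Additive Gaussian noise of
#' the chamber's `noise_sd` is applied and the result quantized to 8-bit
#' gray levels.
#'
#' @param pose a [worm_pose] whose centerline must lie inside the chamber.
#' @param chamber a [chamber_spec].
#' @param seed optional integer; when given the noise stream is local and
#'   the output is bit-identical across calls.
#' @param worm_intensity worm gray level, 0--255; default 35% of background.
#' @return image matrix (rows x cols) in \[0, 1\].
#' @export
render_frame <- function(pose, chamber, seed = NULL, worm_intensity = NULL) {
  stopifnot(inherits(pose, "worm_pose"), inherits(chamber, "chamber_spec"))
  cl <- pose$centerline
  dc <- sqrt((cl[, 1] - chamber$center[1])^2 +
             (cl[, 2] - chamber$center[2])^2)
  if (any(dc > chamber$radius)) {
    i <- which.max(dc)
    stop(sprintf(
      "pose centerline point %d at (%.1f, %.1f) lies outside the chamber (distance %.1f > radius %.1f)",
      i, cl[i, 1], cl[i, 2], dc[i], chamber$radius))
  }
  if (is.null(worm_intensity)) worm_intensity <- 0.35 * chamber$background_intensity
  sh <- chamber$image_shape
  rows <- matrix(seq_len(sh[1]), sh[1], sh[2])
  cols <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  inside <- (rows - chamber$center[1])^2 + (cols - chamber$center[2])^2 <=
    chamber$radius^2
  img <- matrix(chamber$outside_intensity / 255, sh[1], sh[2])
  img[inside] <- chamber$background_intensity / 255

  d <- dist_to_polyline(rows, cols, cl)
  # anti-aliased stadium band: full worm intensity inside half-width,
  # linear 1 px ramp at the boundary
  cover <- pmin(pmax(pose$body_width / 2 - d + 0.5, 0), 1)
  wi <- worm_intensity / 255
  img <- img * (1 - cover) + wi * cover
  img[!inside & cover == 0] <- chamber$outside_intensity / 255

  with_local_seed(seed, {
    if (chamber$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, chamber$noise_sd / 255),
                          nrow(img))
    quantize8(img)
  })
}

# distance from every pixel to a polyline (minimum over segments)
dist_to_polyline <- function(rows, cols, cl) {
  d2 <- matrix(Inf, nrow(rows), ncol(rows))
  for (i in seq_len(nrow(cl) - 1)) {
    a <- cl[i, ]; b <- cl[i + 1, ]
    v <- b - a
    vv <- sum(v^2)
    if (vv < .Machine$double.eps) next
    t <- ((rows - a[1]) * v[1] + (cols - a[2]) * v[2]) / vv
    t <- pmin(pmax(t, 0), 1)
    d2 <- pmin(d2, (rows - (a[1] + t * v[1]))^2 + (cols - (a[2] + t * v[2]))^2)
  }
  sqrt(d2)
}

#' Generate a ground-truthed clip of an undulating, drifting worm
#'
#' Phase advances by `2 * pi * frequency / fps` per frame; the body
#' midpoint follows a linear drift. Frames are rendered with
#' [render_frame]; per-frame true poses are returned alongside.
#'
#' @param pose starting [worm_pose].
#' @param chamber a [chamber_spec].
#' @param n_frames number of frames (>= 2); 140 frames at the default
#'   14 fps gives the nominal 10 s clip.
#' @param fps acquisition rate in Hz.
#' @param drift per-frame (row, col) centroid displacement in pixels.
#' @param seed integer seed controlling the noise stream.
#' @param acquired_at optional POSIXct acquisition time.
#' @param device_id,chamber_id identifiers carried into the stack.
#' @return a [frame_stack] with attribute-style fields `poses` (list of
#'   per-frame `worm_pose`) and `chamber`.
#' @export
generate_clip <- function(pose, chamber, n_frames = 140, fps = 14,
                          drift = c(0, 0), seed = NULL, acquired_at = NULL,
                          device_id = "sim", chamber_id = "c01") {
  stopifnot(n_frames >= 2, fps > 0, length(drift) == 2)
  centers <- cbind(pose$center[1] + drift[1] * (seq_len(n_frames) - 1),
                   pose$center[2] + drift[2] * (seq_len(n_frames) - 1))
  dmax <- sqrt((centers[, 1] - chamber$center[1])^2 +
               (centers[, 2] - chamber$center[2])^2)
  if (any(dmax + pose$body_length / 2 > chamber$radius))
    stop("drift path exits the chamber: reduce drift or n_frames")
  poses <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  with_local_seed(seed, {
    for (i in seq_len(n_frames)) {
      ph <- pose$phase + 2 * pi * pose$undulation_frequency * (i - 1) / fps
      poses[[i]] <- worm_pose(centers[i, ], pose$orientation,
                              pose$body_length, pose$body_width, ph,
                              pose$undulation_amplitude,
                              pose$undulation_frequency, pose$n_points,
                              pose$wavelength_frac)
      frames[[i]] <- render_frame(poses[[i]], chamber, seed = NULL)
    }
  })
  st <- frame_stack(frames, fps = fps, acquired_at = acquired_at,
                    device_id = device_id, chamber_id = chamber_id)
  st$poses <- poses
  st$chamber <- chamber
  st
}

#' Aging profile: ground truth for one individual's activity trace
#'
#' Encodes the two-phase behavioral decline: a high-activity period up to
#' `high_activity_end`, then sporadic low-activity movement until
#' `death_time`, then exact zero.
#'
#' @param death_time death time in days (> 0).
#' @param high_activity_end end of the high-activity phase in days
#'   (0 < value <= death_time).
#' @param high_level,low_level metric levels (high > low >= 0).
#' @param low_burst_prob probability a low-phase sample shows movement.
#'   1 means continuous low-level movement up to death ("burst-free"
#'   recovery regime); values < 1 give sporadic bursts.
#' @param noise_sd SD of multiplicative-free additive noise on the high
#'   phase (metric units).
#' @param rng_seed integer recorded with the profile.
#' @export
aging_profile <- function(death_time, high_activity_end,
                          high_level = 1, low_level = 0.1,
                          low_burst_prob = 0.5, noise_sd = 0,
                          rng_seed = NA_integer_) {
  stopifnot(death_time > 0, high_activity_end > 0,
            high_activity_end <= death_time,
            high_level > low_level, low_level >= 0,
            low_burst_prob >= 0, low_burst_prob <= 1, noise_sd >= 0)
  structure(list(death_time = death_time,
                 high_activity_end = high_activity_end,
                 high_level = high_level, low_level = low_level,
                 low_burst_prob = low_burst_prob, noise_sd = noise_sd,
                 rng_seed = rng_seed),
            class = "aging_profile")
}

#' Default profile sampler: lognormal lifespans around 18 days
#'
#' Death times are lognormal with mean 18 d (CV 25%, the scale of
#' wild-type variability at 25 C); the high-activity phase ends at a
#' Beta(8, 4)-distributed fraction of life (mean 2/3).
#'
#' @param mean_lifespan mean death time in days.
#' @param cv coefficient of variation of death times.
#' @param low_burst_prob probability of movement per low-phase sample.
#' @param noise_sd high-phase noise SD (metric units).
#' @return function(i) -> [aging_profile], drawing from the current RNG.
#' @export
profile_sampler <- function(mean_lifespan = 18, cv = 0.25,
                            low_burst_prob = 0.5, noise_sd = 0.05) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_lifespan) - sdlog^2 / 2
  function(i) {
    death <- rlnorm(1, meanlog, sdlog)
    frac <- stats::rbeta(1, 8, 4)
    aging_profile(death_time = death,
                  high_activity_end = max(frac * death, 0.5),
                  high_level = 1, low_level = 0.1,
                  low_burst_prob = low_burst_prob, noise_sd = noise_sd,
                  rng_seed = i)
  }
}

#' Generate a synthetic aging cohort of activity traces with ground truth
#'
#' Each individual's trace samples its [aging_profile] every
#' `sampling_interval` hours: high level (plus noise, floored at half the
#' low level so live samples stay positive) through `high_activity_end`,
#' Bernoulli(`low_burst_prob`) bursts at `low_level` until `death_time`,
#' and exactly zero strictly after death.
#'
#' @param n_individuals cohort size (>= 1).
#' @param sampler function(i) returning an [aging_profile]; default
#'   [profile_sampler()].
#' @param sampling_interval hours between samples (default 12 h).
#' @param seed integer seed; the cohort is a pure function of
#'   (parameters, seed).
#' @param horizon_days trace end; default max death + 4 d on the grid.
#' @param condition label copied into truth records.
#' @return object of class `worm_cohort`: `traces` (long data.frame:
#'   individual_id, time_days, metric, value), `truth` (data.frame:
#'   individual_id, death_time_days, high_activity_end_days, condition),
#'   `profiles` (list), `sampling_interval_hours`.
#' @export
generate_cohort <- function(n_individuals, sampler = profile_sampler(),
                            sampling_interval = 12, seed = 1,
                            horizon_days = NULL, condition = "synthetic") {
  stopifnot(n_individuals >= 1, sampling_interval > 0)
  with_local_seed(seed, {
    profiles <- lapply(seq_len(n_individuals), sampler)
    dt <- sampling_interval / HOURS_PER_DAY
    if (is.null(horizon_days))
      horizon_days <- ceiling((max(vapply(profiles, `[[`, 0, "death_time")) + 4) / dt) * dt
    times <- seq(0, horizon_days, by = dt)
    traces <- vector("list", n_individuals)
    truth <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      p <- profiles[[i]]
      v <- sample_profile(p, times)
      id <- sprintf("sim%03d", i)
      traces[[i]] <- data.frame(individual_id = id, time_days = times,
                                metric = "raw_movement", value = v,
                                stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(individual_id = id,
                               death_time_days = p$death_time,
                               high_activity_end_days = p$high_activity_end,
                               high_level = p$high_level,
                               low_level = p$low_level,
                               low_burst_prob = p$low_burst_prob,
                               condition = condition,
                               stringsAsFactors = FALSE)
    }
    structure(list(traces = do.call(rbind, traces),
                   truth = do.call(rbind, truth),
                   profiles = profiles,
                   sampling_interval_hours = sampling_interval,
                   seed = seed),
              class = "worm_cohort")
  })
}

# evaluate one profile on a time grid (days); draws from the current RNG
sample_profile <- function(p, times) {
  v <- numeric(length(times))
  high <- times <= p$high_activity_end
  low <- !high & times <= p$death_time
  if (any(high)) {
    x <- p$high_level + rnorm(sum(high), 0, p$noise_sd)
    v[high] <- pmax(x, p$low_level / 2)   # live samples stay positive
  }
  if (any(low))
    v[low] <- p$low_level * rbinom(sum(low), 1, p$low_burst_prob)
  v
}

#' @export
print.worm_cohort <- function(x, ...) {
  cat(sprintf("worm_cohort: %d individuals, %d samples each (every %g h)\n",
              nrow(x$truth), length(unique(x$traces$time_days)),
              x$sampling_interval_hours))
  cat(sprintf("  true death times: %.1f - %.1f d (mean %.1f)\n",
              min(x$truth$death_time_days), max(x$truth$death_time_days),
              mean(x$truth$death_time_days)))
  invisible(x)
}

# --- serialization ----------------------------------------------------------

#' Write activity traces as long-format CSV
#'
#' Columns: individual_id, time_days, metric, value (missing encoded NA),
#' plus any extra columns present (clip_label, condition labels).
#' @param traces long data.frame of traces.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(all(c("individual_id", "time_days", "metric", "value") %in%
                names(traces)))
  write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "time_days", "metric", "value") %in%
                names(tr)))
  tr
}

#' Write a clip as an 8-bit multi-page TIFF
#' @param stack a [frame_stack] (or list of frames).
#' @param path output .tif path.
#' @export
write_clip_tiff <- function(stack, path) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  tiff::writeTIFF(lapply(frames, quantize8), path, bits.per.sample = 8L)
  invisible(path)
}
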