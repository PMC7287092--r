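# End-to-end synthetic pipeline: aging cohorts realized as rendered
# chamber clips, pushed through segmentation, metrics and death calling,
# and compared against generating truth.

# map an activity level (metric units; high_level ~ 1) to worm motion:
# drift speed saturates at 2 px/frame, undulation frequency at 1.5 Hz
activity_to_motion <- function(level) {
  a <- pmin(pmax(level, 0), 1.5)
  list(drift = 1.0 + 1.0 * pmin(a, 1),        # px/frame while moving
       freq = 1.5 * pmin(a, 1),               # Hz
       amplitude = 0.04 + 0.06 * pmin(a, 1))  # fraction of body length
}

#' Run the full synthetic video pipeline against ground truth
#'
#' For each individual, an [aging_profile] drives rendered chamber clips
#' at every sampling timepoint: while the profile says the worm moves,
#' the rendered worm drifts and undulates in proportion to its activity
#' level; after death it is static. Clips are segmented with
#' [consensus_segment], per-clip metrics extracted, raw-movement traces
#' assembled, the detection floor estimated from rendered empty-chamber
#' clips, and deaths called with the two-day cessation rule.
#'
#' @param n_individuals number of individuals.
#' @param n_timepoints timepoints per individual (every
#'   `sampling_interval` hours).
#' @param sampling_interval hours between timepoints (default 12).
#' @param frames_per_clip frames per rendered clip (default 6; short
#'   clips keep the suite fast while giving 5 frame pairs).
#' @param fps frames per second (default 14).
#' @param chamber_px rendered frame side in pixels (default 128).
#' @param noise_sd sensor noise SD in gray levels (default 2).
#' @param sampler profile sampler; default lifespans fit inside the
#'   monitored window (mean 11 d, CV 0.2).
#' @param seed master seed; everything derives from it.
#' @param confirmation_window death-confirmation window in days.
#' @return list: `truth` (generating records), `called` (lifespan
#'   records from the video pipeline), `traces` (measured raw-movement
#'   traces), `activity_threshold`, `segmentation` (per-clip IoU and
#'   centroid RMSE summaries when poses allow).
#' @export
run_synthetic_pipeline <- function(n_individuals = 20, n_timepoints = 40,
                                   sampling_interval = 12,
                                   frames_per_clip = 6, fps = 14,
                                   chamber_px = 128, noise_sd = 2,
                                   sampler = NULL, seed = 1,
                                   confirmation_window = 2) {
  dt_days <- sampling_interval / HOURS_PER_DAY
  horizon <- (n_timepoints - 1) * dt_days
  if (is.null(sampler))
    sampler <- profile_sampler(mean_lifespan = 0.55 * horizon, cv = 0.2,
                               low_burst_prob = 1, noise_sd = 0.05)
  chamber <- chamber_spec(diameter = chamber_px - 16,
                          image_shape = c(chamber_px, chamber_px),
                          background_intensity = 200, noise_sd = noise_sd)
  times <- (seq_len(n_timepoints) - 1) * dt_days

  with_local_seed(seed, {
    profiles <- lapply(seq_len(n_individuals), sampler)

    # detection floor from rendered empty-chamber clips
    empty_vals <- vapply(1:5, function(i) {
      frames <- lapply(seq_len(frames_per_clip), function(j)
        render_empty(chamber))
      st <- frame_stack(frames, fps = fps)
      st$chamber_geom <- chamber_geom_of(chamber)
      as.numeric(raw_movement(st))
    }, numeric(1))
    thr <- estimate_activity_threshold(empty_vals)

    rows <- list()
    seg_iou <- numeric(0); seg_rmse <- numeric(0)
    last_moving <- numeric(n_individuals)
    for (i in seq_len(n_individuals)) {
      p <- profiles[[i]]
      # activity level at each timepoint (same regimes as generate_cohort)
      lv <- sample_profile(p, times)
      last_moving[i] <- if (any(lv > 0)) max(times[lv > 0]) else NA_real_
      prior <- morph_prior(update_weight = 0.2)
      orient <- runif(1, 0, pi)
      for (k in seq_len(n_timepoints)) {
        mo <- activity_to_motion(lv[k])
        moving <- lv[k] > 0
        drift_dir <- runif(1, 0, 2 * pi)
        drift <- if (moving)
          mo$drift * c(sin(drift_dir), cos(drift_dir)) else c(0, 0)
        start <- chamber$center + runif(2, -0.15, 0.15) * chamber$radius
        pose <- worm_pose(start, orientation = orient + runif(1, -0.3, 0.3),
                          body_length = 40, body_width = 6,
                          phase = runif(1, 0, 2 * pi),
                          amplitude = if (moving) mo$amplitude else 0.04,
                          frequency = if (moving) mo$freq else 0)
        clip <- generate_clip(pose, chamber, n_frames = frames_per_clip,
                              fps = fps, drift = drift,
                              chamber_id = sprintf("c%02d", i))
        clip$chamber_geom <- chamber_geom_of(chamber)
        obs <- consensus_segment(clip, prior, skeletons = FALSE)
        prior <- update_prior(prior, obs)
        met <- clip_metrics(clip, obs)
        # segmentation quality vs ground truth on a subsample
        if (k %% 10 == 1) {
          q <- segmentation_quality(clip, obs)
          seg_iou <- c(seg_iou, q$iou)
          seg_rmse <- c(seg_rmse, q$rmse)
        }
        rows[[length(rows) + 1]] <- data.frame(
          chamber_id = sprintf("c%02d", i), time_hours = times[k] * HOURS_PER_DAY,
          raw_movement = met$raw_movement, centroid_speed = met$centroid_speed,
          stringsAsFactors = FALSE)
      }
    }
    metrics <- do.call(rbind, rows)
    registry <- data.frame(chamber_id = sprintf("c%02d", seq_len(n_individuals)),
                           individual_id = sprintf("sim%03d", seq_len(n_individuals)),
                           censored = FALSE, stringsAsFactors = FALSE)
    traces <- assemble_traces(metrics, registry,
                              subsample_hours = sampling_interval)
    called <- call_deaths(traces, activity_threshold = thr,
                          confirmation_window = confirmation_window)
    truth <- data.frame(
      individual_id = sprintf("sim%03d", seq_len(n_individuals)),
      death_time_days = vapply(profiles, `[[`, 0, "death_time"),
      high_activity_end_days = vapply(profiles, `[[`, 0, "high_activity_end"),
      low_burst_prob = vapply(profiles, `[[`, 0, "low_burst_prob"),
      stringsAsFactors = FALSE)
    # the true death time snapped to the sampling grid: the scoring
    # reference ("generated truth" at the pipeline's time resolution)
    truth$death_grid_days <- vapply(truth$death_time_days, function(d)
      max(times[times <= d]), numeric(1))
    # the last sampling time at which the worm actually moved (equals
    # death_grid_days for burst-free traces)
    truth$last_moving_sample <- last_moving
    list(truth = truth, called = called, traces = traces,
         activity_threshold = thr,
         segmentation = list(mean_iou = mean(seg_iou),
                             centroid_rmse = mean(seg_rmse)))
  })
}

render_empty <- function(chamber) {
  sh <- chamber$image_shape
  rows <- matrix(seq_len(sh[1]), sh[1], sh[2])
  cols <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  inside <- (rows - chamber$center[1])^2 + (cols - chamber$center[2])^2 <=
    chamber$radius^2
  img <- matrix(chamber$outside_intensity / 255, sh[1], sh[2])
  img[inside] <- chamber$background_intensity / 255
  if (chamber$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, chamber$noise_sd / 255), sh[1])
  quantize8(img)
}

chamber_geom_of <- function(chamber) {
  sh <- chamber$image_shape
  rows <- matrix(seq_len(sh[1]), sh[1], sh[2])
  cols <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  list(center = chamber$center, radius = chamber$radius,
       inside = (rows - chamber$center[1])^2 +
         (cols - chamber$center[2])^2 <= chamber$radius^2)
}

# IoU of chosen masks vs ground-truth rendered masks; centroid RMSE
segmentation_quality <- function(clip, obs) {
  ious <- numeric(0); errs <- numeric(0)
  for (i in seq_along(clip$poses)) {
    if (obs$flags[i] != "ok") next
    truth_mask <- pose_mask(clip$poses[[i]], dim(clip$frames[[1]]))
    inter <- sum(truth_mask & obs$masks[[i]])
    uni <- sum(truth_mask | obs$masks[[i]])
    if (uni > 0) ious <- c(ious, inter / uni)
    tc <- colMeans(which(truth_mask, arr.ind = TRUE))
    errs <- c(errs, sum((obs$centroids[i, ] - tc)^2))
  }
  list(iou = if (length(ious)) mean(ious) else NA_real_,
       rmse = if (length(errs)) sqrt(mean(errs)) else NA_real_)
}

#' Ground-truth binary mask of a pose
#' @param pose a [worm_pose].
#' @param shape c(rows, cols).
#' @return logical matrix: pixels within body_width/2 of the centerline.
#' @export
pose_mask <- function(pose, shape) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dist_to_polyline(rows, cols, pose$centerline) <= pose$body_width / 2
}

#' Compare called deaths with generating truth
#'
#' @param result output of [run_synthetic_pipeline].
#' @return list(n, exact_fraction, median_abs_error_days): errors are
#'   measured against the true death time snapped to the sampling grid.
#' @export
score_death_calls <- function(result) {
  m <- merge(result$called, result$truth, by = "individual_id")
  err <- abs(m$death_time_days.x - m$death_grid_days)
  list(n = nrow(m),
       exact_fraction = mean(err == 0, na.rm = TRUE),
       median_abs_error_days = median(err, na.rm = TRUE))
}
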