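test_that("raw movement matches the brute-force changed-pixel fraction", {
  # identical frames -> 0
  f <- matrix(0.5, 100, 100)
  st <- make_stack(list(f, f, f))
  expect_equal(raw_movement(st), 0)

  # 200-px worm translating to a disjoint location each frame in a
  # 10,000-px chamber: 400 changed pixels -> 0.04
  worm_at <- function(r0) {
    m <- matrix(200 / 255, 100, 100)
    m[r0:(r0 + 9), 11:30] <- 50 / 255   # 10 x 20 = 200 px
    m
  }
  frames <- list(worm_at(10), worm_at(40), worm_at(70))
  st2 <- make_stack(frames)
  expect_equal(raw_movement(st2), 0.04)
  # brute force oracle on the same frames
  brute <- mean(c(sum(abs(frames[[2]] - frames[[1]]) > 10 / 255),
                  sum(abs(frames[[3]] - frames[[2]]) > 10 / 255))) / 1e4
  expect_equal(raw_movement(st2), brute)

  # frame reversal symmetry
  st_rev <- make_stack(rev(frames))
  expect_equal(raw_movement(st_rev), raw_movement(st2))

  # uniform offsets below the threshold do not register
  st_off <- make_stack(list(f, f + 5 / 255, f))
  expect_equal(raw_movement(st_off), 0)

  # pairs containing invalid frames are excluded
  expect_equal(raw_movement(st2, valid_frames = c(TRUE, FALSE, TRUE)),
               NA_real_, ignore_attr = TRUE)
})

test_that("centroid speed follows displacement arithmetic and skips gaps", {
  # static worm
  obs <- make_obs(centroids = matrix(rep(c(50, 50), 5), 5, 2, byrow = TRUE))
  expect_equal(centroid_speed(obs, fps = 14), 0)
  # constant drift 2 px/frame at 14 fps -> 28 px/s
  tr <- cbind(seq(10, 18, by = 2), rep(20, 5))
  obs2 <- make_obs(centroids = tr)
  expect_equal(centroid_speed(obs2, fps = 14), 28)
  # micron conversion
  expect_equal(centroid_speed(obs2, fps = 14, um_per_px = 10), 280)
  # a missing middle frame: spanning pairs excluded, speed unchanged
  obs3 <- make_obs(centroids = rbind(tr[1:2, ], c(NA, NA), tr[4:5, ]),
                   flags = c("ok", "ok", "missing", "ok", "ok"))
  expect_equal(centroid_speed(obs3, fps = 14), 28)
  # fewer than 2 accepted centroids -> missing with reason
  obs4 <- make_obs(centroids = matrix(c(1, 1), 1, 2))
  expect_true(is.na(centroid_speed(obs4, fps = 14)))
})

test_that("body amplitude matches circle geometry and ranks sinusoids", {
  # straight centerline -> ~0
  straight <- cbind(seq(10, 60), rep(30, 51))
  expect_lt(body_amplitude(make_obs(centerlines = list(straight))), 0.02)
  # semicircular worm: deviation r over arc pi*r -> 1/pi
  th <- seq(0, pi, length.out = 120)
  rows <- matrix(seq_len(120), 120, 120)
  semi <- wormspan:::dist_to_polyline(rows, t(rows),
                                      cbind(60 + 30 * cos(th),
                                            60 + 30 * sin(th))) <= 3
  sk <- skeletonize_mask(semi)
  a <- body_amplitude(make_obs(centerlines = list(sk)))
  expect_equal(a, 1 / pi, tolerance = 0.1)
  # rendered sinusoids: measured amplitude increases with true amplitude
  ch <- test_chamber()
  vals <- vapply(c(0.05, 0.1, 0.2), function(af) {
    img <- render_frame(worm_pose(center = c(64, 64), amplitude = af,
                                  phase = pi / 2), ch)
    m <- img < (0.35 * 200 / 255 + 0.02)
    body_amplitude(make_obs(centerlines = list(skeletonize_mask(m))))
  }, 0)
  expect_true(all(diff(vals) > 0))
  # no centerline -> missing
  expect_true(is.na(body_amplitude(make_obs(centerlines = list(NULL)))))
})

test_that("swimming frequency recovers the generating frequency within a bin", {
  ch <- test_chamber()
  rec <- vapply(c(0.25, 0.5, 1, 2), function(f) {
    clip <- generate_clip(worm_pose(center = c(64, 64), amplitude = 0.1,
                                    frequency = f),
                          ch, n_frames = 140, fps = 14, seed = 6)
    clip$chamber_geom <- chamber_geom(ch)
    obs <- consensus_segment(clip)
    swim_frequency(obs, 14)
  }, 0)
  expect_true(all(abs(rec - c(0.25, 0.5, 1, 2)) <= 0.1))
  # relative ordering preserved
  expect_true(all(diff(rec) > 0))
  # static worm -> 0
  clip0 <- generate_clip(worm_pose(center = c(64, 64), amplitude = 0.1,
                                   frequency = 0),
                         ch, n_frames = 30, fps = 14)
  clip0$chamber_geom <- chamber_geom(ch)
  expect_equal(swim_frequency(consensus_segment(clip0), 14), 0)
  # insufficient valid frames -> missing with reason
  short_obs <- make_obs(centerlines = rep(list(NULL), 30))
  expect_true(is.na(swim_frequency(short_obs, 14)))
})

test_that("clip metrics respect a uniform sub-threshold intensity offset", {
  ch <- test_chamber()
  clip <- generate_clip(worm_pose(center = c(64, 64), amplitude = 0.1,
                                  frequency = 1),
                        ch, n_frames = 10, fps = 14, drift = c(0.5, 0))
  clip$chamber_geom <- chamber_geom(ch)
  shifted <- clip
  shifted$frames <- lapply(clip$frames, function(f) f + 4 / 255)
  expect_equal(raw_movement(shifted), raw_movement(clip))
})

test_that("trace assembly subsamples, drops censored, rejects duplicates", {
  # 2 clips/h over 2 days, 12-h subsampling -> 5 samples
  times_h <- seq(0, 48, by = 0.5)
  metrics <- data.frame(chamber_id = "c01", time_hours = times_h,
                        raw_movement = seq_along(times_h) / 100)
  registry <- data.frame(chamber_id = c("c01", "c02"),
                         individual_id = c("w1", "w2"),
                         censored = c(FALSE, TRUE))
  tr <- assemble_traces(metrics, registry, subsample_hours = 12)
  expect_equal(tr$time_days, c(0, 0.5, 1, 1.5, 2))
  expect_false("w2" %in% tr$individual_id)
  dup <- rbind(metrics, metrics[1, ])
  expect_error(assemble_traces(dup, registry), "duplicate")
})

test_that("metrics pipeline recovers ground-truth activity ordering end to end", {
  ch <- test_chamber(noise_sd = 2)
  levels <- c(0, 0.2, 0.5, 1)
  measured <- vapply(levels, function(a) {
    mo <- wormspan:::activity_to_motion(a)
    moving <- a > 0
    pose <- worm_pose(center = c(64, 64),
                      amplitude = if (moving) mo$amplitude else 0.04,
                      frequency = if (moving) mo$freq else 0)
    clip <- generate_clip(pose, ch, n_frames = 6, fps = 14,
                          drift = if (moving) c(mo$drift, 0) else c(0, 0),
                          seed = 31)
    clip$chamber_geom <- chamber_geom(ch)
    as.numeric(raw_movement(clip))
  }, 0)
  expect_true(all(diff(measured) > 0))
  expect_gt(cor(levels, measured), 0.8)
})
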