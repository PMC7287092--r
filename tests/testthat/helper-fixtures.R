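# Shared fixture builders: all synthetic, constructed at test time.

# device image with bright circular chambers on a dark field
make_device_image <- function(centers, radius, shape,
                              background = 200, outside = 20) {
  img <- matrix(outside / 255, shape[1], shape[2])
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (i in seq_len(nrow(centers)))
    img[(rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= radius^2] <-
      background / 255
  img
}

# standard small test chamber (128 px frame, 112 px chamber)
test_chamber <- function(noise_sd = 0, background = 200) {
  chamber_spec(diameter = 112, image_shape = c(128, 128),
               background_intensity = background, noise_sd = noise_sd)
}

chamber_geom <- function(chamber) wormspan:::chamber_geom_of(chamber)

# minimal worm_observation carrying given centerlines/centroids
make_obs <- function(centerlines = NULL, centroids = NULL, flags = NULL,
                     fps = 14) {
  n <- max(length(centerlines), nrow(centroids), length(flags))
  if (is.null(flags)) flags <- rep("ok", n)
  if (is.null(centroids)) centroids <- matrix(NA_real_, n, 2)
  if (is.null(centerlines)) centerlines <- vector("list", n)
  structure(list(n = n, masks = vector("list", n), centroids = centroids,
                 centerlines = centerlines, flags = flags,
                 frame_stats = vector("list", n), fps = fps,
                 chamber_id = "test"),
            class = "worm_observation")
}

# frame stack from a list of matrices with an all-inside chamber geometry
make_stack <- function(frames, fps = 14) {
  st <- frame_stack(frames, fps = fps)
  d <- dim(frames[[1]])
  st$chamber_geom <- list(center = (d + 1) / 2, radius = max(d),
                          inside = matrix(TRUE, d[1], d[2]))
  st
}

# independent product-limit estimator (hand oracle for Kaplan-Meier)
hand_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times[events]))
  s <- 1
  out <- data.frame(time = ut, survival = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# independent two-group log-rank statistic (hand oracle)
hand_logrank <- function(t1, t2) {
  times <- c(t1, t2); grp <- rep(1:2, c(length(t1), length(t2)))
  ut <- sort(unique(times))
  o1 <- e1 <- v1 <- 0
  for (t in ut) {
    n <- sum(times >= t); n1 <- sum(times >= t & grp == 1)
    d <- sum(times == t); d1 <- sum(times == t & grp == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v1
}
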