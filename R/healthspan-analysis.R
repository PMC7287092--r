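# Healthspan phase classification (k-means on pooled condition data, or
# per-individual moving average), intrapopulation cohorts, relative-life
# trajectories, trajectory PCA, and cohort decline comparison.

#' Classify high/low activity phases by pooled k-means
#'
#' All sample values of the condition are pooled and clustered with
#' k = 2; the cluster with the higher mean is "high activity". Per
#' individual, the high-activity phase ends at the time of its last
#' high-assigned sample. Suited to metrics with well-separated high/low
#' regimes (raw movement, centroid speed, swimming frequency).
#'
#' @param traces long data.frame (individual_id, metric, time_days,
#'   value) for one experimental condition.
#' @param metric which metric to classify on.
#' @param lifespans data.frame (individual_id, death_time_days) used for
#'   duration/fraction; individuals without a lifespan are dropped.
#' @param seed k-means seed (fixed restarts make calls deterministic).
#' @param nstart k-means restarts (default 10).
#' @param debounce if > 0, isolated runs of at most `debounce` high
#'   samples occurring after >= 3 consecutive low samples are ignored
#'   when locating the last high sample (guards against sporadic
#'   low-phase bursts); default 0 (off) for exactness.
#' @return `phase_calls` data.frame: individual_id, metric,
#'   high_activity_end, duration_high, fraction_high.
#' @export
classify_phases_kmeans <- function(traces, metric = "raw_movement",
                                   lifespans, seed = 1, nstart = 10,
                                   debounce = 0) {
  tr <- traces[traces$metric == metric & !is.na(traces$value), , drop = FALSE]
  if (!nrow(tr)) stop("no samples for metric ", metric)
  vals <- tr$value
  if (length(unique(vals)) < 2)
    stop("degenerate pooled data: all sample values equal")
  km <- with_local_seed(seed, kmeans(vals, centers = 2, nstart = nstart))
  high_cluster <- which.max(km$centers)
  tr$high <- km$cluster == high_cluster
  out <- do.call(rbind, lapply(split(tr, tr$individual_id), function(df) {
    df <- df[order(df$time_days), ]
    high <- df$high
    if (debounce > 0) high <- debounce_high(high, debounce)
    if (!any(high)) {
      end <- 0
    } else {
      end <- df$time_days[max(which(high))]
    }
    data.frame(individual_id = df$individual_id[1], metric = metric,
               high_activity_end = end, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  finalize_phase_calls(out, lifespans)
}

# drop isolated high runs (length <= debounce) that follow >= 3 lows
debounce_high <- function(high, debounce) {
  r <- rle(high)
  n <- length(r$lengths)
  prev_low3 <- c(FALSE, r$values[-n] == FALSE & r$lengths[-n] >= 3)
  kill <- r$values & r$lengths <= debounce & prev_low3
  r$values[kill] <- FALSE
  inverse.rle(r)
}

finalize_phase_calls <- function(calls, lifespans) {
  m <- merge(calls, lifespans[, c("individual_id", "death_time_days")],
             by = "individual_id")
  m$duration_high <- pmin(m$high_activity_end, m$death_time_days)
  m$fraction_high <- m$duration_high / m$death_time_days
  m$fraction_high <- pmin(pmax(m$fraction_high, 0), 1)
  out <- m[, c("individual_id", "metric", "high_activity_end",
               "duration_high", "fraction_high")]
  class(out) <- c("phase_calls", "data.frame")
  out
}

#' Classify phases by the moving-average-below-mean rule
#'
#' Tracks the centered moving average of one individual's trace and
#' reports the first time it falls below the individual's whole-life mean
#' and stays below through trace end. Suited to metrics with subtle
#' decline (body amplitude).
#'
#' @param time_days,values one individual's trace (time-sorted).
#' @param window moving-average window in samples (default 5, i.e. 2.5 d
#'   at 12-h sampling); must not exceed the trace length.
#' @return list(high_activity_end, flagged): `flagged` is TRUE when the
#'   moving average never falls below the mean (the whole trace counts as
#'   high activity and `high_activity_end` is the last sample time).
#' @export
classify_phases_moving_average <- function(time_days, values, window = 5) {
  stopifnot(length(time_days) == length(values), window >= 1,
            length(values) >= window)
  ord <- order(time_days)
  time_days <- time_days[ord]; values <- values[ord]
  ma <- stats::filter(values, rep(1 / window, window), sides = 2)
  ma <- as.numeric(ma)
  # edge samples without a full window use the available partial window
  half <- (window - 1) %/% 2
  n <- length(values)
  for (i in which(is.na(ma))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    ma[i] <- mean(values[lo:hi])
  }
  mu <- mean(values)
  below <- ma < mu
  # first index from which `below` holds through trace end
  idx <- NA_integer_
  run <- rev(cumprod(rev(below)))   # 1 where below holds to the end
  if (any(run == 1)) idx <- which(run == 1)[1]
  if (is.na(idx))
    list(high_activity_end = time_days[n], flagged = TRUE)
  else
    list(high_activity_end = time_days[idx], flagged = FALSE)
}

#' Split one condition into shortest- and longest-lived cohorts
#'
#' Bottom and top `percentile`% of uncensored individuals by death time;
#' ties at the boundary are all included.
#'
#' @param records lifespan records data.frame.
#' @param percentile cohort size in percent (default 20).
#' @param min_n minimum uncensored individuals required (default 5).
#' @return list(shortest, longest, flagged): each a records subset;
#'   `flagged` is TRUE when the cohorts coincide (e.g. all-equal
#'   lifespans).
#' @export
define_cohorts <- function(records, percentile = 20, min_n = 5) {
  unc <- records[!records$censored, , drop = FALSE]
  n <- nrow(unc)
  if (n < min_n)
    stop("need at least ", min_n, " uncensored individuals, have ", n)
  k <- ceiling(percentile / 100 * n)
  d <- sort(unc$death_time_days)
  lo_cut <- d[k]
  hi_cut <- d[n - k + 1]
  shortest <- unc[unc$death_time_days <= lo_cut, , drop = FALSE]
  longest <- unc[unc$death_time_days >= hi_cut, , drop = FALSE]
  flagged <- nrow(shortest) == n || nrow(longest) == n
  list(shortest = shortest, longest = longest, flagged = flagged)
}

#' Relative-lifespan trajectory: metric averaged over equal life bins
#'
#' Rescales the trace to relative life t/lifespan and averages samples in
#' `n_bins` equal bins covering (0, 1]; a sample at t = 0 is assigned to
#' the first bin. Empty bins are imputed by linear interpolation between
#' neighboring bins (nearest value at the ends).
#'
#' @param time_days,values one individual's trace.
#' @param lifespan the individual's lifespan in days (> 0).
#' @param n_bins number of relative-time bins (default 11).
#' @return numeric vector of `n_bins` bin means.
#' @export
relative_trajectory <- function(time_days, values, lifespan, n_bins = 11) {
  stopifnot(lifespan > 0, n_bins >= 2, length(time_days) == length(values))
  rel <- time_days / lifespan
  keep <- rel >= 0 & rel <= 1 & !is.na(values)
  if (!any(keep))
    stop("trace has no samples within (0, lifespan]")
  rel <- rel[keep]; v <- values[keep]
  bin <- pmin(pmax(ceiling(rel * n_bins), 1), n_bins)
  means <- tapply(v, factor(bin, levels = seq_len(n_bins)), mean)
  means <- as.numeric(means)
  if (anyNA(means)) {
    obs <- which(!is.na(means))
    means <- approx(obs, means[obs], xout = seq_len(n_bins), rule = 2)$y
  }
  means
}

#' Build the individuals x bins trajectory matrix for a trace set
#'
#' @param traces long data.frame (individual_id, metric, time_days, value).
#' @param records lifespan records supplying per-individual lifespans
#'   (uncensored only).
#' @param metric metric to use.
#' @param n_bins bins per trajectory (default 11).
#' @return numeric matrix with one row per individual (rownames = ids).
#' @export
trajectory_matrix <- function(traces, records, metric = "raw_movement",
                              n_bins = 11) {
  unc <- records[!records$censored, , drop = FALSE]
  tr <- traces[traces$metric == metric, , drop = FALSE]
  ids <- intersect(unique(tr$individual_id), unc$individual_id)
  rows <- lapply(ids, function(id) {
    df <- tr[tr$individual_id == id, ]
    ls <- unc$death_time_days[unc$individual_id == id][1]
    relative_trajectory(df$time_days, df$value, ls, n_bins)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' Principal components of relative trajectories
#'
#' Column-centered PCA (no variance scaling) of the individuals x bins
#' matrix. Scores are reproducible up to sign.
#'
#' @param trajectories individuals x bins numeric matrix.
#' @param n_components components to keep (default all).
#' @return list(scores, loadings, explained_variance) where
#'   `explained_variance` is the fraction per component (non-increasing).
#' @export
trajectory_pca <- function(trajectories, n_components = NULL) {
  stopifnot(is.matrix(trajectories), nrow(trajectories) >= 2)
  if (is.null(n_components))
    n_components <- min(dim(trajectories))
  if (n_components > min(dim(trajectories)))
    stop("requested ", n_components, " components from a ",
         nrow(trajectories), " x ", ncol(trajectories), " matrix")
  p <- prcomp(trajectories, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(min(n_components, ncol(p$x)))
  list(scores = p$x[, k, drop = FALSE],
       loadings = p$rotation[, k, drop = FALSE],
       explained_variance = ev[k])
}

#' Compare behavioral decline between short- and long-lived cohorts
#'
#' Two-sample Kolmogorov-Smirnov test on relative-trajectory values.
#' `pooled` mode (default) compares the pooled distribution of all bin
#' values; `per_bin` tests each bin separately.
#'
#' @param short_traj,long_traj individuals x bins matrices.
#' @param mode "pooled" or "per_bin".
#' @return for pooled mode list(statistic, p_value); for per_bin a
#'   data.frame (bin, statistic, p_value).
#' @export
compare_cohort_decline <- function(short_traj, long_traj, mode = "pooled") {
  stopifnot(nrow(short_traj) >= 1, nrow(long_traj) >= 1)
  mode <- match.arg(mode, c("pooled", "per_bin"))
  kst <- function(a, b) {
    t <- suppressWarnings(ks.test(a, b))
    list(statistic = unname(t$statistic), p_value = t$p.value)
  }
  if (mode == "pooled") {
    kst(as.numeric(short_traj), as.numeric(long_traj))
  } else {
    do.call(rbind, lapply(seq_len(ncol(short_traj)), function(j) {
      r <- kst(short_traj[, j], long_traj[, j])
      data.frame(bin = j, statistic = r$statistic, p_value = r$p_value)
    }))
  }
}
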