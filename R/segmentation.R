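# Consensus worm segmentation: per-frame candidate masks from multiple
# thresholding scales, scored against a morphological prior that is
# updated over the individual's life, chained by positional continuity.

#' Morphological prior for one individual
#'
#' @param area_range plausible worm area interval (px^2).
#' @param length_range plausible body length interval (px).
#' @param aspect_range plausible length/width ratio interval.
#' @param last_centroid (row, col) of the last accepted centroid or NULL.
#' @param update_weight exponential update weight in \[0, 1\]
#'   (0 = frozen prior, 1 = adopt the latest clip's statistics).
#' @export
morph_prior <- function(area_range = c(80, 600),
                        length_range = c(15, 90),
                        aspect_range = c(2.5, 30),
                        last_centroid = NULL, update_weight = 0.2) {
  stopifnot(area_range[1] <= area_range[2],
            length_range[1] <= length_range[2],
            aspect_range[1] <= aspect_range[2],
            update_weight >= 0, update_weight <= 1)
  structure(list(area_range = area_range, length_range = length_range,
                 aspect_range = aspect_range, last_centroid = last_centroid,
                 update_weight = update_weight),
            class = "morph_prior")
}

# soft interval membership: 1 inside, exponential decay outside with
# scale a quarter of the interval half-width
interval_score <- function(x, range) {
  lo <- range[1]; hi <- range[2]
  hw <- max((hi - lo) / 2, .Machine$double.eps)
  ifelse(x >= lo & x <= hi, 1, exp(-4 * pmax(lo - x, x - hi) / hw))
}

# shape statistics of a pixel set: area, rod-equivalent length/width via
# principal axes of the pixel scatter (length = sqrt(12 * var) for an
# ideal uniform rod), centroid
mask_stats <- function(rows, cols) {
  n <- length(rows)
  ctr <- c(mean(rows), mean(cols))
  if (n < 3) return(list(area = n, length = sqrt(n), width = sqrt(n),
                         aspect = 1, centroid = ctr))
  cv <- stats::cov(cbind(rows, cols))
  ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  len <- sqrt(12 * ev[1])
  wid <- max(sqrt(12 * ev[2]), 1)
  list(area = n, length = len, width = wid, aspect = len / wid, centroid = ctr)
}

#' Generate scored worm-mask candidates for one frame
#'
#' Candidates are dark connected components under several thresholding
#' scales (Otsu on the chamber interior plus fixed low quantiles of the
#' interior intensity), scored for morphological plausibility against the
#' prior as the geometric mean of soft area/length/aspect memberships.
#' Near-duplicate masks (IoU > 0.85) are merged keeping the best score.
#'
#' @param frame grayscale matrix, cropped/masked to the chamber.
#' @param chamber_geom list(center, radius) in crop coordinates (as
#'   attached by [crop_chamber]); NULL uses the full frame.
#' @param prior a [morph_prior].
#' @param quantiles interior-intensity quantiles used as extra thresholds.
#' @param min_area smallest candidate area kept (px^2).
#' @return list of candidates: mask (logical matrix), centroid, area,
#'   length, aspect, score; possibly empty.
#' @export
candidate_masks <- function(frame, chamber_geom = NULL, prior = morph_prior(),
                            quantiles = c(0.01, 0.03, 0.08), min_area = 15) {
  if (is.null(chamber_geom)) {
    inside <- matrix(TRUE, nrow(frame), ncol(frame))
  } else if (!is.null(chamber_geom$inside)) {
    inside <- chamber_geom$inside
  } else {
    rows <- matrix(seq_len(nrow(frame)), nrow(frame), ncol(frame))
    cols <- matrix(seq_len(ncol(frame)), nrow(frame), ncol(frame), byrow = TRUE)
    inside <- (rows - chamber_geom$center[1])^2 +
      (cols - chamber_geom$center[2])^2 <= chamber_geom$radius^2
  }
  vals <- frame[inside]
  if (!length(vals)) return(list())
  thr <- unique(c(otsu_threshold(vals), stats::quantile(vals, quantiles,
                                                        names = FALSE)))
  cands <- list()
  for (t in thr) {
    bw <- frame < t & inside
    if (!any(bw)) next
    lab <- EBImage::bwlabel(EBImage::as.Image(bw))
    lab <- EBImage::imageData(lab)
    tab <- tabulate(lab[lab > 0])
    med <- median(vals)
    for (k in which(tab >= min_area)) {
      idx <- which(lab == k)
      rc <- arrayInd(idx, dim(frame))
      st <- mask_stats(rc[, 1], rc[, 2])
      # worms are substantially darker than the chamber background;
      # threshold-speckle barely is (full weight at >= 20 gray levels)
      contrast <- pmin(pmax((med - mean(frame[idx])) * 255 / 20, 0), 1)
      score <- contrast * (interval_score(st$area, prior$area_range) *
                 interval_score(st$length, prior$length_range) *
                 interval_score(st$aspect, prior$aspect_range))^(1 / 3)
      m <- matrix(FALSE, nrow(frame), ncol(frame))
      m[idx] <- TRUE
      cands[[length(cands) + 1]] <-
        list(mask = m, centroid = st$centroid, area = st$area,
             length = st$length, aspect = st$aspect, score = score)
    }
  }
  dedupe_candidates(cands)
}

otsu_threshold <- function(vals) {
  # 256-bin Otsu on 8-bit-quantized intensities
  h <- tabulate(pmin(pmax(floor(vals * 255), 0), 255) + 1, 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  (which.max(sb) - 0.5) / 255
}

dedupe_candidates <- function(cands) {
  if (length(cands) <= 1) return(cands)
  ord <- order(-vapply(cands, `[[`, 0, "score"),
               vapply(cands, `[[`, 0, "area"))
  kept <- list()
  for (i in ord) {
    dup <- FALSE
    for (k in kept) {
      inter <- sum(cands[[i]]$mask & k$mask)
      uni <- sum(cands[[i]]$mask | k$mask)
      if (uni > 0 && inter / uni > 0.85) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- cands[[i]]
  }
  kept
}

#' Consensus segmentation of one chamber clip
#'
#' Chooses one candidate per frame to jointly maximize morphology score
#' minus a quadratic positional-continuity penalty on the centroid jump
#' between consecutive accepted frames (normalized by the chamber
#' radius), via dynamic programming. Frames with no acceptable candidate
#' are flagged `missing`, never fabricated. Ties break deterministically
#' by score, then smallest displacement, then lowest candidate index.
#'
#' @param stack a [frame_stack] of one chamber clip (ideally from
#'   [crop_chamber], which attaches the chamber geometry).
#' @param prior a [morph_prior]; `last_centroid` anchors the first frame.
#' @param continuity_weight weight of the jump penalty (default 1).
#' @param accept_threshold minimum morphology score for a candidate.
#' @param skeletons compute ordered centerlines for accepted frames.
#' @return object of class `worm_observation`: per-frame `masks` (list),
#'   `centroids` (n x 2, NA when missing), `centerlines` (list),
#'   `flags` ("ok", "missing", "loop"), plus candidate stats.
#' @export
consensus_segment <- function(stack, prior = morph_prior(),
                              continuity_weight = 1, accept_threshold = 0.2,
                              skeletons = TRUE) {
  nf <- n_frames(stack)
  geom <- stack$chamber_geom
  radius <- if (!is.null(geom)) geom$radius else min(dim(stack$frames[[1]])) / 2
  cands <- lapply(stack$frames, function(f)
    Filter(function(c) c$score >= accept_threshold,
           candidate_masks(f, geom, prior)))
  choice <- viterbi_choice(cands, radius, continuity_weight,
                           prior$last_centroid)
  masks <- vector("list", nf)
  centerlines <- vector("list", nf)
  centroids <- matrix(NA_real_, nf, 2)
  flags <- rep("missing", nf)
  stats_list <- vector("list", nf)
  for (i in seq_len(nf)) {
    if (is.na(choice[i])) next
    cd <- cands[[i]][[choice[i]]]
    masks[[i]] <- cd$mask
    centroids[i, ] <- cd$centroid
    flags[i] <- "ok"
    stats_list[[i]] <- cd[c("area", "length", "aspect", "score")]
    if (skeletons) {
      sk <- skeletonize_mask(cd$mask)
      if (is.null(sk)) flags[i] <- "loop" else centerlines[[i]] <- sk
    }
  }
  if (skeletons) centerlines <- orient_centerlines(centerlines)
  structure(list(n = nf, masks = masks, centroids = centroids,
                 centerlines = centerlines, flags = flags,
                 frame_stats = stats_list, fps = stack$fps,
                 chamber_id = stack$chamber_id),
            class = "worm_observation")
}

# dynamic program over per-frame candidate choices; returns chosen index
# per frame (NA for frames with no candidates)
viterbi_choice <- function(cands, radius, w, anchor = NULL) {
  nf <- length(cands)
  choice <- rep(NA_integer_, nf)
  have <- which(vapply(cands, length, 0L) > 0)
  if (!length(have)) return(choice)
  # forward pass over frames that have candidates
  prev_scores <- NULL; prev_cents <- NULL
  back <- vector("list", length(have))
  for (j in seq_along(have)) {
    fr <- have[j]
    sc <- vapply(cands[[fr]], `[[`, 0, "score")
    cents <- t(vapply(cands[[fr]], `[[`, c(0, 0), "centroid"))
    if (j == 1) {
      tot <- sc
      if (!is.null(anchor)) {
        d2 <- ((cents[, 1] - anchor[1])^2 + (cents[, 2] - anchor[2])^2) / radius^2
        tot <- tot - w * d2
      }
      back[[j]] <- rep(0L, length(sc))
    } else {
      tot <- numeric(length(sc))
      bk <- integer(length(sc))
      for (k in seq_along(sc)) {
        d2 <- ((prev_cents[, 1] - cents[k, 1])^2 +
               (prev_cents[, 2] - cents[k, 2])^2) / radius^2
        cand_tot <- prev_scores - w * d2
        # deterministic argmax: value, then smaller displacement, then index
        best <- order(-cand_tot, d2, seq_along(cand_tot))[1]
        bk[k] <- best
        tot[k] <- cand_tot[best] + sc[k]
      }
      back[[j]] <- bk
    }
    prev_scores <- tot
    prev_cents <- cents
  }
  # backtrack
  j <- length(have)
  k <- order(-prev_scores, seq_along(prev_scores))[1]
  while (j >= 1) {
    choice[have[j]] <- k
    k <- back[[j]][k]
    j <- j - 1
  }
  choice
}

#' Update a morphological prior from an observation
#'
#' Exponentially weighted update: range midpoints and half-widths move
#' toward the clip's observed statistics (mean +/- max(3 SD, 20% of the
#' mean)) with weight `update_weight`; `last_centroid` becomes the final
#' accepted centroid. Missing-only observations leave the prior unchanged.
#'
#' @param prior a [morph_prior].
#' @param obs a `worm_observation` from the same individual.
#' @export
update_prior <- function(prior, obs) {
  ok <- which(obs$flags == "ok")
  if (!length(ok)) return(prior)
  w <- prior$update_weight
  areas <- vapply(obs$frame_stats[ok], `[[`, 0, "area")
  lens <- vapply(obs$frame_stats[ok], `[[`, 0, "length")
  asps <- vapply(obs$frame_stats[ok], `[[`, 0, "aspect")
  blend <- function(range, x) {
    tgt_mid <- mean(x)
    tgt_hw <- max(3 * sd(c(x, x[1])), 0.2 * tgt_mid, na.rm = TRUE)
    if (!is.finite(tgt_hw)) tgt_hw <- 0.2 * tgt_mid
    mid <- (1 - w) * mean(range) + w * tgt_mid
    hw <- (1 - w) * diff(range) / 2 + w * tgt_hw
    c(mid - hw, mid + hw)
  }
  morph_prior(area_range = blend(prior$area_range, areas),
              length_range = blend(prior$length_range, lens),
              aspect_range = blend(prior$aspect_range, asps),
              last_centroid = obs$centroids[max(ok), ],
              update_weight = w)
}

# --- skeletonization --------------------------------------------------------

#' Ordered centerline of a connected mask
#'
#' Zhang-Suen thinning followed by longest-path extraction on the
#' 8-connected skeleton graph; endpoints are extended along the end
#' tangents to the mask boundary so the centerline spans the full body.
#' Masks whose skeleton has loop topology (no endpoints) return NULL.
#'
#' @param mask logical matrix (one connected component).
#' @return n x 2 matrix of ordered (row, col) centerline points, or NULL
#'   for loop/degenerate topology.
#' @export
skeletonize_mask <- function(mask) {
  sk <- zhang_suen_thin(mask)
  pts <- which(sk, arr.ind = TRUE)
  if (nrow(pts) < 3) return(NULL)
  path <- skeleton_longest_path(sk)
  if (is.null(path)) return(NULL)
  path <- extend_to_boundary(path, mask)
  smooth_path(path)
}

# light coordinate smoothing to remove pixel-lattice jaggedness (which
# inflates arc length), then uniform resampling
smooth_path <- function(path, window = 5, n_out = NULL) {
  np <- nrow(path)
  if (np >= window + 2) {
    k <- rep(1 / window, window)
    sm <- cbind(as.numeric(stats::filter(path[, 1], k, sides = 2)),
                as.numeric(stats::filter(path[, 2], k, sides = 2)))
    keep <- !is.na(sm[, 1])
    # preserve the true endpoints, smooth the interior
    sm <- rbind(path[1, ], sm[keep, , drop = FALSE], path[np, ])
    path <- sm
  }
  if (is.null(n_out)) n_out <- max(15, min(nrow(path), 41))
  if (nrow(path) >= 2) resample_polyline(path, n_out) else path
}

# vectorized Zhang-Suen thinning on a logical matrix
zhang_suen_thin <- function(mask) {
  m <- mask * 1L
  shift <- function(x, dr, dc) {
    out <- matrix(0L, nrow(x), ncol(x))
    rs <- seq_len(nrow(x)) - dr
    cs <- seq_len(ncol(x)) - dc
    ok_r <- rs >= 1 & rs <= nrow(x)
    ok_c <- cs >= 1 & cs <= ncol(x)
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# longest path through the skeleton graph via double BFS; NULL when the
# skeleton has no endpoints (loop topology)
skeleton_longest_path <- function(sk) {
  pts <- which(sk, arr.ind = TRUE)
  n <- nrow(pts)
  key <- pts[, 1] + pts[, 2] * (nrow(sk) + 1)
  index <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = index)
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  nbrs <- lapply(seq_len(n), function(i) {
    kk <- (pts[i, 1] + offs[, 1]) + (pts[i, 2] + offs[, 2]) * (nrow(sk) + 1)
    out <- integer(0)
    for (k in kk) {
      j <- index[[as.character(k)]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  })
  deg <- lengths(nbrs)
  if (!any(deg == 1)) return(NULL)      # loop topology
  bfs_far <- function(start) {
    dist <- rep(-1L, n); par <- rep(0L, n)
    dist[start] <- 0L
    q <- start; head <- 1L
    while (head <= length(q)) {
      u <- q[head]; head <- head + 1L
      for (v in nbrs[[u]]) if (dist[v] < 0) {
        dist[v] <- dist[u] + 1L; par[v] <- u; q <- c(q, v)
      }
    }
    far <- which.max(dist)
    list(far = far, par = par, dist = dist)
  }
  s <- which(deg == 1)[1]
  a <- bfs_far(s)$far
  b <- bfs_far(a)
  # reconstruct path from b$far back to a
  path <- integer(0)
  u <- b$far
  while (u != 0) { path <- c(path, u); u <- b$par[u] }
  cbind(pts[path, 1], pts[path, 2])
}

# extend both path ends along the local tangent until leaving the mask
extend_to_boundary <- function(path, mask) {
  ext_one <- function(pts) {
    np <- nrow(pts)
    k <- min(4, np - 1)
    dir <- pts[1, ] - pts[1 + k, ]
    dir <- dir / max(sqrt(sum(dir^2)), .Machine$double.eps)
    p <- pts[1, ]
    added <- NULL
    repeat {
      p2 <- p + 0.5 * dir
      r <- round(p2[1]); c <- round(p2[2])
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask) || !mask[r, c])
        break
      added <- rbind(p2, added)
      p <- p2
      if (!is.null(added) && nrow(added) > 40) break
    }
    if (is.null(added)) pts else rbind(added[1, , drop = FALSE], pts)
  }
  path <- ext_one(path)
  path <- ext_one(path[rev(seq_len(nrow(path))), , drop = FALSE])
  path[rev(seq_len(nrow(path))), , drop = FALSE]
}

# fix centerline orientation within a clip: first valid frame keeps its
# lexicographically smaller endpoint first; later frames orient to
# minimize endpoint distance to the previous oriented centerline
orient_centerlines <- function(centerlines) {
  prev <- NULL
  for (i in seq_along(centerlines)) {
    cl <- centerlines[[i]]
    if (is.null(cl)) next
    if (is.null(prev)) {
      e1 <- cl[1, ]; e2 <- cl[nrow(cl), ]
      if (e1[1] > e2[1] || (e1[1] == e2[1] && e1[2] > e2[2]))
        cl <- cl[rev(seq_len(nrow(cl))), ]
    } else {
      d_keep <- sum((cl[1, ] - prev[1, ])^2) +
        sum((cl[nrow(cl), ] - prev[nrow(prev), ])^2)
      d_flip <- sum((cl[nrow(cl), ] - prev[1, ])^2) +
        sum((cl[1, ] - prev[nrow(prev), ])^2)
      if (d_flip < d_keep) cl <- cl[rev(seq_len(nrow(cl))), ]
    }
    centerlines[[i]] <- cl
    prev <- cl
  }
  centerlines
}

#' @export
print.worm_observation <- function(x, ...) {
  cat(sprintf("worm_observation: %d frames (%d ok, %d missing, %d loop)\n",
              x$n, sum(x$flags == "ok"), sum(x$flags == "missing"),
              sum(x$flags == "loop")))
  invisible(x)
}

#' Serialize an observation index as CSV
#'
#' One row per frame: chamber_id, frame, centroid_row, centroid_col,
#' quality_flag.
#' @param obs a `worm_observation`.
#' @param path CSV path.
#' @export
write_observation_index <- function(obs, path) {
  df <- data.frame(chamber_id = obs$chamber_id, frame = seq_len(obs$n),
                   centroid_row = obs$centroids[, 1],
                   centroid_col = obs$centroids[, 2],
                   quality_flag = obs$flags, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
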