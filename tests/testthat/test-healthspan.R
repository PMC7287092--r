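test_that("pooled k-means separates well-split activity regimes", {
  set.seed(17)
  n <- 400
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  vals <- ifelse(truth, rnorm(n, 1.0, 0.05), rnorm(n, 0.1, 0.05))
  traces <- data.frame(individual_id = rep(sprintf("w%02d", 1:20), each = 20),
                       metric = "raw_movement",
                       time_days = rep(seq(0.5, 10, by = 0.5), 20),
                       value = vals)
  ls <- data.frame(individual_id = sprintf("w%02d", 1:20),
                   death_time_days = 10)
  pc <- classify_phases_kmeans(traces, "raw_movement", ls, seed = 2)
  # recover assignment accuracy from the pooled clustering
  km <- with(traces, {
    k <- suppressWarnings(kmeans(value, 2, nstart = 10))
    (k$cluster == which.max(k$centers)) == truth
  })
  expect_gte(mean(km), 0.99)
  expect_s3_class(pc, "phase_calls")
  expect_true(all(pc$fraction_high >= 0 & pc$fraction_high <= 1))
})

test_that("a half-high trace yields fraction_high near one half", {
  t <- seq(0.5, 10, by = 0.5)
  mk <- function(id, v) data.frame(individual_id = id,
                                   metric = "raw_movement",
                                   time_days = t, value = v)
  traces <- rbind(mk("hi", ifelse(t <= 5, 1, 0.01) + rnorm(20, 0, 0.01)),
                  mk("lo", ifelse(t <= 5, 0.98, 0.012) + rnorm(20, 0, 0.01)))
  ls <- data.frame(individual_id = c("hi", "lo"), death_time_days = 10)
  pc <- classify_phases_kmeans(traces, "raw_movement", ls, seed = 1)
  expect_equal(pc$fraction_high, c(0.5, 0.5), tolerance = 0.5 / 10 + 1e-9)
  expect_error(classify_phases_kmeans(mk("x", rep(1, 20)), "raw_movement",
                                      ls, seed = 1), "degenerate")
})

test_that("phase calls are invariant to cluster labels and sample order", {
  set.seed(30)
  t <- seq(0.5, 10, by = 0.5)
  traces <- data.frame(individual_id = rep(c("a", "b"), each = 20),
                       metric = "raw_movement", time_days = rep(t, 2),
                       value = c(ifelse(t <= 6, 1, 0.1),
                                 ifelse(t <= 4, 0.9, 0.12)) +
                         rnorm(40, 0, 0.02))
  ls <- data.frame(individual_id = c("a", "b"), death_time_days = 10)
  p1 <- classify_phases_kmeans(traces, "raw_movement", ls, seed = 1)
  p2 <- classify_phases_kmeans(traces, "raw_movement", ls, seed = 77)
  p3 <- classify_phases_kmeans(traces[sample(nrow(traces)), ],
                               "raw_movement", ls, seed = 1)
  expect_equal(p1$high_activity_end, p2$high_activity_end)
  expect_equal(p1$high_activity_end,
               p3$high_activity_end[match(p1$individual_id,
                                          p3$individual_id)])
})

test_that("moving-average phase rule finds the mean crossing", {
  # monotone linear decline, window 1: crossing at the mean-crossing point
  t <- 1:11
  v <- seq(1, 0, length.out = 11)
  r <- classify_phases_moving_average(t, v, window = 1)
  expect_false(r$flagged)
  expect_equal(r$high_activity_end, 7)  # first sample with value < 0.5
  # constant trace never falls below its mean: flagged, all high
  rc <- classify_phases_moving_average(t, rep(2, 11), window = 1)
  expect_true(rc$flagged)
  expect_equal(rc$high_activity_end, 11)
  # step trace lands on the step
  vs <- c(rep(1, 5), rep(0, 5))
  rs <- classify_phases_moving_average(1:10, vs, window = 1)
  expect_equal(rs$high_activity_end, 6)
})

test_that("lifespan cohorts take the stated percentiles with ties included", {
  rec <- data.frame(individual_id = letters[1:10], death_time_days = 1:10,
                    censored = FALSE)
  co <- define_cohorts(rec, percentile = 20)
  expect_setequal(co$shortest$death_time_days, c(1, 2))
  expect_setequal(co$longest$death_time_days, c(9, 10))
  expect_false(co$flagged)
  # boundary ties are all included
  rec2 <- data.frame(individual_id = letters[1:10],
                     death_time_days = c(1, 2, 2, 2, 5, 6, 7, 8, 9, 10),
                     censored = FALSE)
  co2 <- define_cohorts(rec2, percentile = 20)
  expect_equal(nrow(co2$shortest), 4)
  # all-equal lifespans: both cohorts equal the full set, flagged
  rec3 <- data.frame(individual_id = letters[1:6], death_time_days = 7,
                     censored = FALSE)
  co3 <- define_cohorts(rec3)
  expect_true(co3$flagged)
  expect_equal(nrow(co3$shortest), 6)
  expect_error(define_cohorts(rec[1:3, ]), "at least")
})

test_that("relative trajectories bin on the individual's own lifespan", {
  t <- seq(0.5, 10, by = 0.5)
  expect_equal(relative_trajectory(t, rep(3, 20), lifespan = 10), rep(3, 11))
  # linear decline: bin means decrease monotonically
  traj <- relative_trajectory(t, 1 - t / 10, lifespan = 10)
  expect_true(all(diff(traj) < 0))
  # proportional traces with different lifespans coincide after
  # per-individual max-normalization
  t2 <- seq(1, 20, by = 1)
  a <- relative_trajectory(t, 5 * (1 - t / 10), lifespan = 10)
  b <- relative_trajectory(t2, 2 * (1 - t2 / 20), lifespan = 20)
  expect_equal(a / max(a), b / max(b), tolerance = 1e-9)
  # empty interior bins are interpolated
  sparse <- relative_trajectory(c(1, 9), c(1, 0.2), lifespan = 10)
  expect_equal(length(sparse), 11)
  expect_false(anyNA(sparse))
  expect_error(relative_trajectory(c(20, 30), c(1, 1), lifespan = 10),
               "no samples")
})

test_that("trajectory PCA explains variance in the expected order", {
  base <- seq(1, 0, length.out = 11)
  m <- outer(seq(0.5, 2, length.out = 12), base)   # rank-1
  p <- trajectory_pca(m)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # two orthogonal archetypes separate perfectly on the leading PCs
  a1 <- c(rep(1, 6), rep(0, 5)); a2 <- c(rep(0, 6), rep(1, 5))
  set.seed(3)
  g <- rep(c(TRUE, FALSE), each = 15)
  m2 <- t(vapply(g, function(x) (if (x) a1 else a2) + rnorm(11, 0, 0.01),
                 numeric(11)))
  p2 <- trajectory_pca(m2, n_components = 2)
  s <- p2$scores[, 1]
  auc_sep <- max(mean(outer(s[g], s[!g], ">")),
                 mean(outer(s[g], s[!g], "<")))
  expect_equal(auc_sep, 1)
  # sign flips leave the reconstruction unchanged
  rec1 <- p2$scores %*% t(p2$loadings)
  rec2 <- (-p2$scores) %*% t(-p2$loadings)
  expect_equal(rec1, rec2)
  expect_error(trajectory_pca(m2, n_components = 50), "components")
})

test_that("cohort decline comparison behaves at the KS extremes with power", {
  m1 <- matrix(runif(55), 5, 11)
  r_same <- compare_cohort_decline(m1, m1)
  expect_equal(r_same$statistic, 0)
  r_disj <- compare_cohort_decline(m1, m1 + 10)
  expect_equal(r_disj$statistic, 1)
  # power against a 1-SD shift with n = 50 per cohort
  set.seed(11)
  hits <- vapply(1:60, function(i) {
    a <- matrix(rnorm(50 * 11), 50, 11)
    b <- matrix(rnorm(50 * 11, mean = 1), 50, 11)
    compare_cohort_decline(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  pb <- compare_cohort_decline(m1, m1 + 10, mode = "per_bin")
  expect_equal(nrow(pb), 11)
})
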