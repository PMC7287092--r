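# Lifespan prediction: engineered behavioral feature table (daily max,
# daily mean per metric x clip label, plus early-life decline slopes) and
# an L1-penalized linear model tuned by 10-fold cross-validation.

#' Build the per-individual behavioral feature matrix
#'
#' For every metric x clip label x day of `day_grid`, two daily
#' statistics (maximum, mean) over the samples falling in \[day, day+1);
#' plus one early-life decline slope (least-squares, over
#' `early_window`) per metric x label. Features on days an individual
#' did not survive to are missing, not zero; the death day itself
#' contributes its partial samples. Column names follow the grammar
#' `metric.stat.dayNN.label` (slopes: `metric.slope.label`).
#'
#' @param traces long data.frame (individual_id, metric, time_days,
#'   value, clip_label).
#' @param records lifespan records (death bounds feature availability).
#' @param day_grid integer days (default 0 to the last whole day of the
#'   longest-lived individual).
#' @param early_window c(first, last) day of the decline-slope window
#'   (default days 1-10).
#' @return object of class `feature_matrix`: numeric matrix `x` (rows =
#'   individuals), `lifespans` aligned vector, `imputation_medians`
#'   (NULL until [censor_and_impute]).
#' @export
build_features <- function(traces, records, day_grid = NULL,
                           early_window = c(1, 10)) {
  if (!"clip_label" %in% names(traces)) traces$clip_label <- "constant"
  unc <- records[!records$censored, , drop = FALSE]
  ids <- intersect(unique(traces$individual_id), unc$individual_id)
  if (!length(ids)) stop("no individuals shared between traces and records")
  if (is.null(day_grid))
    day_grid <- 0:floor(max(unc$death_time_days))
  metrics <- sort(unique(traces$metric))
  labels <- sort(unique(traces$clip_label))
  daily <- expand.grid(stat = c("max", "mean"), day = day_grid,
                       label = labels, metric = metrics,
                       stringsAsFactors = FALSE)
  slopes <- expand.grid(label = labels, metric = metrics,
                        stringsAsFactors = FALSE)
  cols <- c(sprintf("%s.%s.day%02d.%s", daily$metric, daily$stat,
                    daily$day, daily$label),
            sprintf("%s.slope.%s", slopes$metric, slopes$label))
  x <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  lifespans <- setNames(unc$death_time_days[match(ids, unc$individual_id)], ids)
  empty <- character(0)
  for (id in ids) {
    tr <- traces[traces$individual_id == id & !is.na(traces$value), ]
    tr <- tr[tr$time_days <= lifespans[id], ]
    if (!nrow(tr)) { empty <- c(empty, id); next }
    for (m in unique(tr$metric)) for (l in unique(tr$clip_label)) {
      sub <- tr[tr$metric == m & tr$clip_label == l, ]
      if (!nrow(sub)) next
      for (d in day_grid) {
        if (d > lifespans[id]) break
        sel <- sub$time_days >= d & sub$time_days < d + 1
        if (!any(sel)) next
        x[id, sprintf("%s.max.day%02d.%s", m, d, l)] <- max(sub$value[sel])
        x[id, sprintf("%s.mean.day%02d.%s", m, d, l)] <- mean(sub$value[sel])
      }
      win <- sub$time_days >= early_window[1] & sub$time_days <= early_window[2]
      if (sum(win) >= 2 && var(sub$time_days[win]) > 0)
        x[id, paste0(m, ".slope.", l)] <-
          unname(coef(lm(sub$value[win] ~ sub$time_days[win]))[2])
    }
  }
  if (length(empty)) {
    warning("dropping individuals with no samples: ",
            paste(empty, collapse = ", "))
    keep <- setdiff(ids, empty)
    x <- x[keep, , drop = FALSE]
    lifespans <- lifespans[keep]
  }
  structure(list(x = x, lifespans = lifespans, imputation_medians = NULL),
            class = "feature_matrix")
}

#' Censor sparse feature columns and impute the rest by column medians
#'
#' Columns whose missing fraction exceeds `sparsity_threshold` are
#' removed (sparse data mostly reflects unreliable segmentation);
#' remaining missing entries are replaced by the column median over
#' observed values. Idempotent.
#'
#' @param fm a `feature_matrix`.
#' @param sparsity_threshold maximum tolerated missing fraction, in
#'   (0, 1); default 0.5.
#' @return the `feature_matrix` with no missing values and
#'   `imputation_medians` recorded per kept column.
#' @export
censor_and_impute <- function(fm, sparsity_threshold = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"),
            sparsity_threshold > 0, sparsity_threshold < 1)
  miss <- colMeans(is.na(fm$x))
  keep <- miss <= sparsity_threshold
  if (!any(keep)) stop("all feature columns exceed the sparsity threshold")
  x <- fm$x[, keep, drop = FALSE]
  med <- apply(x, 2, median, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- med[j]
  }
  fm$x <- x
  fm$imputation_medians <- med
  fm
}

#' Fit a LASSO lifespan model with 10-fold cross-validation
#'
#' Features are standardized before penalization; the penalty grid spans
#' the null-to-saturated path and the reported penalty minimizes mean CV
#' error (`rule = "1se"` selects the sparser one-SE model). Fold
#' assignment is a deterministic function of `seed`, and out-of-fold
#' predictions at the chosen penalty are retained. The final model is
#' refit on all data at that penalty.
#'
#' @param fm a `feature_matrix` with no missing values (run
#'   [censor_and_impute] first), or a plain numeric matrix.
#' @param lifespans response vector (days); defaults to the matrix's
#'   aligned lifespans.
#' @param n_folds CV folds (default 10).
#' @param seed fold-assignment seed.
#' @param rule "min" (default) or "1se".
#' @return object of class `lasso_lifespan`: nonzero `coefficients`,
#'   `lambda`, `cv` curve, `oof_predictions`, `oof_r2`, `foldid`,
#'   training medians for schema alignment, and the glmnet fit.
#' @export
fit_lasso_cv <- function(fm, lifespans = NULL, n_folds = 10, seed = 1,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  if (inherits(fm, "feature_matrix")) {
    x <- fm$x
    if (is.null(lifespans)) lifespans <- fm$lifespans
    med <- fm$imputation_medians
  } else {
    x <- fm
    med <- apply(x, 2, median)
  }
  stopifnot(!anyNA(x), nrow(x) >= n_folds, length(lifespans) == nrow(x))
  if (var(lifespans) < .Machine$double.eps)
    stop("constant response: lifespans have no variance")
  foldid <- with_local_seed(seed,
    sample(rep(seq_len(n_folds), length.out = nrow(x))))
  cv <- glmnet::cv.glmnet(x, lifespans, alpha = 1, foldid = foldid,
                          standardize = TRUE, keep = TRUE)
  lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  ilam <- which.min(abs(cv$lambda - lambda))
  oof <- cv$fit.preval[, ilam]
  beta <- coef(cv, s = lambda)
  nz <- which(as.numeric(beta)[-1] != 0)
  structure(list(
    coefficients = setNames(as.numeric(beta)[c(1, nz + 1)],
                            c("(Intercept)", rownames(beta)[nz + 1])),
    selected = rownames(beta)[nz + 1],
    lambda = lambda, rule = rule, foldid = foldid, seed = seed,
    cv = data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                    nzero = as.numeric(cv$nzero)),
    oof_predictions = setNames(as.numeric(oof), rownames(x)),
    oof_r2 = 1 - sum((oof - lifespans)^2) /
      sum((lifespans - mean(lifespans))^2),
    training_medians = med, schema = colnames(x),
    glmnet_cv = cv, lifespans = lifespans),
    class = "lasso_lifespan")
}

#' @export
print.lasso_lifespan <- function(x, ...) {
  cat(sprintf(
    "lasso_lifespan: %d features selected (lambda = %.4g, %s rule)\n",
    length(x$selected), x$lambda, x$rule))
  cat(sprintf("  out-of-fold R^2 = %.3f over n = %d individuals\n",
              x$oof_r2, length(x$oof_predictions)))
  invisible(x)
}

#' @export
coef.lasso_lifespan <- function(object, ...) object$coefficients

#' @export
plot.lasso_lifespan <- function(x, ...) {
  plot(x$lifespans, x$oof_predictions,
       xlab = "Observed lifespan (days)",
       ylab = "Out-of-fold predicted lifespan (days)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Predict lifespans for new individuals
#'
#' @param object a `lasso_lifespan` fit.
#' @param newdata `feature_matrix` or numeric matrix; columns are aligned
#'   to the training schema, absent columns imputed with training
#'   medians.
#' @param ... unused.
#' @export
predict.lasso_lifespan <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  if (is.null(colnames(x)))
    stop("newdata must have named feature columns")
  aligned <- matrix(rep(object$training_medians, each = nrow(x)),
                    nrow(x), length(object$schema),
                    dimnames = list(rownames(x), object$schema))
  common <- intersect(colnames(x), object$schema)
  if (!length(common))
    stop("schema mismatch: newdata shares no feature columns with the fit")
  aligned[, common] <- x[, common]
  if (anyNA(aligned)) {
    for (j in seq_len(ncol(aligned))) {
      na <- is.na(aligned[, j])
      if (any(na)) aligned[na, j] <- object$training_medians[j]
    }
  }
  as.numeric(predict(object$glmnet_cv, newx = aligned, s = object$lambda))
}

#' Transfer a fitted model to another condition and summarize residuals
#'
#' Predicts lifespans for condition B with a model trained on condition
#' A and reports signed residuals (predicted - observed) plus a
#' one-sided sign test on the median residual: a positive median means
#' systematic overestimation of B's lifespans.
#'
#' @param fit a `lasso_lifespan` trained on condition A.
#' @param fm_b feature matrix for condition B (schema aligned, absent
#'   columns imputed by A's training medians).
#' @param lifespans_b observed lifespans of B.
#' @param alternative sign-test alternative for the residual sign:
#'   "greater" (overestimation), "less", or "two.sided".
#' @return list(residuals, median_residual, n_positive, n, p_value).
#' @export
transfer_residuals <- function(fit, fm_b, lifespans_b,
                               alternative = c("greater", "less",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  pred <- predict(fit, fm_b)
  if (inherits(fm_b, "feature_matrix") && is.null(lifespans_b))
    lifespans_b <- fm_b$lifespans
  stopifnot(length(pred) == length(lifespans_b))
  res <- pred - lifespans_b
  nz <- res[res != 0]
  bt <- binom.test(sum(nz > 0), length(nz), 0.5, alternative = alternative)
  list(residuals = res, median_residual = median(res),
       n_positive = sum(nz > 0), n = length(nz), p_value = bt$p.value)
}
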