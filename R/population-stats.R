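# Population survival statistics: Kaplan-Meier, mean +/- SEM lifespan,
# log-rank, one-way ANOVA with Tukey's HSD, healthspan-lifespan Pearson
# correlation. Estimation is delegated to the survival package and base
# stats; this module fixes the conventions (which individuals enter which
# summary) and the serialized shapes.

records_to_surv <- function(records) {
  survival::Surv(records$death_time_days, event = !records$censored)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring; censored individuals
#' contribute at-risk time, uncensored individuals events.
#'
#' @param records lifespan records data.frame (individual_id,
#'   death_time_days, censored).
#' @return object of class `survival_curve`: data.frame `curve` (time,
#'   survival, n_risk, n_event, n_censor) and the fitted survfit object.
#' @export
kaplan_meier <- function(records) {
  if (!any(!records$censored))
    stop("Kaplan-Meier requires at least one uncensored event")
  fit <- survival::survfit(records_to_surv(records) ~ 1)
  curve <- data.frame(time = fit$time, survival = fit$surv,
                      n_risk = fit$n.risk, n_event = fit$n.event,
                      n_censor = fit$n.censor)
  structure(list(curve = curve, fit = fit, n = nrow(records)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  med <- summary(x$fit)$table["median"]
  cat(sprintf("survival_curve: n = %d, %d event times, median %.2f d\n",
              x$n, nrow(x$curve), med))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, xlab = "Time (days)",
                                ylab = "Fraction surviving", ...) {
  plot(x$fit, conf.int = FALSE, mark.time = TRUE, xlab = xlab,
       ylab = ylab, ...)
  invisible(x)
}

#' Write survival-curve coordinates as CSV
#' @param curve a `survival_curve`.
#' @param path CSV path.
#' @export
write_survival_csv <- function(curve, path) {
  write.csv(curve$curve, path, row.names = FALSE)
  invisible(path)
}

#' Mean lifespan with SEM over uncensored individuals
#'
#' @param records lifespan records data.frame.
#' @return list(mean, sem, n) in days; n counts uncensored individuals.
#' @export
mean_sem <- function(records) {
  d <- records$death_time_days[!records$censored]
  if (length(d) < 2)
    stop("mean_sem requires at least 2 uncensored individuals")
  list(mean = mean(d), sem = sd(d) / sqrt(length(d)), n = length(d))
}

#' Log-rank test across groups of lifespan records
#'
#' @param groups named list of lifespan records data.frames (>= 2), or a
#'   single records data.frame with a `group` column.
#' @return list(chisq, df, p_value).
#' @export
logrank <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot("group" %in% names(groups))
    rec <- groups
  } else {
    stopifnot(length(groups) >= 2)
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    rec <- do.call(rbind, lapply(names(groups), function(g) {
      df <- groups[[g]]
      if (!nrow(df) || !any(!df$censored))
        stop("log-rank group '", g, "' has no events")
      df$group <- g
      df[, c("death_time_days", "censored", "group")]
    }))
  }
  sd1 <- survival::survdiff(records_to_surv(rec) ~ group, data = rec)
  df <- length(sd1$n) - 1
  list(chisq = unname(sd1$chisq), df = df,
       p_value = stats::pchisq(sd1$chisq, df, lower.tail = FALSE))
}

#' One-way ANOVA with Tukey's HSD pairwise comparisons
#'
#' Standard one-way ANOVA followed by Tukey's studentized-range pairwise
#' test (Tukey-Kramer for unequal group sizes).
#'
#' @param values numeric response (e.g. high-activity durations).
#' @param groups factor/character of the same length.
#' @return list(F, p_value, df_between, df_within, tukey) where `tukey`
#'   is a data.frame (comparison, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  wvar <- tapply(values, groups, var)
  if (all(wvar < .Machine$double.eps))
    stop("zero within-group variance in every group: ANOVA undefined")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = s[1, "F value"], p_value = s[1, "Pr(>F)"],
       df_between = s[1, "Df"], df_within = s[2, "Df"], tukey = tukey)
}

#' Pearson correlation of healthspan measures with lifespan
#'
#' Correlates per-individual high-activity duration and life fraction
#' with lifespan (uncensored individuals).
#'
#' @param phase_calls `phase_calls` data.frame ([classify_phases_kmeans]).
#' @param records lifespan records data.frame.
#' @return data.frame (measure, r, p_value, n, flagged) where `flagged`
#'   marks zero-variance (undefined) correlations.
#' @export
healthspan_lifespan_correlation <- function(phase_calls, records) {
  unc <- records[!records$censored, c("individual_id", "death_time_days")]
  m <- merge(phase_calls, unc, by = "individual_id")
  if (nrow(m) < 3) stop("need >= 3 paired healthspan/lifespan values")
  one <- function(x, label) {
    if (var(x) < .Machine$double.eps || var(m$death_time_days) < .Machine$double.eps)
      return(data.frame(measure = label, r = NA_real_, p_value = NA_real_,
                        n = nrow(m), flagged = TRUE))
    ct <- cor.test(x, m$death_time_days, method = "pearson")
    data.frame(measure = label, r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(m), flagged = FALSE)
  }
  rbind(one(m$duration_high, "duration_high"),
        one(m$fraction_high, "fraction_high"))
}

#' Per-condition lifespan summary table
#'
#' @param records lifespan records with condition columns.
#' @param by character vector of condition column names.
#' @return data.frame with one row per condition: n, mean_days, sem_days.
#' @export
lifespan_summary <- function(records, by) {
  stopifnot(all(by %in% names(records)))
  unc <- records[!records$censored, , drop = FALSE]
  key <- interaction(unc[, by, drop = FALSE], drop = TRUE, sep = " / ")
  out <- do.call(rbind, lapply(split(unc, key), function(df) {
    ms <- mean_sem(df)
    cbind(df[1, by, drop = FALSE],
          data.frame(n = ms$n, mean_days = ms$mean, sem_days = ms$sem))
  }))
  rownames(out) <- NULL
  out
}
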