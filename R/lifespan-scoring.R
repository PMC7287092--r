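# Lifespan scoring: the two-day movement-cessation rule and censoring.

#' Call death from a raw-movement trace
#'
#' An individual is scored dead at the time of its last sample above
#' `activity_threshold`, provided all later samples stay at or below the
#' threshold and the trace extends at least `confirmation_window` days
#' past that time (no raw movement detected for two days, by default).
#' Otherwise the individual is alive/undetermined at trace end.
#'
#' @param time_days strictly increasing sample times in days.
#' @param values raw-movement values (same length).
#' @param activity_threshold detection floor; 0 for noise-free traces,
#'   otherwise estimate with [estimate_activity_threshold].
#' @param confirmation_window movement-free confirmation period in days
#'   (default 2).
#' @return list(death_time, status) where status is one of "dead",
#'   "alive", "never_moved" (death at the first sample time, flagged for
#'   manual review).
#' @export
call_death <- function(time_days, values, activity_threshold = 0,
                       confirmation_window = 2) {
  stopifnot(length(time_days) == length(values), length(time_days) >= 1)
  if (is.unsorted(time_days, strictly = TRUE))
    stop("trace times must be strictly increasing")
  keep <- !is.na(values)
  time_days <- time_days[keep]; values <- values[keep]
  if (!length(values)) return(list(death_time = NA_real_, status = "alive"))
  above <- values > activity_threshold
  if (!any(above))
    return(list(death_time = time_days[1], status = "never_moved"))
  last <- max(which(above))
  t_last <- time_days[last]
  if (max(time_days) - t_last >= confirmation_window)
    list(death_time = t_last, status = "dead")
  else
    list(death_time = NA_real_, status = "alive")
}

#' Estimate the raw-movement detection floor from empty chambers
#'
#' The 95th percentile of raw-movement values measured in verified-empty
#' chambers, scaled by a safety margin so that post-mortem clips drawn
#' from the same noise distribution rarely cross it.
#'
#' @param empty_values raw-movement values from empty-chamber clips.
#' @param margin multiplicative safety factor (default 2).
#' @export
estimate_activity_threshold <- function(empty_values, margin = 2) {
  stopifnot(length(empty_values) >= 1)
  as.numeric(quantile(empty_values, 0.95, names = FALSE)) * margin
}

#' Call deaths for a whole trace set
#'
#' @param traces long data.frame (individual_id, metric, time_days,
#'   value); only `metric == "raw_movement"` rows are used.
#' @param activity_threshold,confirmation_window see [call_death].
#' @return `lifespan_records` data.frame: individual_id, death_time_days,
#'   censored, censor_reason, status. Individuals alive at trace end are
#'   right-censored at their last sample time (reason end_of_experiment).
#' @export
call_deaths <- function(traces, activity_threshold = 0,
                        confirmation_window = 2) {
  tr <- traces[traces$metric == "raw_movement", , drop = FALSE]
  if (!nrow(tr)) stop("no raw_movement traces found")
  out <- do.call(rbind, lapply(split(tr, tr$individual_id), function(df) {
    id <- df$individual_id[1]
    df <- df[order(df$time_days), ]
    # multiple clip labels at one timepoint: use the max across labels
    if (anyDuplicated(df$time_days)) {
      agg <- aggregate(value ~ time_days, df,
                       function(v) if (all(is.na(v))) NA_real_ else
                         max(v, na.rm = TRUE), na.action = NULL)
      df <- data.frame(time_days = agg$time_days, value = agg$value)
    }
    res <- call_death(df$time_days, df$value, activity_threshold,
                      confirmation_window)
    data.frame(individual_id = id,
               death_time_days = if (res$status == "alive")
                 max(df$time_days) else res$death_time,
               censored = res$status == "alive",
               censor_reason = if (res$status == "alive")
                 "end_of_experiment" else NA_character_,
               status = res$status, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("lifespan_records", "data.frame")
  out
}

#' Apply censoring rules to lifespan records
#'
#' Individuals in multi-occupancy chambers and individuals with manual
#' censor flags (e.g. vulval bursting) are marked censored with the
#' appropriate reason; they are excluded from mean-lifespan summaries but
#' retained for Kaplan-Meier estimation with their censor flags.
#'
#' @param records `lifespan_records` data.frame.
#' @param registry data.frame with individual_id, chamber_id and optional
#'   logical `burst` / character `manual_censor` columns.
#' @return updated records.
#' @export
apply_censoring <- function(records, registry) {
  stopifnot(all(c("individual_id", "chamber_id") %in% names(registry)))
  unknown <- setdiff(registry$individual_id, records$individual_id)
  if (length(unknown))
    stop("registry lists unknown individuals: ",
         paste(unknown, collapse = ", "))
  occ <- table(registry$chamber_id)
  multi <- registry$individual_id[registry$chamber_id %in%
                                    names(occ)[occ > 1]]
  burst <- character(0)
  if ("burst" %in% names(registry))
    burst <- registry$individual_id[isTRUE_vec(registry$burst)]
  for (i in seq_len(nrow(records))) {
    id <- records$individual_id[i]
    if (id %in% multi) {
      records$censored[i] <- TRUE
      records$censor_reason[i] <- "multi_worm"
    } else if (id %in% burst) {
      records$censored[i] <- TRUE
      records$censor_reason[i] <- "burst"
    }
  }
  records
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write / read a lifespan table CSV
#'
#' Schema mirrors a deposited per-individual lifespan table:
#' individual_id, death_time_days, censored, censor_reason plus any
#' condition columns present (genotype, temp_C, food_OD, trial, device).
#'
#' @param records lifespan records data.frame.
#' @param path CSV path.
#' @export
write_lifespan_csv <- function(records, path) {
  stopifnot(all(c("individual_id", "death_time_days", "censored") %in%
                names(records)))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lifespan_csv
#' @export
read_lifespan_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "death_time_days", "censored") %in%
                names(rec)))
  rec$censored <- as.logical(rec$censored)
  class(rec) <- c("lifespan_records", "data.frame")
  rec
}
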