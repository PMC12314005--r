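# Behaviour time budgets: 5-second ethogram labels -> hourly budgets ->
# daily daypart summaries, with the weighing-day exclusion rule.

#' Hourly behaviour budgets
#'
#' Counts 5-second labels per class per (animal, hour): each record
#' contributes 5/3600 h to its class, so a fully labelled hour sums to 1.0 h
#' across classes. Duplicate (animal, timestamp) records are an error.
#'
#' @param records Behaviour records (see [read_behavior()]).
#' @return Data frame with `animal_id`, `hour` (POSIXct, hour start), one
#'   column per class in [behavior_classes], and `coverage` (labelled fraction
#'   of the hour, in \[0, 1\]).
#' @export
hourly_budget <- function(records) {
  stopifnot(all(c("animal_id", "t", "label") %in% names(records)))
  dup <- duplicated(records[c("animal_id", "t")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate behaviour record for animal ", records$animal_id[i],
         " at ", format(records$t[i]), call. = FALSE)
  }
  tz <- attr(records$t, "tzone")
  hour <- .POSIXct(floor(as.numeric(records$t) / 3600) * 3600, tz = tz)
  lab <- factor(as.character(records$label), levels = behavior_classes)
  if (anyNA(lab)) stop("unknown behaviour label", call. = FALSE)
  tab <- table(key = paste(records$animal_id, as.numeric(hour), sep = "\r"),
               label = lab)
  parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
  out <- data.frame(animal_id = vapply(parts, `[`, "", 1L),
                    hour = .POSIXct(as.numeric(vapply(parts, `[`, "", 2L)),
                                    tz = tz))
  m <- unclass(tab) * 5 / 3600
  for (cl in behavior_classes) out[[cl]] <- as.numeric(m[, cl])
  out$coverage <- rowSums(m)
  out <- out[order(out$animal_id, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag hourly rows with calendar date and daypart
#'
#' Daytime is the half-open local interval `[day_start, day_end)` (default
#' 05:00--18:00, following sunrise/sunset at the trial site); all other hours
#' are night. By default a date's night comprises that same date's evening
#' (18:00--24:00) and pre-dawn (00:00--05:00) hours; set
#' `night_same_date = FALSE` in the config to attribute pre-dawn hours to the
#' previous date instead.
#'
#' @param hourly Table with a POSIXct `hour` column (e.g. from
#'   [hourly_budget()] or [synchronize()]).
#' @param config A [herd_config()].
#' @return `hourly` with `date` and `daypart` columns appended.
#' @export
split_daypart <- function(hourly, config = herd_config()) {
  stopifnot("hour" %in% names(hourly))
  tz <- config$tz
  lt <- as.POSIXlt(hourly$hour, tz = tz)
  hourly$date <- as.Date(lt)
  hod <- lt$hour
  hourly$daypart <- .daypart_of_hour(hod, config)
  if (!config$night_same_date) {
    predawn <- hod < config$day_start
    hourly$date[predawn] <- hourly$date[predawn] - 1L
  }
  hourly
}

#' Exclude weighing days (Mondays) from behavioural tables
#'
#' Weighing-day (Monday) rows carry atypical activity induced by mustering
#' and are dropped from behavioural analysis; weight records themselves are
#' unaffected. Idempotent.
#'
#' @param daily Data frame with a `date` column (class `Date`).
#' @return The table without Monday rows; warns if nothing remains.
#' @export
exclude_weighing_days <- function(daily) {
  stopifnot("date" %in% names(daily))
  keep <- format(daily$date, "%u") != "1"
  out <- daily[keep, , drop = FALSE]
  if (nrow(daily) > 0 && nrow(out) == 0)
    warning("all rows fell on weighing days (Mondays); table is empty",
            call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Build daily animal summaries
#'
#' Aggregates hourly budgets to one row per animal, date and daypart
#' (`full`, `day`, `night`): class hours summed, movement variables joined,
#' the date's maximum CCI attached to all three dayparts, and the trial-week
#' index assigned. Dayparts whose hour coverage (fraction of daypart hours
#' containing at least one behaviour record) falls below
#' `config$coverage_threshold` are flagged `incomplete` and later dropped
#' from correlation analyses.
#'
#' @param hourly Hourly budget table ([hourly_budget()] output, or any table
#'   with `animal_id`, `hour` and the six class columns).
#' @param movement Movement summaries from [movement_summary()] (optional).
#' @param daily_cci Output of [daily_max_cci()] (optional; matched on
#'   `trial_id` + `date` when both carry `trial_id`, else on `date`).
#' @param week_map Data frame mapping `date` to `week_index` (1..8) and
#'   `trial_id`, e.g. from [make_week_map()] (optional).
#' @param config A [herd_config()].
#' @return Data frame of daily animal summaries; behavioural class columns
#'   are the six entries of [behavior_classes].
#' @export
build_daily_summaries <- function(hourly, movement = NULL, daily_cci = NULL,
                                  week_map = NULL, config = herd_config()) {
  h <- split_daypart(hourly, config)
  cls <- intersect(behavior_classes, names(h))
  stopifnot(length(cls) == length(behavior_classes))

  agg_part <- function(rows, daypart) {
    if (!length(rows)) return(NULL)
    sub <- h[rows, ]
    key <- paste(sub$animal_id, sub$date, sep = "\r")
    sums <- rowsum(as.matrix(sub[cls]), key, na.rm = TRUE)
    hrs_obs <- rowsum(as.numeric(rowSums(!is.na(sub[cls])) > 0), key)
    parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
    data.frame(animal_id = vapply(parts, `[`, "", 1L),
               date = as.Date(vapply(parts, `[`, "", 2L)),
               daypart = daypart,
               as.data.frame(sums),
               hours_observed = as.numeric(hrs_obs),
               row.names = NULL)
  }
  out <- rbind(agg_part(seq_len(nrow(h)), "full"),
               agg_part(which(h$daypart == "day"), "day"),
               agg_part(which(h$daypart == "night"), "night"))

  dp_len <- .daypart_hours(config)
  out$coverage <- out$hours_observed / dp_len[out$daypart]
  out$incomplete <- out$coverage < config$coverage_threshold

  if (!is.null(movement)) {
    out <- merge(out,
                 movement[c("animal_id", "date", "daypart", "time_in_open",
                            "distance", "excluded")],
                 by = c("animal_id", "date", "daypart"), all.x = TRUE,
                 sort = FALSE)
  } else {
    out$time_in_open <- NA_real_; out$distance <- NA_real_
    out$excluded <- FALSE
  }
  if (!is.null(week_map)) {
    out <- merge(out, week_map, by = "date", all.x = TRUE, sort = FALSE)
  }
  if (!is.null(daily_cci)) {
    by <- if ("trial_id" %in% names(daily_cci) && "trial_id" %in% names(out))
      c("trial_id", "date") else "date"
    out <- merge(out, daily_cci[c(by, "max_cci")], by = by, all.x = TRUE,
                 sort = FALSE)
  }
  out <- out[order(out$animal_id, out$date, out$daypart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trial-week calendar
#'
#' Maps each date of each trial window to its trial and overall week index:
#' weeks are consecutive 7-day blocks from each trial's start date, numbered
#' 1..4 within the first trial and 5..8 within the second.
#'
#' @param trial_starts Named vector/list of trial start dates
#'   (`trial1`, `trial2`, ... in order).
#' @param n_days Days per trial window (default 28, i.e. 4 weeks).
#' @return Data frame with `date`, `trial_id`, `week_index`.
#' @export
make_week_map <- function(trial_starts, n_days = 28L) {
  trial_starts <- as.Date(unlist(lapply(trial_starts, as.character)))
  ids <- names(trial_starts)
  if (is.null(ids)) ids <- paste0("trial", seq_along(trial_starts))
  n_weeks <- ceiling(n_days / 7)
  out <- do.call(rbind, lapply(seq_along(trial_starts), function(i) {
    dates <- trial_starts[i] + 0:(n_days - 1)
    data.frame(date = dates, trial_id = ids[i],
               week_index = (i - 1L) * n_weeks +
                 as.integer(dates - trial_starts[i]) %/% 7L + 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Weekly behaviour summary (median and MAD)
#'
#' Median daily hours per behaviour class per trial week, each accompanied by
#' the raw (unscaled) median absolute deviation, computed over full-day
#' summaries of non-excluded, complete animal-days. Time in the open and
#' distance are summarised alongside the six classes.
#'
#' @param summaries Output of [build_daily_summaries()] including
#'   `week_index`; daytime rows supply `time_in_open`.
#' @return Data frame with `week_index`, `variable`, `median`, `mad`, `n`.
#' @export
behavior_summary <- function(summaries) {
  stopifnot("week_index" %in% names(summaries))
  raw_mad <- function(x) stats::median(abs(x - stats::median(x)))
  use <- summaries[!summaries$incomplete &
                     !(summaries$excluded %in% TRUE), ]
  full <- use[use$daypart == "full", ]
  day <- use[use$daypart == "day", ]
  rows <- list()
  for (w in sort(unique(use$week_index))) {
    fw <- full[full$week_index == w, ]
    for (v in c(behavior_classes, "distance")) {
      x <- fw[[v]]; x <- x[!is.na(x)]
      if (length(x))
        rows[[length(rows) + 1L]] <- data.frame(
          week_index = w, variable = v, median = stats::median(x),
          mad = raw_mad(x), n = length(x))
    }
    x <- day$time_in_open[day$week_index == w]
    x <- x[!is.na(x)]
    if (length(x))
      rows[[length(rows) + 1L]] <- data.frame(
        week_index = w, variable = "time_in_open", median = stats::median(x),
        mad = raw_mad(x), n = length(x))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
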