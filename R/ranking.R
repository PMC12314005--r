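# Climate-exposure ranking: merged-trial days ranked by daily maximum CCI
# (rank 1 = coldest), weekly average ranks, weeks paired into four exposure
# groups, and Table-1-style weather summaries per group.

#' Rank merged-trial days by daily maximum CCI
#'
#' Days from both trials are pooled and ranked ascending by `max_cci`
#' (rank 1 = coldest day); ties receive the average of the tied positions,
#' which makes the ranking invariant to input permutation.
#'
#' @param daily_cci Data frame with `date`, `max_cci` and (usually)
#'   `trial_id`, e.g. from [daily_max_cci()] on merged weather.
#' @return The input with a `rank` column appended.
#' @export
rank_days <- function(daily_cci) {
  if (is.null(daily_cci) || nrow(daily_cci) == 0)
    stop("rank_days: empty input", call. = FALSE)
  stopifnot(all(c("date", "max_cci") %in% names(daily_cci)))
  daily_cci$rank <- rank(daily_cci$max_cci, ties.method = "average")
  daily_cci
}

#' Weekly average day rank
#'
#' Arithmetic mean of member-day ranks per trial week. All calendar days of
#' the week are included: the weighing-day (Monday) exclusion applies to
#' behavioural summaries, not to climate ranking.
#'
#' @param day_ranks Output of [rank_days()].
#' @param week_map Date-to-week mapping from [make_week_map()].
#' @return Data frame with `week_index`, `trial_id`, `avg_rank`, `n_days`.
#' @export
weekly_average_rank <- function(day_ranks, week_map) {
  by <- if ("trial_id" %in% names(day_ranks) &&
              "trial_id" %in% names(week_map))
    c("date", "trial_id") else "date"
  m <- merge(day_ranks, week_map, by = by)
  if (nrow(m) == 0) stop("no ranked days map to any week", call. = FALSE)
  weeks <- sort(unique(week_map$week_index))
  missing <- setdiff(weeks, unique(m$week_index))
  if (length(missing))
    stop("week(s) with zero ranked days: ", paste(missing, collapse = ", "),
         call. = FALSE)
  avg <- tapply(m$rank, m$week_index, mean)
  n <- tapply(m$rank, m$week_index, length)
  tid <- tapply(as.character(m$trial_id), m$week_index, `[`, 1L)
  out <- data.frame(week_index = as.integer(names(avg)),
                    trial_id = as.character(tid),
                    avg_rank = as.numeric(avg),
                    n_days = as.integer(n))
  out[order(out$week_index), , drop = FALSE]
}

#' Pair ranked weeks into exposure groups
#'
#' Weeks are sorted ascending by average rank and paired consecutively:
#' group 1 holds the two coolest weeks, the last group the two warmest.
#' Requires an even number of weeks (the study design has 8).
#'
#' @param weekly Output of [weekly_average_rank()].
#' @return Object of class `"week_groups"`: a data frame with `week_index`,
#'   `trial_id`, `avg_rank`, `group_id`, ordered by group then rank.
#' @export
pair_weeks <- function(weekly) {
  stopifnot(all(c("week_index", "avg_rank") %in% names(weekly)))
  n <- nrow(weekly)
  if (n %% 2 != 0)
    stop("odd number of weeks (", n, "); supply an explicit grouping instead",
         call. = FALSE)
  # deterministic tie-break on week_index keeps the output stable
  o <- order(weekly$avg_rank, weekly$week_index)
  out <- weekly[o, , drop = FALSE]
  out$group_id <- rep(seq_len(n / 2), each = 2)
  rownames(out) <- NULL
  class(out) <- c("week_groups", "data.frame")
  out
}

#' @export
print.week_groups <- function(x, ...) {
  cat("week-pair climate-exposure groups (1 = coolest)\n")
  for (g in sort(unique(x$group_id))) {
    sub <- x[x$group_id == g, ]
    cat(sprintf("  group %d: weeks %s (avg day rank %s)\n", g,
                paste(sub$week_index, collapse = ", "),
                paste(sprintf("%.2f", sub$avg_rank), collapse = ", ")))
  }
  invisible(x)
}

#' Group-level weather summary
#'
#' Summarises weather per exposure group from daily values over the group's
#' member weeks: maximum of daily maximum temperature, minimum of daily
#' minimum temperature, mean of daily mean temperature, total rainfall, mean
#' wind speed (reported in km/h), and mean solar radiation.
#'
#' @param weather Weather records (ws in m/s) covering the member weeks, with
#'   `trial_id` when the week map carries one.
#' @param groups A [pair_weeks()] result.
#' @param week_map Date-to-week mapping from [make_week_map()].
#' @param tz Timezone for assigning records to dates.
#' @return Data frame with one row per group: `group_id`, `temp_max`,
#'   `temp_min`, `temp_mean`, `rain_total`, `wind_mean_kmh`, `rad_mean`.
#' @export
group_weather_summary <- function(weather, groups, week_map,
                                  tz = "Etc/GMT-10") {
  weather$date <- as.Date(format(weather$t, "%Y-%m-%d", tz = tz))
  by <- if ("trial_id" %in% names(weather) &&
              "trial_id" %in% names(week_map))
    c("date", "trial_id") else "date"
  w <- merge(weather, week_map, by = by)
  w <- merge(w, as.data.frame(groups)[c("week_index", "group_id")],
             by = "week_index")
  dkey <- paste(w$group_id, w$date, w$week_index, sep = "\r")
  daily <- data.frame(
    key = sort(unique(dkey)),
    tmax = as.numeric(tapply(w$ta, dkey, max)),
    tmin = as.numeric(tapply(w$ta, dkey, min)),
    tmean = as.numeric(tapply(w$ta, dkey, mean)),
    rain = as.numeric(tapply(w$rain, dkey, sum)),
    wind = as.numeric(tapply(w$ws, dkey, mean)),
    rad = as.numeric(tapply(w$rad, dkey, mean)))
  daily$group_id <- as.integer(vapply(strsplit(daily$key, "\r", fixed = TRUE),
                                      `[`, "", 1L))
  out <- data.frame(
    group_id = sort(unique(daily$group_id)),
    temp_max = as.numeric(tapply(daily$tmax, daily$group_id, max)),
    temp_min = as.numeric(tapply(daily$tmin, daily$group_id, min)),
    temp_mean = as.numeric(tapply(daily$tmean, daily$group_id, mean)),
    rain_total = as.numeric(tapply(daily$rain, daily$group_id, sum)),
    wind_mean_kmh = as.numeric(tapply(daily$wind, daily$group_id, mean)) * 3.6,
    rad_mean = as.numeric(tapply(daily$rad, daily$group_id, mean)))
  rownames(out) <- NULL
  out
}
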