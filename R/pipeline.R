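# End-to-end orchestration: streams -> CCI -> positions/movement -> budgets
# -> exposure groups -> correlation tables, wrapped in one classed object.

#' Run the full thermal-exposure analysis
#'
#' Executes the whole pipeline on a set of input streams: computes the CCI
#' and its daily maxima, reduces GNSS fixes to 10-minute median positions
#' with canopy/open classification and daypart movement summaries, builds
#' hourly and daily behaviour budgets, excludes weighing days (Mondays) from
#' behavioural tables, ranks merged-trial days by daily maximum CCI into
#' paired-week exposure groups, and computes the group- and
#' daypart-stratified correlation suite.
#'
#' @param streams Named list with `behavior` (5-second records or an hourly
#'   budget table), `gnss` (raw fixes or 10-minute median positions),
#'   `weather`, `canopy` (a [canopy_map()]) and `animals`, as returned by
#'   [read_streams()] or [simulate_trials()]`$streams`.
#' @param config A [herd_config()].
#' @param week_map Optional date-to-week mapping; by default weeks are
#'   derived as consecutive 7-day blocks from each trial's first weather
#'   date.
#' @param unit Unit of correlation analysis; see [correlation_suite()].
#' @return Object of class `"herd_analysis"` with components `cci`,
#'   `daily_cci`, `positions`, `movement`, `summaries` (Monday-excluded),
#'   `week_map`, `day_ranks`, `weekly_ranks`, `groups`, `group_weather`,
#'   `weekly_medians`, `gains`, `correlations`, `config`.
#' @export
herd_analysis <- function(streams, config = herd_config(), week_map = NULL,
                          unit = "animal_day") {
  tz <- config$tz
  cci <- compute_cci(streams$weather, envelope = config$cci_envelope)
  dmax <- daily_max_cci(cci, tz = tz)

  if (is.null(week_map)) {
    wdate <- as.Date(format(streams$weather$t, "%Y-%m-%d", tz = tz))
    tid <- if ("trial_id" %in% names(streams$weather))
      streams$weather$trial_id else rep("trial1", length(wdate))
    starts <- tapply(wdate, tid, min)
    spans <- tapply(wdate, tid, function(d) as.integer(max(d) - min(d)) + 1L)
    week_map <- make_week_map(stats::setNames(as.Date(starts, origin = "1970-01-01"),
                                              names(starts)),
                              n_days = max(spans))
  }

  pos <- streams$gnss
  if (!is.null(pos) && !"interval_start" %in% names(pos))
    pos <- median_positions(pos)
  pos <- classify_open(pos, streams$canopy)
  movement <- movement_summary(pos, config)

  hourly <- streams$behavior
  if (!is.null(hourly) && "label" %in% names(hourly))
    hourly <- hourly_budget(hourly)

  summaries <- build_daily_summaries(hourly, movement, dmax, week_map, config)
  summaries <- exclude_weighing_days(summaries)

  ranks <- rank_days(dmax)
  weekly <- weekly_average_rank(ranks, week_map)
  groups <- pair_weeks(weekly)
  gw <- group_weather_summary(streams$weather, groups, week_map, tz)

  gains <- weekly_weight_gain(streams$animals, week_map)
  correlations <- correlation_suite(summaries, gains, streams$animals,
                                    groups, unit = unit)

  structure(list(cci = cci, daily_cci = dmax, positions = pos,
                 movement = movement, summaries = summaries,
                 week_map = week_map, day_ranks = ranks,
                 weekly_ranks = weekly, groups = groups, group_weather = gw,
                 weekly_medians = behavior_summary(summaries),
                 gains = gains, correlations = correlations,
                 config = config),
            class = "herd_analysis")
}

#' @export
print.herd_analysis <- function(x, ...) {
  cat("thermal-exposure herd analysis\n")
  cat(sprintf("  %d animal-day summaries (%d animals), %d trial days\n",
              sum(x$summaries$daypart == "full"),
              length(unique(x$summaries$animal_id)),
              nrow(x$daily_cci)))
  cat(sprintf("  daily max CCI: %.1f to %.1f\n",
              min(x$daily_cci$max_cci), max(x$daily_cci$max_cci)))
  print(x$groups)
  print(x$correlations)
  invisible(x)
}

#' @export
summary.herd_analysis <- function(object, ...) {
  p <- object$correlations
  p <- p[p$method == "pearson", ]
  warm <- max(p$group_id); cool <- min(p$group_id)
  pick <- function(g, dp, xv, yv) {
    row <- p[p$group_id == g & p$daypart == dp & p$x_var == xv &
               p$y_var == yv, ]
    if (nrow(row)) row$r[1] else NA_real_
  }
  out <- data.frame(
    quantity = c("r(CCI, daytime time in open), warmest group",
                 "r(CCI, daytime grazing), warmest group",
                 "r(CCI, night grazing), warmest group",
                 "r(CCI, daytime resting), warmest group",
                 "r(CCI, daytime time in open), coolest group"),
    value = c(pick(warm, "day", "max_cci", "time_in_open"),
              pick(warm, "day", "max_cci", "grazing"),
              pick(warm, "night", "max_cci", "grazing"),
              pick(warm, "day", "max_cci", "resting"),
              pick(cool, "day", "max_cci", "time_in_open")))
  cat("headline correlations (Pearson):\n")
  print(out, row.names = FALSE, digits = 3)
  invisible(out)
}

#' @export
plot.herd_analysis <- function(x, group_id = max(x$groups$group_id),
                               daypart = "day", ...) {
  forest_plot(x$correlations, group_id = group_id, daypart = daypart, ...)
}

#' Write analysis outputs as CSV
#'
#' Writes the correlation table, daily summaries, weekly medians and group
#' weather summaries to a directory. Output is deterministic for a
#' deterministic analysis.
#'
#' @param x A [herd_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "herd_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(correlations = file.path(dir, "correlations.csv"),
             summaries = file.path(dir, "daily_summaries.csv"),
             weekly_medians = file.path(dir, "weekly_medians.csv"),
             groups = file.path(dir, "groups.csv"),
             group_weather = file.path(dir, "group_weather.csv"))
  utils::write.csv(as.data.frame(x$correlations), paths["correlations"],
                   row.names = FALSE)
  utils::write.csv(x$summaries, paths["summaries"], row.names = FALSE)
  utils::write.csv(x$weekly_medians, paths["weekly_medians"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(x$groups), paths["groups"],
                   row.names = FALSE)
  utils::write.csv(x$group_weather, paths["group_weather"],
                   row.names = FALSE)
  invisible(paths)
}
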