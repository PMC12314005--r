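#' Pipeline configuration
#'
#' Collects the fixed conventions of the analysis pipeline: the trial's local
#' timezone (a fixed UTC offset; the study region observes no daylight saving),
#' the wind-speed unit of the weather file, the daypart boundaries, the GNSS
#' gap rule and the daily-distance plausibility range.
#'
#' @param tz Olson timezone used to interpret all timestamps. The default,
#'   `"Etc/GMT-10"`, is fixed UTC+10 (note the POSIX sign convention).
#' @param wind_unit Unit of the wind-speed column in the weather file; either
#'   `"m/s"` (stored as-is) or `"km/h"` (converted to m/s on read).
#' @param day_start,day_end Local hours bounding daytime. Daytime is the
#'   half-open interval `[day_start, day_end)`; the default 05:00--18:00
#'   follows local sunrise/sunset, giving a 13 h day and an 11 h night.
#' @param gap_limit_min No travel segment is accumulated across a gap of more
#'   than this many minutes between consecutive 10-minute median positions.
#' @param distance_range_km Plausibility range for full-day travel distance;
#'   animal-days outside it are flagged `excluded`.
#' @param coverage_threshold Minimum fraction of a daypart's hours that must
#'   contain at least one behaviour record for the daypart summary to count as
#'   complete; incomplete rows are dropped from correlation analyses.
#' @param night_same_date If `TRUE` (default) a date's night is that date's
#'   18:00--24:00 plus that same date's 00:00--05:00. If `FALSE`, the pre-dawn
#'   hours are attributed to the previous calendar date (night spans midnight).
#' @param cci_envelope How to treat weather inputs outside the validity
#'   envelope of the climate-index equations: `"warn"` (compute anyway, warn),
#'   `"clamp"` (clamp to the envelope), or `"reject"` (error).
#' @return A list of class `"herd_config"`.
#' @export
herd_config <- function(tz = "Etc/GMT-10",
                        wind_unit = c("m/s", "km/h"),
                        day_start = 5L,
                        day_end = 18L,
                        gap_limit_min = 60,
                        distance_range_km = c(0, 10),
                        coverage_threshold = 0.8,
                        night_same_date = TRUE,
                        cci_envelope = c("warn", "clamp", "reject")) {
  wind_unit <- match.arg(wind_unit)
  cci_envelope <- match.arg(cci_envelope)
  stopifnot(day_start >= 0, day_end <= 24, day_start < day_end,
            length(distance_range_km) == 2,
            distance_range_km[1] <= distance_range_km[2],
            coverage_threshold >= 0, coverage_threshold <= 1)
  structure(list(tz = tz, wind_unit = wind_unit,
                 day_start = as.integer(day_start),
                 day_end = as.integer(day_end),
                 gap_limit_min = gap_limit_min,
                 distance_range_km = distance_range_km,
                 coverage_threshold = coverage_threshold,
                 night_same_date = isTRUE(night_same_date),
                 cci_envelope = cci_envelope),
            class = "herd_config")
}

#' The six behaviour classes of the collar ethogram
#' @export
behavior_classes <- c("grazing", "walking", "ruminating", "resting",
                      "drinking", "other")

#' @export
print.herd_config <- function(x, ...) {
  cat("thermoherd pipeline configuration\n")
  cat(sprintf("  timezone        : %s\n", x$tz))
  cat(sprintf("  wind unit (in)  : %s\n", x$wind_unit))
  cat(sprintf("  daytime         : [%02d:00, %02d:00)\n", x$day_start, x$day_end))
  cat(sprintf("  gap limit       : %g min\n", x$gap_limit_min))
  cat(sprintf("  distance range  : [%g, %g] km/day\n",
              x$distance_range_km[1], x$distance_range_km[2]))
  cat(sprintf("  coverage thresh : %g\n", x$coverage_threshold))
  invisible(x)
}

# daypart of an hour-of-day under a config: "day" or "night"
.daypart_of_hour <- function(hour, config) {
  ifelse(hour >= config$day_start & hour < config$day_end, "day", "night")
}

# length in hours of each daypart
.daypart_hours <- function(config) {
  day <- config$day_end - config$day_start
  c(full = 24, day = day, night = 24 - day)
}
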