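# Readers/writers for the five external streams. One CSV dialect throughout:
# comma-separated, header row, ISO-8601 timestamps interpreted at the
# configured fixed-offset timezone. GeoJSON vertices are (lon, lat) per the
# standard; internal matrices carry (lat, lon) -- the converters own the swap.

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

# ISO-8601 timestamp parser with row-numbered errors ("line" counts the
# header, matching what a user sees in the file).
.parse_time <- function(x, tz, what) {
  x <- sub("T", " ", x, fixed = TRUE)
  t <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = tz))
  for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(t)
    if (!any(miss)) break
    t[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = tz))
  }
  bad <- which(is.na(t) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop("unparseable timestamp in ", what, " at line ", bad[1] + 1L,
         ": '", x[bad[1]], "'", call. = FALSE)
  t
}

.fmt_time <- function(t, tz) format(t, "%Y-%m-%d %H:%M:%S", tz = tz)

#' Read a behaviour-label stream
#'
#' Expects columns `animal_id`, `t`, `label`; labels must be one of the six
#' ethogram classes in [behavior_classes] (5-second interval labels).
#'
#' @param path CSV file path.
#' @param tz Timezone of the timestamps (fixed trial offset).
#' @return Data frame with `animal_id` (character), `t` (POSIXct), `label`
#'   (factor over [behavior_classes]), sorted by animal then time.
#' @export
read_behavior <- function(path, tz = "Etc/GMT-10") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("animal_id", "t", "label"), basename(path))
  bad <- which(!df$label %in% behavior_classes)
  if (length(bad))
    stop("schema error in ", basename(path), ": unknown behaviour label '",
         df$label[bad[1]], "' at line ", bad[1] + 1L, call. = FALSE)
  out <- data.frame(animal_id = as.character(df$animal_id),
                    t = .parse_time(df$t, tz, basename(path)),
                    label = factor(df$label, levels = behavior_classes))
  out[order(out$animal_id, out$t), , drop = FALSE]
}

#' @rdname read_behavior
#' @param behavior Data frame as returned by [read_behavior()].
#' @export
write_behavior <- function(behavior, path, tz = "Etc/GMT-10") {
  utils::write.csv(data.frame(animal_id = behavior$animal_id,
                              t = .fmt_time(behavior$t, tz),
                              label = as.character(behavior$label)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GNSS fix stream
#'
#' Expects columns `animal_id`, `t`, `lat`, `lon` (WGS84 decimal degrees,
#' nominal 1 Hz cadence).
#' @inheritParams read_behavior
#' @return Data frame sorted by animal then time.
#' @export
read_gnss <- function(path, tz = "Etc/GMT-10") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("animal_id", "t", "lat", "lon"), basename(path))
  lat <- as.numeric(df$lat); lon <- as.numeric(df$lon)
  if (any(!is.finite(lat) | !is.finite(lon) |
            abs(lat) > 90 | abs(lon) > 180))
    stop("invalid coordinates in ", basename(path), call. = FALSE)
  out <- data.frame(animal_id = as.character(df$animal_id),
                    t = .parse_time(df$t, tz, basename(path)),
                    lat = lat, lon = lon)
  out[order(out$animal_id, out$t), , drop = FALSE]
}

#' @rdname read_gnss
#' @param gnss Data frame of fixes.
#' @export
write_gnss <- function(gnss, path, tz = "Etc/GMT-10") {
  utils::write.csv(data.frame(animal_id = gnss$animal_id,
                              t = .fmt_time(gnss$t, tz),
                              lat = sprintf("%.7f", gnss$lat),
                              lon = sprintf("%.7f", gnss$lon)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 10-minute weather-station record stream
#'
#' Expects columns `t`, `ta` (degC), `rh` (percent), `ws` (wind speed), `rad`
#' (W/m^2), `rain` (mm). Wind speed is stored internally in m/s; if the file's
#' unit is km/h, pass `wind_unit = "km/h"` and values are divided by 3.6.
#' An optional `trial_id` column is carried through.
#'
#' @inheritParams read_behavior
#' @param wind_unit Unit of the `ws` column in the file.
#' @export
read_weather <- function(path, tz = "Etc/GMT-10", wind_unit = c("m/s", "km/h")) {
  wind_unit <- match.arg(wind_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("t", "ta", "rh", "ws", "rad", "rain"), basename(path))
  out <- data.frame(t = .parse_time(df$t, tz, basename(path)),
                    ta = as.numeric(df$ta), rh = as.numeric(df$rh),
                    ws = as.numeric(df$ws), rad = as.numeric(df$rad),
                    rain = as.numeric(df$rain))
  if ("trial_id" %in% names(df)) out$trial_id <- as.character(df$trial_id)
  if (wind_unit == "km/h") out$ws <- out$ws / 3.6
  if (any(out$rh < 0 | out$rh > 100, na.rm = TRUE))
    stop("relative humidity outside [0, 100] in ", basename(path), call. = FALSE)
  if (any(out$rad < 0, na.rm = TRUE) || any(out$rain < 0, na.rm = TRUE))
    stop("negative radiation or rainfall in ", basename(path), call. = FALSE)
  out[order(out$t), , drop = FALSE]
}

#' @rdname read_weather
#' @param weather Data frame of weather records (ws in m/s).
#' @export
write_weather <- function(weather, path, tz = "Etc/GMT-10") {
  df <- data.frame(t = .fmt_time(weather$t, tz), ta = weather$ta,
                   rh = weather$rh, ws = weather$ws, rad = weather$rad,
                   rain = weather$rain)
  if ("trial_id" %in% names(weather)) df$trial_id <- weather$trial_id
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the animal table
#'
#' Long format: one row per animal per weigh date, with per-animal constants
#' repeated. Columns: `animal_id`, `trial_id`, `initial_weight` (kg),
#' `bos_indicus` (fraction in \[0, 1\]), `weigh_date` (ISO date, a Monday),
#' `weight` (kg).
#' @inheritParams read_behavior
#' @export
read_animals <- function(path, tz = "Etc/GMT-10") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("animal_id", "trial_id", "initial_weight",
                      "bos_indicus", "weigh_date", "weight"), basename(path))
  out <- data.frame(animal_id = as.character(df$animal_id),
                    trial_id = as.character(df$trial_id),
                    initial_weight = as.numeric(df$initial_weight),
                    bos_indicus = as.numeric(df$bos_indicus),
                    weigh_date = as.Date(df$weigh_date),
                    weight = as.numeric(df$weight))
  if (any(out$weight <= 0 | out$initial_weight <= 0, na.rm = TRUE))
    stop("non-positive weight in ", basename(path), call. = FALSE)
  if (any(out$bos_indicus < 0 | out$bos_indicus > 1, na.rm = TRUE))
    stop("bos_indicus outside [0, 1] in ", basename(path), call. = FALSE)
  out[order(out$animal_id, out$weigh_date), , drop = FALSE]
}

#' @rdname read_animals
#' @param animals Long-format animal table.
#' @export
write_animals <- function(animals, path) {
  utils::write.csv(data.frame(animal_id = animals$animal_id,
                              trial_id = animals$trial_id,
                              initial_weight = animals$initial_weight,
                              bos_indicus = animals$bos_indicus,
                              weigh_date = format(animals$weigh_date),
                              weight = animals$weight),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: validate a (lat, lon) ring matrix
.check_ring <- function(m, what) {
  if (!is.matrix(m) || ncol(m) != 2)
    stop("geometry error: ", what, " is not a 2-column vertex matrix",
         call. = FALSE)
  # drop an explicitly closed last vertex
  n <- nrow(m)
  if (n >= 2 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3)
    stop("geometry error: ", what, " has fewer than 3 distinct vertices",
         call. = FALSE)
  m
}

#' Canopy map constructor
#'
#' @param paddock Matrix of paddock-boundary vertices, columns `(lat, lon)`;
#'   the ring may be open or explicitly closed.
#' @param canopies List of canopy polygons in the same format.
#' @return Object of class `"canopy_map"`.
#' @export
canopy_map <- function(paddock, canopies = list()) {
  paddock <- .check_ring(paddock, "paddock")
  canopies <- lapply(seq_along(canopies), function(i)
    .check_ring(canopies[[i]], paste0("canopy ", i)))
  structure(list(paddock = paddock, canopies = canopies),
            class = "canopy_map")
}

#' @export
print.canopy_map <- function(x, ...) {
  cat(sprintf("canopy map: paddock with %d vertices, %d canopy polygon(s)\n",
              nrow(x$paddock), length(x$canopies)))
  invisible(x)
}

#' Read/write the canopy map as GeoJSON
#'
#' A FeatureCollection of Polygon features; each feature's `role` property is
#' `"paddock"` (exactly one) or `"canopy"`. GeoJSON coordinates are
#' `(lon, lat)`; the returned [canopy_map()] carries `(lat, lon)` matrices.
#' @param path GeoJSON file path.
#' @export
read_canopy <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features))
    stop("geometry error: ", basename(path), " is not a FeatureCollection",
         call. = FALSE)
  paddock <- NULL; canopies <- list()
  for (f in gj$features) {
    ring <- f$geometry$coordinates[[1]]  # outer ring, (lon, lat) pairs
    m <- do.call(rbind, lapply(ring, function(v)
      c(as.numeric(v[[2]]), as.numeric(v[[1]]))))  # swap to (lat, lon)
    role <- f$properties$role
    if (identical(role, "paddock")) paddock <- m
    else if (identical(role, "canopy")) canopies[[length(canopies) + 1L]] <- m
    else stop("geometry error: feature role must be 'paddock' or 'canopy'",
              call. = FALSE)
  }
  if (is.null(paddock))
    stop("geometry error: no paddock feature in ", basename(path),
         call. = FALSE)
  canopy_map(paddock, canopies)
}

#' @rdname read_canopy
#' @param map A [canopy_map()] object.
#' @export
write_canopy <- function(map, path) {
  ring_json <- function(m) {
    m <- rbind(m, m[1, ])  # GeoJSON rings are explicitly closed
    list(lapply(seq_len(nrow(m)), function(i) c(m[i, 2], m[i, 1])))
  }
  feat <- function(m, role) list(
    type = "Feature", properties = list(role = role),
    geometry = list(type = "Polygon", coordinates = ring_json(m)))
  gj <- list(type = "FeatureCollection",
             features = c(list(feat(map$paddock, "paddock")),
                          lapply(map$canopies, feat, role = "canopy")))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read all five input streams
#'
#' @param paths Named list or vector with elements `behavior`, `gnss`,
#'   `weather`, `canopy`, `animals` (file paths).
#' @param config A [herd_config()].
#' @return Named list with elements `behavior`, `gnss`, `weather`, `canopy`,
#'   `animals`, timestamps normalised to the configured trial offset.
#' @export
read_streams <- function(paths, config = herd_config()) {
  paths <- as.list(paths)
  .require_cols(paths, c("behavior", "gnss", "weather", "canopy", "animals"),
                "paths")
  list(behavior = read_behavior(paths$behavior, config$tz),
       gnss = read_gnss(paths$gnss, config$tz),
       weather = read_weather(paths$weather, config$tz, config$wind_unit),
       canopy = read_canopy(paths$canopy),
       animals = read_animals(paths$animals, config$tz))
}

#' Synchronise behaviour, position and weather streams onto hourly keys
#'
#' Joins hourly behaviour budgets, hourly open-time from 10-minute median
#' positions, and hourly weather/CCI onto `(animal_id, hour)` keys. The output
#' has one row per animal per hour in which *any* stream has data; streams
#' absent for a given hour contribute explicit `NA`s, never silent zeros.
#' Animals present in GNSS but absent from the behaviour stream are retained
#' with missing behaviour (a warning is logged).
#'
#' @param behavior Behaviour records (see [read_behavior()]), or an hourly
#'   budget table from [hourly_budget()].
#' @param positions Classified median positions from [classify_open()]
#'   (may be `NULL`).
#' @param weather Weather records with CCI columns from [compute_cci()]
#'   (may be `NULL`).
#' @param config A [herd_config()].
#' @return Data frame keyed by `(animal_id, hour)` with behaviour hours per
#'   class, `coverage`, `time_in_open`, `n_intervals`, and hourly `cci_max`,
#'   `ta_mean`.
#' @export
synchronize <- function(behavior, positions = NULL, weather = NULL,
                        config = herd_config()) {
  hb <- if (!is.null(behavior) && "label" %in% names(behavior))
    hourly_budget(behavior) else behavior
  tz <- config$tz

  animals <- character(); hours <- .POSIXct(numeric(0), tz = tz)
  if (!is.null(hb)) { animals <- union(animals, hb$animal_id); hours <- c(hours, hb$hour) }
  pos_hour <- NULL
  if (!is.null(positions) && nrow(positions)) {
    positions$hour <- as.POSIXct(trunc(positions$interval_start, "hours"))
    agg <- stats::aggregate(cbind(open = positions$in_open,
                                  n = rep(1L, nrow(positions))),
                            by = list(animal_id = positions$animal_id,
                                      hour = positions$hour), FUN = sum)
    pos_hour <- data.frame(animal_id = agg$animal_id, hour = agg$hour,
                           time_in_open = agg$open / 6, n_intervals = agg$n)
    animals <- union(animals, pos_hour$animal_id)
    hours <- c(hours, pos_hour$hour)
  }
  wx_hour <- NULL
  if (!is.null(weather) && nrow(weather)) {
    weather$hour <- as.POSIXct(trunc(weather$t, "hours"))
    wcols <- intersect(c("ta", "cci"), names(weather))
    agg <- stats::aggregate(weather[wcols], by = list(hour = weather$hour),
                            FUN = mean, na.rm = TRUE)
    names(agg)[match("ta", names(agg))] <- "ta_mean"
    if ("cci" %in% names(agg)) {
      mx <- stats::aggregate(list(cci_max = weather$cci),
                             by = list(hour = weather$hour), FUN = max,
                             na.rm = TRUE)
      agg <- merge(agg, mx, by = "hour")
      agg$cci <- NULL
    }
    wx_hour <- agg
    hours <- c(hours, wx_hour$hour)
  }
  if (!length(animals) || !length(hours))
    stop("synchronize: no animal-hour keys in the inputs", call. = FALSE)

  if (!is.null(hb) && !is.null(pos_hour)) {
    orphans <- setdiff(unique(pos_hour$animal_id), unique(hb$animal_id))
    if (length(orphans))
      warning("animal(s) present in GNSS but absent from behaviour stream: ",
              paste(orphans, collapse = ", "), "; retained with missing ",
              "behaviour", call. = FALSE)
  }

  hours <- sort(unique(hours))
  grid <- expand.grid(animal_id = sort(unique(animals)), hour = hours,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- grid
  if (!is.null(hb)) out <- merge(out, hb, by = c("animal_id", "hour"),
                                 all.x = TRUE, sort = FALSE)
  if (!is.null(pos_hour)) out <- merge(out, pos_hour,
                                       by = c("animal_id", "hour"),
                                       all.x = TRUE, sort = FALSE)
  if (!is.null(wx_hour)) out <- merge(out, wx_hour, by = "hour",
                                      all.x = TRUE, sort = FALSE)
  out <- out[order(out$animal_id, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  attr(out$hour, "tzone") <- tz
  out
}
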