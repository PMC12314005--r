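# GNSS trajectory processing: 10-minute median positions, canopy/open
# occupancy, haversine travel distances with a gap rule and a daily
# plausibility filter.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km (the estimator used for
#' consecutive 10-minute median positions). Vectorised; arguments recycle.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 1, 0)   # one degree of meridian arc, ~111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
        any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("coordinates out of range", call. = FALSE)
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                      r = 6371.0))
}

#' 10-minute median positions
#'
#' Reduces raw (nominally 1 Hz) fixes to one position per animal per
#' 10-minute interval containing at least one fix, taking the median of each
#' coordinate independently (the even-count convention is the mean of the two
#' middle values). Intervals with no fixes are absent from the output.
#'
#' @param fixes Data frame with `animal_id`, `t` (POSIXct), `lat`, `lon`.
#' @return Data frame with `animal_id`, `interval_start` (aligned to the
#'   10-minute grid), `lat`, `lon`, `n_fixes`.
#' @export
median_positions <- function(fixes) {
  if (is.null(fixes) || nrow(fixes) == 0)
    return(data.frame(animal_id = character(),
                      interval_start = as.POSIXct(character()),
                      lat = numeric(), lon = numeric(),
                      n_fixes = integer()))
  tz <- attr(fixes$t, "tzone")
  if (is.null(tz)) tz <- ""
  iv <- floor(as.numeric(fixes$t) / 600) * 600
  key <- paste(fixes$animal_id, iv, sep = "\r")
  o <- order(key)
  key <- key[o]
  lat <- fixes$lat[o]; lon <- fixes$lon[o]
  first <- !duplicated(key)
  idx <- cumsum(first)
  med_lat <- as.numeric(tapply(lat, idx, stats::median))
  med_lon <- as.numeric(tapply(lon, idx, stats::median))
  n <- as.integer(tabulate(idx))
  parts <- strsplit(key[first], "\r", fixed = TRUE)
  out <- data.frame(
    animal_id = vapply(parts, `[`, "", 1L),
    interval_start = .POSIXct(as.numeric(vapply(parts, `[`, "", 2L)), tz = tz),
    lat = med_lat, lon = med_lon, n_fixes = n)
  out <- out[order(out$animal_id, out$interval_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Even-odd ray casting, vectorised over points; a point exactly on a ring
# edge or vertex counts as inside. `ring` is an open (lat, lon) matrix.
.point_in_ring <- function(lat, lon, ring) {
  n <- nrow(ring)
  inside <- logical(length(lat))
  on_edge <- logical(length(lat))
  tol <- 1e-12
  j <- n
  for (i in seq_len(n)) {
    yi <- ring[i, 1]; xi <- ring[i, 2]
    yj <- ring[j, 1]; xj <- ring[j, 2]
    cross <- (xj - xi) * (lat - yi) - (yj - yi) * (lon - xi)
    within <- lon >= pmin(xi, xj) - tol & lon <= pmax(xi, xj) + tol &
      lat >= pmin(yi, yj) - tol & lat <= pmax(yi, yj) + tol
    on_edge <- on_edge | (abs(cross) <= tol & within)
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < xi + (lat - yi) * (xj - xi) / (yj - yi))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Classify median positions as open or under canopy
#'
#' A position is *open* iff it lies inside the paddock and inside no canopy
#' polygon (even-odd ray casting). A point exactly on a canopy boundary counts
#' as canopy, not open -- the conservative convention for shade estimates.
#' Points outside the paddock are classified (`in_open = FALSE`), flagged
#' `out_of_paddock`, and a warning is logged.
#'
#' @param positions Data frame from [median_positions()] (any data frame with
#'   `lat`, `lon` works).
#' @param map A [canopy_map()].
#' @return `positions` with logical columns `in_open` and `out_of_paddock`
#'   appended.
#' @export
classify_open <- function(positions, map) {
  stopifnot(inherits(map, "canopy_map"))
  if (nrow(positions) == 0) {
    positions$in_open <- logical(0)
    positions$out_of_paddock <- logical(0)
    return(positions)
  }
  in_paddock <- .point_in_ring(positions$lat, positions$lon, map$paddock)
  in_canopy <- rep(FALSE, nrow(positions))
  for (poly in map$canopies)
    in_canopy <- in_canopy | .point_in_ring(positions$lat, positions$lon, poly)
  positions$in_open <- in_paddock & !in_canopy
  positions$out_of_paddock <- !in_paddock
  if (any(positions$out_of_paddock))
    warning(sum(positions$out_of_paddock),
            " position(s) outside the paddock boundary", call. = FALSE)
  positions
}

#' Daypart movement summaries
#'
#' Per animal, date and daypart (`full`, `day`, `night`): time in the open
#' (daytime only; 1/6 h per open 10-minute interval), travel distance as the
#' sum of haversine segments between consecutive median positions (each
#' segment is attributed to the daypart of its starting interval, so day and
#' night distances partition the full-day distance exactly on gap-free
#' tracks; no segment spans a gap longer than `config$gap_limit_min`), and
#' the plausibility flag `excluded`, set when the full-day distance falls
#' outside `config$distance_range_km` and propagated to all three dayparts
#' of that animal-day.
#'
#' @param positions Classified positions from [classify_open()].
#' @param config A [herd_config()].
#' @return Data frame with `animal_id`, `date`, `daypart`, `time_in_open`,
#'   `time_under_canopy`, `distance`, `n_intervals`, `excluded`.
#' @export
movement_summary <- function(positions, config = herd_config()) {
  cols <- c("animal_id", "interval_start", "lat", "lon", "in_open")
  stopifnot(all(cols %in% names(positions)))
  p <- positions[order(positions$animal_id, positions$interval_start), ]
  tz <- config$tz
  lt <- as.POSIXlt(p$interval_start, tz = tz)
  p$date <- as.Date(lt)
  hod <- lt$hour
  p$daypart <- .daypart_of_hour(hod, config)
  if (!config$night_same_date) {
    predawn <- hod < config$day_start
    p$date[predawn] <- p$date[predawn] - 1L
  }

  n <- nrow(p)
  # consecutive-segment distances (row i -> i+1), masked at animal/date/gap
  # boundaries
  if (n >= 2) {
    i1 <- seq_len(n - 1); i2 <- i1 + 1
    seg <- haversine_km(p$lat[i1], p$lon[i1], p$lat[i2], p$lon[i2])
    same_animal <- p$animal_id[i1] == p$animal_id[i2]
    same_date <- p$date[i1] == p$date[i2]
    dt_min <- as.numeric(difftime(p$interval_start[i2], p$interval_start[i1],
                                  units = "mins"))
    ok <- same_animal & same_date & dt_min <= config$gap_limit_min
  } else {
    seg <- numeric(0); ok <- logical(0)
    i1 <- integer(0)
  }

  # integer (animal, date) keys keep the aggregation fast at trial scale
  aid_f <- factor(p$animal_id)
  ukey <- (as.integer(aid_f) - 1) * 1e6 + as.integer(p$date)
  lev <- sort(unique(ukey))
  kf <- match(ukey, lev)
  nk <- length(lev)
  sum_by <- function(val, rows) {
    out <- numeric(nk)
    if (length(rows)) {
      s <- rowsum(val, kf[rows])
      out[as.integer(rownames(s))] <- s[, 1]
    }
    out
  }

  full_dist <- sum_by(seg[ok], i1[ok])
  day_seg <- ok & p$daypart[i1] == "day"
  night_seg <- ok & p$daypart[i1] == "night"
  day_dist <- sum_by(seg[day_seg], i1[day_seg])
  night_dist <- sum_by(seg[night_seg], i1[night_seg])

  cnt <- function(rows) sum_by(rep(1, length(rows)), rows)
  n_full <- cnt(seq_len(n))
  day_idx <- which(p$daypart == "day")
  night_idx <- which(p$daypart == "night")
  n_day <- cnt(day_idx)
  n_night <- cnt(night_idx)
  open_day <- sum_by(as.numeric(p$in_open[day_idx]), day_idx)

  aid <- levels(aid_f)[lev %/% 1e6 + 1]
  dte <- as.Date(lev %% 1e6, origin = "1970-01-01")
  excl <- full_dist < config$distance_range_km[1] |
    full_dist > config$distance_range_km[2]

  mk <- function(daypart, dist, nint, open, canop) {
    data.frame(animal_id = aid, date = dte, daypart = daypart,
               time_in_open = open, time_under_canopy = canop,
               distance = dist, n_intervals = as.integer(nint),
               excluded = excl)
  }
  out <- rbind(
    mk("full", full_dist, n_full, NA_real_, NA_real_),
    mk("day", day_dist, n_day, open_day / 6, (n_day - open_day) / 6),
    mk("night", night_dist, n_night, NA_real_, NA_real_))
  out <- out[order(out$animal_id, out$date, out$daypart), ]
  rownames(out) <- NULL
  out
}
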