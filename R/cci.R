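# Comprehensive Climate Index (CCI) of Mader, Johnson & Gaughan (2010),
# J. Anim. Sci. 88:2153-2165: apparent temperature = air temperature plus
# additive adjustments for relative humidity, wind speed and solar radiation,
# valid across both cold- and heat-stress ranges.
#
# All equation coefficients live in this one table so the index is auditable
# and swappable; do not scatter literals elsewhere.
.cci_constants <- list(
  version = "mader-2010",
  # RH adjustment: exp(e1*RH + e2*Ta*RH) * (q2*Ta^2 + q1*Ta + q0) * (RH - rh_ref)
  rh = c(e1 = 0.00182, e2 = 1.8e-5, q2 = 0.000054, q1 = 0.00192,
         q0 = -0.0246, rh_ref = 30),
  # WS adjustment:
  #   a / exp( (1/(b*WS + c)) ^ (d*(e + f*WS^p - log_base(b*WS + g))) ) + h*WS^2 + i
  ws = c(a = -6.56, b = 2.26, c = 0.23, d = 0.45, e = 2.9, f = 1.14e-6,
         p = 2.5, g = 0.33, log_base = 0.3, h = -0.00566, i = 3.33),
  # RAD adjustment: a*RAD + b*RAD*Ta + c*Ta^2*sqrt(RAD) + d*Ta + e
  rad = c(a = 0.0076, b = -0.00002, c = 0.00005, d = 0.1, e = -2),
  # validity envelope of the published equations (approximate; inputs outside
  # it are computed with a warning by default)
  envelope = list(ta = c(-30, 45), ws = c(0, 30), rad = c(0, 1500))
)

.cci_rh_adj <- function(ta, rh) {
  k <- .cci_constants$rh
  exp(k[["e1"]] * rh + k[["e2"]] * ta * rh) *
    (k[["q2"]] * ta^2 + k[["q1"]] * ta + k[["q0"]]) * (rh - k[["rh_ref"]])
}

.cci_ws_adj <- function(ws) {
  k <- .cci_constants$ws
  inner <- (1 / (k[["b"]] * ws + k[["c"]]))^(k[["d"]] *
    (k[["e"]] + k[["f"]] * ws^k[["p"]] -
       log(k[["b"]] * ws + k[["g"]], base = k[["log_base"]])))
  k[["a"]] / exp(inner) + k[["h"]] * ws^2 + k[["i"]]
}

.cci_rad_adj <- function(ta, rad) {
  k <- .cci_constants$rad
  k[["a"]] * rad + k[["b"]] * rad * ta + k[["c"]] * ta^2 * sqrt(rad) +
    k[["d"]] * ta + k[["e"]]
}

#' Comprehensive Climate Index from weather records
#'
#' Computes the CCI and its additive decomposition for each weather record:
#' `cci = ta + rh_adj + ws_adj + rad_adj`, where the three adjustments (in
#' degree-Celsius equivalents) correct air temperature for relative humidity,
#' wind speed and solar radiation. Wind speed must be in m/s (see
#' [read_weather()] for unit conversion on input).
#'
#' @param weather Data frame with columns `ta` (air temperature, degC), `rh`
#'   (relative humidity, percent, in \[0, 100\]), `ws` (wind speed, m/s) and
#'   `rad` (solar radiation, W/m^2, non-negative). A timestamp column `t` and
#'   any further columns are carried through.
#' @param envelope Treatment of inputs outside the validity envelope of the
#'   index equations: `"warn"` (default; compute and warn), `"clamp"`, or
#'   `"reject"`. Humidity outside \[0, 100\] or negative radiation is always a
#'   domain error.
#' @return `weather` with columns `rh_adj`, `ws_adj`, `rad_adj` and `cci`
#'   appended.
#' @examples
#' w <- data.frame(ta = 30, rh = 50, ws = 1.2, rad = 600)
#' compute_cci(w)
#' @export
compute_cci <- function(weather, envelope = c("warn", "clamp", "reject")) {
  envelope <- match.arg(envelope)
  for (col in c("ta", "rh", "ws", "rad")) {
    if (!col %in% names(weather))
      stop("weather is missing required column '", col, "'", call. = FALSE)
  }
  ta <- as.numeric(weather$ta); rh <- as.numeric(weather$rh)
  ws <- as.numeric(weather$ws); rad <- as.numeric(weather$rad)
  ok <- stats::complete.cases(ta, rh, ws, rad)
  if (any(rh[ok] < 0 | rh[ok] > 100))
    stop("relative humidity outside [0, 100]", call. = FALSE)
  if (any(rad[ok] < 0))
    stop("negative solar radiation", call. = FALSE)
  if (any(ws[ok] < 0))
    stop("negative wind speed", call. = FALSE)

  env <- .cci_constants$envelope
  out_env <- ok & (ta < env$ta[1] | ta > env$ta[2] |
                     ws > env$ws[2] | rad > env$rad[2])
  if (any(out_env)) {
    if (envelope == "reject")
      stop(sum(out_env), " weather record(s) outside the CCI validity envelope",
           call. = FALSE)
    if (envelope == "clamp") {
      ta <- pmin(pmax(ta, env$ta[1]), env$ta[2])
      ws <- pmin(ws, env$ws[2])
      rad <- pmin(rad, env$rad[2])
    } else {
      warning(sum(out_env),
              " weather record(s) outside the CCI validity envelope; ",
              "computed anyway", call. = FALSE)
    }
  }

  weather$rh_adj <- .cci_rh_adj(ta, rh)
  weather$ws_adj <- .cci_ws_adj(ws)
  weather$rad_adj <- .cci_rad_adj(ta, rad)
  weather$cci <- ta + weather$rh_adj + weather$ws_adj + weather$rad_adj
  weather
}

#' Daily maximum CCI
#'
#' Reduces a CCI series to one record per local calendar date carrying the
#' date's maximum CCI (the peak-thermal-load summary attached downstream to
#' full-day, daytime and nighttime summaries alike) and the number of
#' contributing records. Dates with no records are simply absent.
#'
#' @param cci Data frame from [compute_cci()] with a POSIXct column `t` and a
#'   numeric column `cci`; an optional `trial_id` column is carried through
#'   (the maximum is then per trial and date).
#' @param tz Timezone used to assign records to calendar dates.
#' @return Data frame with columns `trial_id` (if present), `date`, `max_cci`,
#'   `n_records`.
#' @export
daily_max_cci <- function(cci, tz = "Etc/GMT-10") {
  stopifnot(is.data.frame(cci), nrow(cci) > 0,
            all(c("t", "cci") %in% names(cci)))
  date <- as.Date(format(cci$t, "%Y-%m-%d", tz = tz))
  keep <- !is.na(cci$cci)
  if (!all(keep)) {
    message("daily_max_cci: dropping ", sum(!keep), " record(s) with missing CCI")
  }
  if (!any(keep)) stop("no non-missing CCI records", call. = FALSE)
  if ("trial_id" %in% names(cci)) {
    key <- interaction(cci$trial_id[keep], date[keep], drop = TRUE, sep = "\r")
    mx <- tapply(cci$cci[keep], key, max)
    n <- tapply(cci$cci[keep], key, length)
    parts <- strsplit(names(mx), "\r", fixed = TRUE)
    out <- data.frame(trial_id = vapply(parts, `[`, "", 1L),
                      date = as.Date(vapply(parts, `[`, "", 2L)),
                      max_cci = as.numeric(mx),
                      n_records = as.integer(n))
    out <- out[order(out$trial_id, out$date), ]
  } else {
    mx <- tapply(cci$cci[keep], date[keep], max)
    n <- tapply(cci$cci[keep], date[keep], length)
    out <- data.frame(date = as.Date(names(mx)),
                      max_cci = as.numeric(mx),
                      n_records = as.integer(n))
    out <- out[order(out$date), ]
  }
  rownames(out) <- NULL
  out
}
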