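# Synthetic two-trial generator: weather -> CCI, GNSS tracks with
# CCI-dependent canopy occupancy, ethogram labels with CCI-dependent
# day->night grazing shift and daytime-resting gain, and animal weights with
# behaviour-linked weekly gains. Effects are planted at the daily-budget
# level so their theoretical signs/magnitudes are available in closed form;
# ground truth is returned alongside the streams.

#' Simulation configuration
#'
#' Defaults encode the study conditions being emulated: two 4-week trials of
#' 60 collared animals on ~3 ha paddocks in a subtropical late-spring/early-
#' summer climate (daily maximum CCI spanning roughly 36--52), behaviour
#' budgets centred on the observed weekly medians (grazing ~7 h/day,
#' ruminating ~2.9 h, resting ~2.1 h, walking ~0.75 h, drinking ~0.1 h),
#' initial weights with median 259 kg and spread 39 kg, Bos indicus
#' proportion uniform on \[0.47, 0.95\], and ~25 kg median gain over 4 weeks.
#'
#' @param seed Integer RNG seed; the full fixture is a pure function of the
#'   configuration.
#' @param n_animals Animals per trial.
#' @param n_days Days per trial window.
#' @param trial_starts Two Monday start dates.
#' @param resolution `"hourly"` emits hourly behaviour budgets and 10-minute
#'   median positions directly (the trial-scale route); `"full"` emits
#'   5-second labels and `gnss_hz` Hz fixes (used at small scale and for
#'   fixture files). Both share identical planted daily targets.
#' @param gnss_hz Fix rate in Hz for `resolution = "full"`.
#' @param effects Named list of planted effect sizes: `shade_affinity`
#'   (logit of daytime canopy occupancy per CCI unit), `graze_shift` (hours
#'   of grazing moved day to night per CCI unit), `rest_gain` (daytime
#'   resting hours per CCI unit), `walk_bos_cci` (walking hours per CCI unit
#'   per unit Bos indicus deviation), `gain_graze` and `gain_dist` (kg of
#'   weekly gain per unit of mean daily grazing hours / distance km).
#' @param weather Named list of weather-process parameters (see defaults).
#' @param cci_midpoint Centre of the CCI range; planted effects are linear in
#'   `max_cci - cci_midpoint`.
#' @param animal_sd Named list of animal-level random-effect SDs (set to zero
#'   for a fully exchangeable null fixture).
#' @param bos_range,weight_median,weight_spread,weekly_gain_base,gain_noise
#'   Animal-table parameters.
#' @param ... Reserved.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_animals = 60L,
                       n_days = 28L,
                       trial_starts = c(trial1 = "2022-11-21",
                                        trial2 = "2023-11-20"),
                       resolution = c("hourly", "full"),
                       gnss_hz = 1,
                       effects = list(),
                       weather = list(),
                       cci_midpoint = 44,
                       animal_sd = list(),
                       bos_range = c(0.47, 0.95),
                       weight_median = 259,
                       weight_spread = 39,
                       weekly_gain_base = 6.25,
                       gain_noise = 2.2,
                       ...) {
  resolution <- match.arg(resolution)
  eff <- utils::modifyList(list(
    shade_affinity = 0.12,  # logit canopy occupancy per CCI unit (daytime)
    graze_shift = 0.12,     # h of grazing moved day -> night per CCI unit
    rest_gain = 0.06,       # daytime resting h per CCI unit
    walk_bos_cci = 0.03,    # walking h per CCI unit per unit bos deviation
    gain_graze = 0.8,       # kg weekly gain per h of mean daily grazing
    gain_dist = -0.5        # kg weekly gain per km of mean daily distance
  ), effects)
  wx <- utils::modifyList(list(
    ta_mean = 26.5, ta_amp = 7, ta_peak_hour = 15,
    ar_phi = 0.65, ar_sd = 2.2, ta_noise = 0.3,
    trial_offset = c(0, 0.8),
    rh_mean = 65, rh_slope = -1.8, rh_noise = 3,
    rad_peak = 950, sunrise = 5.5, sunset = 18.5,
    ws_meanlog = log(1.2), ws_sdlog = 0.45,
    rain_prob = 0.25, rain_shape = 0.7, rain_scale = 12
  ), weather)
  asd <- utils::modifyList(list(
    grazing = 0.35, ruminating = 0.3, resting = 0.25, walking = 0.1
  ), animal_sd)
  stopifnot(vapply(eff, is.finite, TRUE), length(trial_starts) == 2)
  structure(list(seed = as.integer(seed), n_animals = as.integer(n_animals),
                 n_days = as.integer(n_days),
                 trial_starts = trial_starts, resolution = resolution,
                 gnss_hz = gnss_hz, effects = eff, weather = wx,
                 cci_midpoint = cci_midpoint, animal_sd = asd,
                 bos_range = bos_range, weight_median = weight_median,
                 weight_spread = weight_spread,
                 weekly_gain_base = weekly_gain_base,
                 gain_noise = gain_noise,
                 # baseline daily behaviour budgets (hours)
                 budgets = list(
                   grazing_total = 7.0, grazing_total_sd = 0.45,
                   grazing_day_frac = 0.75, graze_shift_sd = 0.25,
                   ruminating_total = 2.9, ruminating_sd = 0.35,
                   ruminating_day_frac = 0.45,
                   resting_day = 1.3, resting_day_sd = 0.3,
                   resting_night = 0.8, resting_night_sd = 0.2,
                   walking_total = 0.75, walking_sd = 0.12,
                   walking_day_frac = 0.7,
                   drinking_total = 0.07, drinking_sd = 0.04,
                   other_total = 0.15),
                 # occupancy model
                 shade_base_logit = stats::qlogis(0.17),
                 night_canopy_prob = 0.15,
                 # geometry (metres)
                 paddock_m = c(200, 150), origin = c(-27.55, 152.33),
                 canopy_side_m = 22,
                 canopy_xy = rbind(c(45, 35), c(145, 45), c(95, 105)),
                 open_scatter_m = 10, anchor_offset_m = 28,
                 walk_noise_m = 4, gps_noise_m = 3),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed %d, %d animals x 2 trials x %d days, %s resolution\n",
              x$seed, x$n_animals, x$n_days, x$resolution))
  invisible(x)
}

# metres -> degrees at the paddock origin
.m2deg <- function(cfg) {
  lat0 <- cfg$origin[1]
  c(lat = 1 / 111320, lon = 1 / (111320 * cos(lat0 * pi / 180)))
}

#' Synthetic paddock and canopy map
#'
#' A ~3 ha rectangular paddock with square canopy polygons at fixed interior
#' positions. Purely deterministic given the configuration.
#' @param cfg A [sim_config()].
#' @return A [canopy_map()].
#' @export
generate_paddock <- function(cfg) {
  s <- .m2deg(cfg); lat0 <- cfg$origin[1]; lon0 <- cfg$origin[2]
  xy2ll <- function(x, y) cbind(lat = lat0 + y * s["lat"],
                                lon = lon0 + x * s["lon"])
  W <- cfg$paddock_m[1]; H <- cfg$paddock_m[2]
  paddock <- xy2ll(c(0, W, W, 0), c(0, 0, H, H))
  half <- cfg$canopy_side_m / 2
  canopies <- lapply(seq_len(nrow(cfg$canopy_xy)), function(i) {
    cx <- cfg$canopy_xy[i, 1]; cy <- cfg$canopy_xy[i, 2]
    xy2ll(cx + c(-half, half, half, -half), cy + c(-half, -half, half, half))
  })
  canopy_map(paddock, canopies)
}

#' Synthetic 10-minute weather series for both trials
#'
#' Air temperature follows a diurnal sinusoid (peak mid-afternoon) riding on
#' an AR(1) day-to-day drift plus noise; humidity is anti-correlated with
#' temperature; radiation is a solar half-sine, exactly zero at night, scaled
#' by a daily cloud factor; wind is log-normal; rain is sparse. Parameters
#' are calibrated so daily maximum CCI spans roughly 36--52.
#'
#' @param cfg A [sim_config()]. Draws from the current RNG stream.
#' @return Weather data frame (`t`, `ta`, `rh`, `ws`, `rad`, `rain`,
#'   `trial_id`), ws in m/s.
#' @export
generate_weather <- function(cfg) {
  w <- cfg$weather
  tz <- "Etc/GMT-10"
  out <- list()
  for (tr in 1:2) {
    start <- as.Date(cfg$trial_starts[[tr]])
    n <- cfg$n_days
    # AR(1) day offsets, stationary start
    off <- numeric(n)
    off[1] <- stats::rnorm(1, 0, w$ar_sd / sqrt(1 - w$ar_phi^2))
    if (n > 1)
      for (d in 2:n) off[d] <- w$ar_phi * off[d - 1] +
        stats::rnorm(1, 0, w$ar_sd)
    cloud <- stats::runif(n, 0.55, 1)
    t0 <- as.POSIXct(paste(start, "00:00:00"), tz = tz)
    tt <- t0 + seq(0, n * 86400 - 600, by = 600)
    day_idx <- rep(seq_len(n), each = 144)
    hfrac <- (as.numeric(tt) - as.numeric(t0)) %% 86400 / 3600
    ta <- w$ta_mean + w$trial_offset[tr] + off[day_idx] +
      w$ta_amp * cos(2 * pi * (hfrac - w$ta_peak_hour) / 24) +
      stats::rnorm(length(tt), 0, w$ta_noise)
    rh <- pmin(100, pmax(5, w$rh_mean + w$rh_slope * (ta - w$ta_mean) +
                           stats::rnorm(length(tt), 0, w$rh_noise)))
    daylight <- hfrac >= w$sunrise & hfrac < w$sunset
    rad <- numeric(length(tt))
    rad[daylight] <- pmax(0, w$rad_peak * cloud[day_idx[daylight]] *
                            sin(pi * (hfrac[daylight] - w$sunrise) /
                                  (w$sunset - w$sunrise)) +
                            stats::rnorm(sum(daylight), 0, 15))
    ws <- stats::rlnorm(length(tt), w$ws_meanlog, w$ws_sdlog)
    rain <- numeric(length(tt))
    wet <- stats::runif(n) < w$rain_prob
    for (d in which(wet)) {
      total <- stats::rgamma(1, w$rain_shape, scale = w$rain_scale)
      k <- sample(1:6, 1)
      slot0 <- sample(1:(144 - k), 1)
      idx <- (d - 1) * 144 + slot0 + seq_len(k) - 1
      rain[idx] <- rain[idx] + total / k
    }
    out[[tr]] <- data.frame(t = tt, ta = ta, rh = rh, ws = ws, rad = rad,
                            rain = rain,
                            trial_id = names(cfg$trial_starts)[tr])
  }
  do.call(rbind, out)
}

# per-animal base profiles + behavioural random effects
.generate_profiles <- function(cfg) {
  out <- list()
  for (tr in 1:2) {
    ids <- sprintf("%s_A%02d", names(cfg$trial_starts)[tr],
                   seq_len(cfg$n_animals))
    out[[tr]] <- data.frame(
      animal_id = ids, trial_id = names(cfg$trial_starts)[tr],
      initial_weight = stats::rnorm(cfg$n_animals, cfg$weight_median,
                                    cfg$weight_spread),
      bos_indicus = stats::runif(cfg$n_animals, cfg$bos_range[1],
                                 cfg$bos_range[2]),
      re_grazing = stats::rnorm(cfg$n_animals, 0, cfg$animal_sd$grazing),
      re_ruminating = stats::rnorm(cfg$n_animals, 0, cfg$animal_sd$ruminating),
      re_resting = stats::rnorm(cfg$n_animals, 0, cfg$animal_sd$resting),
      re_walking = stats::rnorm(cfg$n_animals, 0, cfg$animal_sd$walking))
  }
  do.call(rbind, out)
}

# hourly allocation templates (positive everywhere so every hour is observed)
.templates <- list(
  day = list(hours = 5:17,
             grazing = c(1.6, 2, 1.6, 1, .7, .6, .6, .7, .9, 1.3, 1.8, 2, 1.6),
             ruminating = c(.6, .7, .9, 1.2, 1.4, 1.5, 1.5, 1.4, 1.2, 1, .8, .7, .6),
             resting = c(.4, .5, .8, 1.2, 1.5, 1.7, 1.7, 1.5, 1.2, .9, .6, .5, .4),
             walking = c(1.2, 1.1, 1, 1, .9, .9, .9, .9, 1, 1, 1.1, 1.2, 1.2),
             drinking = c(.3, .5, .8, 1.2, 1.5, 1.6, 1.6, 1.5, 1.2, .9, .6, .4, .3),
             other = rep(1, 13)),
  night = list(hours = c(18:23, 0:4),
               grazing = c(1.8, 1.5, 1.2, .9, .8, .7, .5, .4, .4, .5, .9),
               ruminating = c(.8, 1, 1.2, 1.3, 1.3, 1.2, 1.2, 1.1, 1, .9, .8),
               resting = c(.8, .9, 1, 1.2, 1.3, 1.3, 1.2, 1.2, 1.1, 1, .9),
               walking = rep(1, 11),
               drinking = rep(1, 11),
               other = rep(1, 11)))

# planted daily behaviour targets for each animal-day (the ground truth)
.daily_targets <- function(cfg, profiles, daily_cci) {
  b <- cfg$budgets; eff <- cfg$effects
  grid <- merge(profiles, daily_cci[c("trial_id", "date", "max_cci")],
                by = "trial_id")
  grid <- grid[order(grid$animal_id, grid$date), ]
  n <- nrow(grid)
  cci_c <- grid$max_cci - cfg$cci_midpoint
  bos_c <- grid$bos_indicus - mean(cfg$bos_range)

  graz_tot <- pmax(3, pmin(11, b$grazing_total + grid$re_grazing +
                             stats::rnorm(n, 0, b$grazing_total_sd)))
  shift <- eff$graze_shift * cci_c + stats::rnorm(n, 0, b$graze_shift_sd)
  graz_day <- pmax(0.3, pmin(12, b$grazing_day_frac * graz_tot - shift))
  graz_night <- pmax(0.1, pmin(10, (1 - b$grazing_day_frac) * graz_tot + shift))

  rum_tot <- pmax(1, pmin(5, b$ruminating_total + grid$re_ruminating +
                            stats::rnorm(n, 0, b$ruminating_sd)))
  rest_day <- pmax(0.2, pmin(6, b$resting_day + grid$re_resting +
                               eff$rest_gain * cci_c +
                               stats::rnorm(n, 0, b$resting_day_sd)))
  rest_night <- pmax(0.1, pmin(4, b$resting_night +
                                 stats::rnorm(n, 0, b$resting_night_sd)))
  walk_tot <- pmax(0.2, pmin(2, b$walking_total + grid$re_walking +
                               eff$walk_bos_cci * bos_c * cci_c +
                               stats::rnorm(n, 0, b$walking_sd)))
  drink_tot <- pmax(0, pmin(0.4, stats::rnorm(n, b$drinking_total,
                                              b$drinking_sd)))
  p_canopy_day <- pmin(0.99, pmax(0.01, stats::plogis(
    cfg$shade_base_logit + eff$shade_affinity * cci_c)))

  data.frame(
    animal_id = grid$animal_id, trial_id = grid$trial_id, date = grid$date,
    max_cci = grid$max_cci, bos_indicus = grid$bos_indicus,
    grazing_day = graz_day, grazing_night = graz_night,
    ruminating_day = b$ruminating_day_frac * rum_tot,
    ruminating_night = (1 - b$ruminating_day_frac) * rum_tot,
    resting_day = rest_day, resting_night = rest_night,
    walking_day = b$walking_day_frac * walk_tot,
    walking_night = (1 - b$walking_day_frac) * walk_tot,
    drinking_day = 0.8 * drink_tot, drinking_night = 0.2 * drink_tot,
    other_day = 0.6 * b$other_total, other_night = 0.4 * b$other_total,
    p_canopy_day = p_canopy_day)
}

# allocate daypart class targets (hours) to hours of day; returns an
# (n_animal_days x 24) matrix per class, capped at 1 h per hour in total,
# quantised to 5-s counts
.allocate_hours <- function(targets) {
  n <- nrow(targets)
  mats <- lapply(behavior_classes, function(cl) matrix(0, n, 24))
  names(mats) <- behavior_classes
  for (dp in c("day", "night")) {
    tpl <- .templates[[dp]]
    nh <- length(tpl$hours)
    for (cl in behavior_classes) {
      w <- matrix(stats::rgamma(n * nh, shape = 5, rate = 5), n, nh)
      w <- w * rep(tpl[[cl]], each = n)
      w <- w / rowSums(w)
      tgt <- targets[[paste0(cl, "_", dp)]]
      mats[[cl]][, tpl$hours + 1L] <- mats[[cl]][, tpl$hours + 1L] + w * tgt
    }
  }
  tot <- Reduce(`+`, mats)
  scale <- ifelse(tot > 1, 1 / tot, 1)
  # flooring (not rounding) to the 5-s grid keeps each hour's six-class
  # total at or below the 720-slot capacity
  for (cl in behavior_classes)
    mats[[cl]] <- floor(mats[[cl]] * scale * 720) / 720
  mats
}

#' Synthetic behaviour stream
#'
#' Draws per-animal-day class-hour targets around the observed weekly-median
#' envelope with animal-level random effects, plants the CCI-linear
#' day-to-night grazing shift and daytime-resting gain, allocates targets to
#' hours through diurnal templates (capped at 1 h per hour, quantised to the
#' 5-second label grid), and emits either an hourly budget table
#' (`resolution = "hourly"`) or 5-second label records (`"full"`).
#'
#' @param cfg A [sim_config()].
#' @param daily_cci Per-trial daily maximum CCI ([daily_max_cci()] on the
#'   generated weather).
#' @param profiles Internal profile table (from [simulate_trials()]).
#' @return List with `stream` (records or hourly table), `targets` (planted
#'   daily targets) and `realized` (post-quantisation daypart budgets).
#' @export
generate_behaviors <- function(cfg, daily_cci, profiles) {
  targets <- .daily_targets(cfg, profiles, daily_cci)
  mats <- .allocate_hours(targets)
  n <- nrow(targets)
  tz <- "Etc/GMT-10"
  day_hours <- .templates$day$hours

  # realized daypart budgets after capping/quantisation
  realized <- targets[c("animal_id", "trial_id", "date", "max_cci",
                        "bos_indicus", "p_canopy_day")]
  for (cl in behavior_classes) {
    realized[[paste0(cl, "_day")]] <- rowSums(mats[[cl]][, day_hours + 1L,
                                                         drop = FALSE])
    realized[[paste0(cl, "_night")]] <- rowSums(mats[[cl]]) -
      realized[[paste0(cl, "_day")]]
  }

  day0 <- as.POSIXct(paste(targets$date, "00:00:00"), tz = tz)
  if (cfg$resolution == "hourly") {
    hour <- rep(day0, each = 24) + rep(0:23 * 3600, times = n)
    tab <- data.frame(animal_id = rep(targets$animal_id, each = 24),
                      hour = hour)
    for (cl in behavior_classes) tab[[cl]] <- as.numeric(t(mats[[cl]]))
    tab$coverage <- rowSums(as.matrix(tab[behavior_classes]))
    tab <- tab[order(tab$animal_id, tab$hour), ]
    rownames(tab) <- NULL
    return(list(stream = tab, targets = targets, realized = realized))
  }

  # full resolution: expand counts to 5-s label records, classes in blocks
  counts <- lapply(mats, function(m) round(t(m) * 720))  # 24 x n matrices
  recs <- list()
  for (cl in behavior_classes) {
    cnt <- counts[[cl]]
    idx <- which(cnt > 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    reps <- cnt[idx]
    # offset of the class block within the hour: cumulative counts of the
    # classes emitted before it
    before <- matrix(0, 24, n)
    for (prev in behavior_classes) {
      if (prev == cl) break
      before <- before + counts[[prev]]
    }
    start <- rep(day0[idx[, 2]] + (idx[, 1] - 1) * 3600 +
                   before[idx] * 5, reps)
    within <- unlist(lapply(reps, seq_len)) - 1L
    recs[[cl]] <- data.frame(
      animal_id = rep(targets$animal_id[idx[, 2]], reps),
      t = start + within * 5,
      label = cl)
  }
  stream <- do.call(rbind, recs)
  stream$label <- factor(stream$label, levels = behavior_classes)
  stream <- stream[order(stream$animal_id, stream$t), ]
  rownames(stream) <- NULL
  list(stream = stream, targets = targets, realized = realized)
}

#' Synthetic GNSS stream
#'
#' Per animal and 10-minute block, canopy occupancy is Bernoulli with the
#' planted daily logistic probability during daytime and a fixed probability
#' at night. Canopy blocks place the animal uniformly inside its animal-day
#' home canopy; open blocks scatter around an open anchor near that canopy,
#' so consecutive-position distances stay in the observed 2.5--4 km/day
#' envelope and below the 10 km plausibility bound. `resolution = "full"`
#' expands each block into `gnss_hz` Hz fixes with walk and receiver noise
#' (~3 m); `"hourly"` emits the block (median) positions directly.
#'
#' @inheritParams generate_behaviors
#' @param map The [generate_paddock()] canopy map.
#' @param targets Planted daily targets from [generate_behaviors()].
#' @return List with `stream` (fixes or median positions) and `blocks`
#'   (per-block ground-truth states).
#' @export
generate_tracks <- function(cfg, targets, map) {
  s <- .m2deg(cfg); tz <- "Etc/GMT-10"
  half <- cfg$canopy_side_m / 2
  k <- nrow(cfg$canopy_xy)
  # open anchors: offset from each canopy centre toward the paddock centre
  centre <- cfg$paddock_m / 2
  anchors <- t(vapply(seq_len(k), function(i) {
    v <- centre - cfg$canopy_xy[i, ]
    cfg$canopy_xy[i, ] + v / sqrt(sum(v^2)) * (half + cfg$anchor_offset_m)
  }, numeric(2)))

  n_ad <- nrow(targets)
  nb <- 144L
  N <- n_ad * nb
  block_h <- rep(0:143 %/% 6, times = n_ad)  # hour of day per block, per day
  is_day <- block_h >= 5 & block_h < 18
  p <- ifelse(is_day, rep(targets$p_canopy_day, each = nb),
              cfg$night_canopy_prob)
  in_canopy <- stats::runif(N) < p
  home <- rep(sample.int(k, n_ad, replace = TRUE), each = nb)

  cx <- cfg$canopy_xy[home, 1]; cy <- cfg$canopy_xy[home, 2]
  # canopy blocks: uniform in the inner 70% of the home canopy square
  x <- cx + stats::runif(N, -0.7 * half, 0.7 * half)
  y <- cy + stats::runif(N, -0.7 * half, 0.7 * half)
  # open blocks: Gaussian scatter around the home open anchor
  ox <- anchors[home, 1] + stats::rnorm(N, 0, cfg$open_scatter_m)
  oy <- anchors[home, 2] + stats::rnorm(N, 0, cfg$open_scatter_m)
  x[!in_canopy] <- ox[!in_canopy]
  y[!in_canopy] <- oy[!in_canopy]
  # keep everything strictly inside the paddock
  x <- pmin(pmax(x, 1), cfg$paddock_m[1] - 1)
  y <- pmin(pmax(y, 1), cfg$paddock_m[2] - 1)

  day0 <- as.POSIXct(paste(targets$date, "00:00:00"), tz = tz)
  t_block <- rep(day0, each = nb) + rep(0:143 * 600, times = n_ad)
  lat <- cfg$origin[1] + y * s["lat"]
  lon <- cfg$origin[2] + x * s["lon"]
  blocks <- data.frame(animal_id = rep(targets$animal_id, each = nb),
                       interval_start = t_block, lat = lat, lon = lon,
                       in_canopy_true = in_canopy, is_day = is_day)

  if (cfg$resolution == "hourly") {
    stream <- blocks[c("animal_id", "interval_start", "lat", "lon")]
    names(stream)[2] <- "interval_start"
    stream$n_fixes <- 600L
    return(list(stream = stream, blocks = blocks))
  }

  per <- max(1L, as.integer(round(600 * cfg$gnss_hz)))
  noise_sd <- sqrt(cfg$walk_noise_m^2 + cfg$gps_noise_m^2)
  fix_t <- rep(blocks$interval_start, each = per) +
    rep(round(seq(0, 600 - 600 / per, length.out = per)), times = N)
  fx <- rep(x, each = per) + stats::rnorm(N * per, 0, noise_sd)
  fy <- rep(y, each = per) + stats::rnorm(N * per, 0, noise_sd)
  fx <- pmin(pmax(fx, 0.5), cfg$paddock_m[1] - 0.5)
  fy <- pmin(pmax(fy, 0.5), cfg$paddock_m[2] - 0.5)
  stream <- data.frame(animal_id = rep(blocks$animal_id, each = per),
                       t = fix_t,
                       lat = cfg$origin[1] + fy * s["lat"],
                       lon = cfg$origin[2] + fx * s["lon"])
  list(stream = stream, blocks = blocks)
}

#' Synthetic animal table with behaviour-linked weekly gains
#'
#' Initial weights are drawn around the 259 kg median with 39 kg spread;
#' five Monday weighings per animal (trial start plus four weeks). Weekly
#' gains are a baseline plus small planted coefficients on the week's mean
#' daily grazing hours and mean travelled distance, plus noise, totalling
#' ~25 kg median over the trial.
#'
#' @inheritParams generate_behaviors
#' @param realized Realized daily budgets from [generate_behaviors()].
#' @param distances Optional per animal-date full-day distances (km) used in
#'   the gain model; when `NULL` the distance term is dropped.
#' @return Long-format animal table (see [read_animals()]).
#' @export
generate_animals <- function(cfg, profiles, realized, distances = NULL) {
  wk <- make_week_map(cfg$trial_starts, cfg$n_days)
  grz <- realized
  grz$grazing_total <- grz$grazing_day + grz$grazing_night
  grz <- merge(grz, wk[c("date", "trial_id", "week_index")],
               by = c("date", "trial_id"))
  key <- paste(grz$animal_id, grz$week_index, sep = "\r")
  mean_graz <- tapply(grz$grazing_total, key, mean)
  mean_dist <- NULL
  if (!is.null(distances)) {
    d <- merge(distances, wk[c("date", "week_index")], by = "date")
    mean_dist <- tapply(d$distance, paste(d$animal_id, d$week_index,
                                          sep = "\r"), mean)
  }
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    aid <- profiles$animal_id[i]
    tr <- profiles$trial_id[i]
    start <- as.Date(cfg$trial_starts[[tr]])
    n_weeks <- cfg$n_days %/% 7
    wk_idx <- (match(tr, names(cfg$trial_starts)) - 1L) * n_weeks +
      seq_len(n_weeks)
    mg <- mean_graz[paste(aid, wk_idx, sep = "\r")]
    mg[is.na(mg)] <- cfg$budgets$grazing_total
    gains <- cfg$weekly_gain_base +
      cfg$effects$gain_graze * (mg - cfg$budgets$grazing_total) +
      stats::rnorm(n_weeks, 0, cfg$gain_noise)
    if (!is.null(mean_dist)) {
      md <- mean_dist[paste(aid, wk_idx, sep = "\r")]
      md[is.na(md)] <- 3.2
      gains <- gains + cfg$effects$gain_dist * (md - 3.2)
    }
    weights <- profiles$initial_weight[i] + c(0, cumsum(gains))
    out[[i]] <- data.frame(animal_id = aid, trial_id = tr,
                           initial_weight = profiles$initial_weight[i],
                           bos_indicus = profiles$bos_indicus[i],
                           weigh_date = start + 7 * (0:n_weeks),
                           weight = weights)
  }
  do.call(rbind, out)
}

#' Run the full synthetic generator
#'
#' Seeds the RNG once from the configuration and generates, in a fixed
#' order, the paddock map, weather (with CCI and daily maxima), behaviour,
#' GNSS and animal streams, plus the ground truth needed for planted-effect
#' recovery tests. The result is a pure function of the configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `streams` (elements `behavior`, `gnss`, `weather`,
#'   `canopy`, `animals`), `truth` (planted targets, realized budgets,
#'   per-block occupancy states, effect sizes, daily CCI) and `config`.
#' @export
simulate_trials <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  map <- generate_paddock(cfg)
  weather <- generate_weather(cfg)
  cci <- compute_cci(weather, envelope = "warn")
  dmax <- daily_max_cci(cci, tz = "Etc/GMT-10")
  profiles <- .generate_profiles(cfg)
  beh <- generate_behaviors(cfg, dmax, profiles)
  trk <- generate_tracks(cfg, beh$targets, map)
  # full-day true distances for the gain model (from block positions)
  b <- trk$blocks
  bdate <- format(b$interval_start, "%Y-%m-%d", tz = "Etc/GMT-10")
  dseg <- haversine_km(b$lat[-nrow(b)], b$lon[-nrow(b)],
                       b$lat[-1], b$lon[-1])
  same <- b$animal_id[-nrow(b)] == b$animal_id[-1] &
    bdate[-nrow(b)] == bdate[-1]
  dist_day <- tapply(dseg[same],
                     paste(b$animal_id[-nrow(b)][same],
                           bdate[-nrow(b)][same], sep = "\r"), sum)
  kp <- strsplit(names(dist_day), "\r", fixed = TRUE)
  distances <- data.frame(animal_id = vapply(kp, `[`, "", 1L),
                          date = as.Date(vapply(kp, `[`, "", 2L)),
                          distance = as.numeric(dist_day))
  animals <- generate_animals(cfg, profiles, beh$realized, distances)
  list(streams = list(behavior = beh$stream, gnss = trk$stream,
                      weather = weather, canopy = map, animals = animals),
       truth = list(targets = beh$targets, realized = beh$realized,
                    blocks = trk$blocks, daily_cci = dmax,
                    distances = distances, effects = cfg$effects,
                    profiles = profiles),
       config = cfg)
}

#' Write a synthetic fixture to disk
#'
#' Emits the five input files in the pipeline's dialects plus a ground-truth
#' JSON. Requires `resolution = "full"` (the on-disk dialect is 5-second
#' labels and raw fixes). Identical seeds produce byte-identical files.
#'
#' @param cfg A [sim_config()] with `resolution = "full"`.
#' @param dir Output directory.
#' @param force Overwrite existing files.
#' @return Invisibly, a named vector of the six file paths.
#' @export
write_fixture <- function(cfg, dir, force = FALSE) {
  if (cfg$resolution != "full")
    stop("write_fixture requires resolution = 'full' (on-disk dialects are ",
         "5-second labels and raw fixes)", call. = FALSE)
  sim <- simulate_trials(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(behavior = file.path(dir, "behavior.csv"),
             gnss = file.path(dir, "gnss.csv"),
             weather = file.path(dir, "weather.csv"),
             canopy = file.path(dir, "canopy.geojson"),
             animals = file.path(dir, "animals.csv"),
             truth = file.path(dir, "truth.json"))
  if (!force && any(file.exists(paths)))
    stop("output files exist; use force = TRUE to overwrite", call. = FALSE)
  write_behavior(sim$streams$behavior, paths["behavior"])
  write_gnss(sim$streams$gnss, paths["gnss"])
  write_weather(sim$streams$weather, paths["weather"])
  write_canopy(sim$streams$canopy, paths["canopy"])
  write_animals(sim$streams$animals, paths["animals"])
  truth <- sim$truth
  truth$blocks <- NULL  # block states can be regenerated from the config
  truth$targets$date <- format(truth$targets$date)
  truth$realized$date <- format(truth$realized$date)
  truth$daily_cci$date <- format(truth$daily_cci$date)
  truth$distances$date <- format(truth$distances$date)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  invisible(paths)
}
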