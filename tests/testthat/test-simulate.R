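test_that("generation is deterministic in the seed", {
  a <- simulate_trials(tiny_full_cfg(seed = 5))
  b <- simulate_trials(tiny_full_cfg(seed = 5))
  expect_identical(a$streams$behavior, b$streams$behavior)
  expect_identical(a$streams$gnss, b$streams$gnss)
  expect_identical(a$streams$weather, b$streams$weather)
  expect_identical(a$streams$animals, b$streams$animals)
  c <- simulate_trials(tiny_full_cfg(seed = 6))
  expect_false(identical(a$streams$weather$ta, c$streams$weather$ta))
  expect_identical(names(a$streams), names(c$streams))
})

test_that("the two emission resolutions share identical planted truth", {
  full <- simulate_trials(tiny_full_cfg(seed = 12))
  hourly <- simulate_trials(sim_config(seed = 12, n_animals = 2L,
                                       n_days = 7L, resolution = "hourly"))
  expect_equal(full$truth$realized, hourly$truth$realized)
  expect_equal(full$truth$blocks[c("animal_id", "lat", "lon",
                                   "in_canopy_true")],
               hourly$truth$blocks[c("animal_id", "lat", "lon",
                                     "in_canopy_true")])
  # budgets reconstructed from the 5-s labels equal the realized truth
  hb <- hourly_budget(full$streams$behavior)
  s <- build_daily_summaries(hb)
  f <- s[s$daypart == "day", ]
  r <- full$truth$realized
  key <- paste(f$animal_id, f$date)
  expect_equal(f$grazing,
               r$grazing_day[match(key, paste(r$animal_id, r$date))],
               tolerance = 1e-9)
})

test_that("weather is physically shaped and CCI-calibrated", {
  mins <- maxs <- numeric(0)
  for (seed in 1:5) {
    sim <- default_sim(200 + seed)
    wx <- sim$streams$weather
    hfrac <- as.integer(format(wx$t, "%H", tz = TZ))
    expect_true(all(wx$rad[hfrac < 5] == 0))  # no sun at 02:00
    expect_true(all(wx$rad >= 0 & wx$rh >= 0 & wx$rh <= 100 & wx$ws > 0))
    mins <- c(mins, min(sim$truth$daily_cci$max_cci))
    maxs <- c(maxs, max(sim$truth$daily_cci$max_cci))
  }
  expect_true(all(mins >= 30) && all(maxs <= 60))
})

test_that("tracks stay in the paddock and follow the planted occupancy", {
  sim <- default_sim()
  map <- sim$streams$canopy
  blocks <- sim$truth$blocks
  expect_true(all(thermoherd:::.point_in_ring(blocks$lat, blocks$lon,
                                              map$paddock)))
  # realized daytime canopy frequency tracks the planted logistic: noisy at
  # the animal-day level (78 Bernoulli blocks), tight at the herd-day level
  day <- blocks[blocks$is_day, ]
  tg <- sim$truth$targets
  key <- paste(day$animal_id, as.Date(format(day$interval_start, tz = TZ)))
  freq <- tapply(day$in_canopy_true, key, mean)
  planted <- tg$p_canopy_day[match(names(freq), paste(tg$animal_id, tg$date))]
  expect_lt(mean(abs(freq - planted)), 0.06)  # binomial MC error at n=78
  dkey <- as.Date(format(day$interval_start, tz = TZ))
  herd_freq <- tapply(day$in_canopy_true, dkey, mean)
  herd_planted <- tapply(tg$p_canopy_day, tg$date, mean)
  expect_gt(stats::cor(herd_freq, herd_planted[names(herd_freq)]), 0.95)
  expect_lt(mean(abs(herd_freq - herd_planted[names(herd_freq)])), 0.02)
})

test_that("null configurations plant no effects", {
  null_cfg <- sim_config(seed = 31, n_animals = 20L,
                         effects = list(shade_affinity = 0, graze_shift = 0,
                                        rest_gain = 0, walk_bos_cci = 0,
                                        gain_graze = 0, gain_dist = 0))
  sim <- suppressWarnings(simulate_trials(null_cfg))
  tg <- sim$truth$targets
  # canopy probability is flat and the day/night grazing split is
  # uncorrelated with CCI
  expect_equal(stats::sd(tg$p_canopy_day), 0)
  expect_lt(abs(stats::cor(tg$max_cci, tg$grazing_night)), 0.15)
})

test_that("animal tables match the study's weight and breed structure", {
  sim <- default_sim()
  an <- sim$streams$animals
  first <- an[!duplicated(an$animal_id), ]
  expect_equal(nrow(first), 120L)
  expect_lt(abs(stats::median(first$initial_weight) - 259), 15)
  expect_true(all(first$bos_indicus >= 0.47 & first$bos_indicus <= 0.95))
  # five Monday weigh dates per animal -> four weekly gains
  expect_true(all(table(an$animal_id) == 5L))
  expect_true(all(format(an$weigh_date, "%u") == "1"))
  gains <- weekly_weight_gain(an)
  expect_equal(nrow(gains), 480L)
  expect_false(any(gains$nonweekly))
  # total gain over the four weeks lands near the observed ~25 kg median
  tot <- tapply(gains$gain, gains$animal_id, sum)
  expect_lt(abs(stats::median(tot) - 25), 6)
})

test_that("weekly behaviour medians stay within the observed envelope", {
  spans <- list(grazing = c(6.4, 7.8), ruminating = c(2.2, 3.6),
                resting = c(1.4, 2.6), walking = c(0.6, 0.9),
                drinking = c(0.0, 0.1), time_in_open = c(8.3, 12.2),
                distance = c(2.5, 3.9))
  for (seed in c(101, 202)) {
    wm <- default_analysis(seed)$weekly_medians
    for (v in names(spans)) {
      med <- wm$median[wm$variable == v]
      expect_true(all(med >= spans[[v]][1] - 1e-9 &
                        med <= spans[[v]][2] + 1e-9),
                  label = sprintf("%s medians within Table-2 span (seed %d)",
                                  v, seed))
    }
  }
})

test_that("fixture writing is deterministic and complete", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- tiny_full_cfg(seed = 9)
  p1 <- write_fixture(cfg, dir1)
  p2 <- write_fixture(cfg, dir2)
  expect_length(p1, 6L)
  expect_true(all(file.exists(p1)))
  expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_error(write_fixture(cfg, dir1), "force")
  expect_error(write_fixture(sim_config(seed = 9, resolution = "hourly"),
                             dir1), "resolution")
  # the written fixture reads back through the io layer
  streams <- read_streams(p1[1:5])
  expect_equal(sort(unique(streams$behavior$animal_id)),
               sort(unique(streams$animals$animal_id)))
})
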