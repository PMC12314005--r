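test_that("day ranking is ascending from the coldest with midrank ties", {
  df <- data.frame(date = as.Date("2022-11-21") + 0:2,
                   max_cci = c(40, 36, 52))
  expect_equal(rank_days(df)$rank, c(2, 1, 3))
  tie <- data.frame(date = as.Date("2022-11-21") + 0:1, max_cci = c(40, 40))
  expect_equal(rank_days(tie)$rank, c(1.5, 1.5))
  # permutation invariance of the date -> rank mapping
  set.seed(3)
  df <- data.frame(date = as.Date("2022-11-21") + 0:55,
                   max_cci = stats::runif(56, 36, 52))
  a <- rank_days(df)
  b <- rank_days(df[sample(56), ])
  expect_equal(a$rank[match(b$date, a$date)], b$rank)
  # invariance under strictly monotone transforms of the index
  mono <- df
  mono$max_cci <- exp(mono$max_cci / 10)
  expect_equal(rank_days(mono)$rank, a$rank)
  expect_error(rank_days(df[0, ]), "empty")
})

test_that("weekly average rank equals the brute-force mean of day ranks", {
  wm <- make_week_map(c(trial1 = "2022-11-21", trial2 = "2023-11-20"), 28)
  set.seed(8)
  dmax <- data.frame(date = wm$date, trial_id = wm$trial_id,
                     max_cci = stats::runif(56, 36, 52))
  ranked <- rank_days(dmax)
  weekly <- weekly_average_rank(ranked, wm)
  expect_equal(weekly$n_days, rep(7L, 8))
  br <- brute_rank(dmax$max_cci)
  for (w in 1:8) {
    member <- wm$week_index == w
    expect_equal(weekly$avg_rank[weekly$week_index == w],
                 mean(br[member]))
  }
  # a simple hand case and the degenerate all-equal case
  expect_equal(mean(1:7), 4)
  flat <- dmax; flat$max_cci <- 44
  wflat <- weekly_average_rank(rank_days(flat), wm)
  expect_true(all(wflat$avg_rank == wflat$avg_rank[1]))
})

test_that("week pairing groups ascending pairs and ignores input order", {
  weekly <- data.frame(week_index = 1:8, trial_id = "trial1",
                       avg_rank = c(30, 10, 70, 20, 80, 50, 60, 40))
  g <- pair_weeks(weekly)
  expect_equal(sort(g$week_index[g$group_id == 1]), c(2, 4))  # means 10, 20
  expect_equal(sort(g$week_index[g$group_id == 4]), c(3, 5))  # means 70, 80
  g2 <- pair_weeks(weekly[sample(8), ])
  expect_equal(as.data.frame(g), as.data.frame(g2))
  expect_error(pair_weeks(weekly[1:7, ]), "odd")
})

test_that("group weather summaries equal brute-force daily recomputation", {
  set.seed(21)
  wm <- make_week_map(c(trial1 = "2022-11-21", trial2 = "2023-11-20"), 28)
  t0 <- as.POSIXct("2022-11-21 00:00:00", tz = TZ)
  t1 <- as.POSIXct("2023-11-20 00:00:00", tz = TZ)
  tt <- c(t0 + seq(0, 28 * 86400 - 600, by = 600),
          t1 + seq(0, 28 * 86400 - 600, by = 600))
  wx <- data.frame(t = tt, ta = stats::runif(length(tt), 15, 38),
                   rh = 50, ws = stats::runif(length(tt), 0.3, 4),
                   rad = stats::runif(length(tt), 0, 900),
                   rain = stats::rbinom(length(tt), 1, 0.01) * 2,
                   trial_id = rep(c("trial1", "trial2"), each = 28 * 144))
  dmax <- daily_max_cci(compute_cci(wx), TZ)
  groups <- pair_weeks(weekly_average_rank(rank_days(dmax), wm))
  gs <- group_weather_summary(wx, groups, wm, TZ)
  expect_equal(nrow(gs), 4L)

  # brute force for one group from scratch
  g1_weeks <- groups$week_index[groups$group_id == 1]
  sel <- wm[wm$week_index %in% g1_weeks, ]
  rows <- wx[paste(as.Date(format(wx$t, tz = TZ)), wx$trial_id) %in%
               paste(sel$date, sel$trial_id), ]
  dkey <- paste(as.Date(format(rows$t, tz = TZ)), rows$trial_id)
  expect_equal(gs$temp_max[1], max(tapply(rows$ta, dkey, max)))
  expect_equal(gs$temp_min[1], min(tapply(rows$ta, dkey, min)))
  expect_equal(gs$temp_mean[1], mean(tapply(rows$ta, dkey, mean)))
  expect_equal(gs$rain_total[1], sum(rows$rain))
  expect_equal(gs$wind_mean_kmh[1], mean(tapply(rows$ws, dkey, mean)) * 3.6)
  expect_equal(gs$rad_mean[1], mean(tapply(rows$rad, dkey, mean)))

  # constant weather: max = min = mean
  cwx <- wx; cwx$ta <- 25
  cgs <- group_weather_summary(cwx, groups, wm, TZ)
  expect_equal(cgs$temp_max, cgs$temp_min)
  expect_equal(cgs$temp_max, cgs$temp_mean)
})

test_that("planted week-level ordering is recovered end to end", {
  an <- default_analysis()
  sim <- default_sim()
  truth_rank <- brute_rank(sim$truth$daily_cci$max_cci)
  wk <- an$week_map
  truth_avg <- tapply(truth_rank[match(paste(wk$date, wk$trial_id),
                                       paste(sim$truth$daily_cci$date,
                                             sim$truth$daily_cci$trial_id))],
                      wk$week_index, mean)
  expect_equal(an$weekly_ranks$avg_rank, as.numeric(truth_avg))
  expect_equal(order(an$weekly_ranks$avg_rank),
               an$groups$week_index[order(an$groups$group_id,
                                          an$groups$avg_rank)])
})
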