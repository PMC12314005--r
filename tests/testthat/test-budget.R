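test_that("hourly budgets convert 5-s label counts to hours", {
  h <- as.POSIXct("2022-11-22 06:00:00", tz = TZ)
  hb <- hourly_budget(make_behavior("A1", h, list(grazing = 720)))
  expect_equal(hb$grazing, 1.0)
  expect_equal(hb$coverage, 1.0)

  hb <- hourly_budget(make_behavior("A1", h, list(grazing = 360,
                                                  resting = 360)))
  expect_equal(hb$grazing, 0.5)
  expect_equal(hb$resting, 0.5)
  expect_equal(hb$walking, 0)

  dup <- rbind(make_behavior("A1", h, list(grazing = 2)),
               make_behavior("A1", h, list(resting = 1)))
  expect_error(hourly_budget(dup), "duplicate")
})

test_that("aggregation is order-invariant", {
  h <- as.POSIXct("2022-11-22 06:00:00", tz = TZ)
  set.seed(9)
  beh <- do.call(rbind, lapply(0:5, function(k)
    make_behavior("A1", h + k * 3600,
                  list(grazing = sample(0:300, 1), walking = sample(0:200, 1),
                       ruminating = sample(0:200, 1)))))
  a <- hourly_budget(beh)
  b <- hourly_budget(beh[sample(nrow(beh)), ])
  expect_equal(a, b)
})

test_that("daypart split uses half-open [05:00, 18:00) daytime", {
  day <- as.POSIXct("2022-11-22 00:00:00", tz = TZ)
  tab <- data.frame(hour = day + c(5, 17, 18, 4, 0, 23) * 3600)
  out <- split_daypart(tab)
  expect_equal(out$daypart, c("day", "day", "night", "night", "night",
                              "night"))
  expect_true(all(out$date == as.Date("2022-11-22")))
  # alternative convention: pre-dawn hours belong to the previous date
  alt <- split_daypart(tab, herd_config(night_same_date = FALSE))
  expect_equal(as.character(alt$date),
               c(rep("2022-11-22", 3), "2022-11-21", "2022-11-21",
                 "2022-11-22"))
})

test_that("weighing-day exclusion removes exactly the Mondays, idempotently", {
  dates <- as.Date("2022-11-21") + 0:27  # starts on a Monday: 4 Mondays
  df <- data.frame(date = rep(dates, 2), x = 1)
  out <- exclude_weighing_days(df)
  expect_equal(nrow(out), 2 * 24L)
  expect_false(any(format(out$date, "%u") == "1"))
  expect_equal(exclude_weighing_days(out), out)
  # a table with no Mondays is unchanged
  tu <- df[format(df$date, "%u") == "2", ]
  expect_equal(nrow(exclude_weighing_days(tu)), nrow(tu))
  expect_warning(exclude_weighing_days(df[format(df$date, "%u") == "1", ]),
                 "empty")
})

test_that("daily summaries conserve class hours across dayparts", {
  an <- default_analysis()
  s <- an$summaries
  f <- s[s$daypart == "full", ]
  d <- s[s$daypart == "day", ]
  n <- s[s$daypart == "night", ]
  m <- merge(merge(f, d, by = c("animal_id", "date"),
                   suffixes = c("_full", "_day")),
             n, by = c("animal_id", "date"))
  for (cl in behavior_classes) {
    expect_equal(m[[paste0(cl, "_day")]] + m[[cl]],
                 m[[paste0(cl, "_full")]], tolerance = 1e-12)
  }
  # distance partitions the same way
  mv <- an$movement
  mf <- mv[mv$daypart == "full", ]
  md <- mv[mv$daypart == "day", ]
  mn <- mv[mv$daypart == "night", ]
  expect_equal(mf$distance, md$distance + mn$distance, tolerance = 1e-12)
  # six-class hours never exceed the daypart length
  lens <- c(full = 24, day = 13, night = 11)
  tot <- rowSums(s[behavior_classes])
  expect_true(all(tot <= lens[s$daypart] + 1e-9))
})

test_that("a two-trial default run keeps 24 behavioural days per animal", {
  an <- default_analysis()
  f <- an$summaries[an$summaries$daypart == "full", ]
  expect_equal(nrow(f), 2880L)  # 120 animals x 24 non-Monday days
  expect_equal(unname(table(f$animal_id)[1]), 24L, ignore_attr = TRUE)
  per_trial <- table(an$week_map$trial_id[match(f$date, an$week_map$date)])
  expect_equal(unname(per_trial), c(1440L, 1440L), ignore_attr = TRUE)
  # the date's maximum CCI is attached to all three dayparts alike
  s <- an$summaries
  spread <- tapply(s$max_cci, paste(s$animal_id, s$date),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("weekly medians come with raw MAD and full coverage flags work", {
  an <- default_analysis()
  wm <- an$weekly_medians
  expect_true(all(c("median", "mad", "n") %in% names(wm)))
  g <- wm[wm$variable == "grazing", ]
  expect_equal(nrow(g), 8L)
  # raw MAD, not the 1.4826-scaled version: recompute for one week
  s <- an$summaries
  x <- s$grazing[s$daypart == "full" & s$week_index == 1 & !s$incomplete]
  expect_equal(g$mad[g$week_index == 1],
               stats::median(abs(x - stats::median(x))))
})
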