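test_that("haversine matches closed-form values and is symmetric", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0, tolerance = 1e-9)
  expect_equal(haversine_km(0, 0, 1, 0), 6371.0 * pi / 180, tolerance = 1e-9)
  expect_equal(haversine_km(-27.55, 152.33, -27.42, 152.61),
               haversine_km(-27.42, 152.61, -27.55, 152.33))
  expect_error(haversine_km(95, 0, 0, 0), "out of range")
})

test_that("median positions use per-coordinate medians on the 10-min grid", {
  t0 <- as.POSIXct("2022-11-22 06:00:00", tz = TZ)
  fx <- data.frame(animal_id = "A1", t = t0 + 0:599,
                   lat = -27.55, lon = 152.33)
  mp <- median_positions(fx)
  expect_equal(nrow(mp), 1L)
  expect_equal(mp$lat, -27.55)
  expect_equal(as.numeric(mp$interval_start), as.numeric(t0))

  fx <- data.frame(animal_id = "A1", t = t0 + 0:2, lat = c(1, 2, 100),
                   lon = c(10, 30, 20))
  expect_equal(median_positions(fx)$lat, 2)
  expect_equal(median_positions(fx)$lon, 20)

  fx <- data.frame(animal_id = "A1", t = t0 + 0:3, lat = c(1, 2, 3, 10),
                   lon = 0)
  expect_equal(median_positions(fx)$lat, 2.5)
  expect_equal(median_positions(data.frame(animal_id = character(),
                                           t = t0[0], lat = numeric(),
                                           lon = numeric())) |> nrow(), 0L)
})

test_that("median position resists a single wild outlier", {
  t0 <- as.POSIXct("2022-11-22 06:00:00", tz = TZ)
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    lat <- -27.55 + stats::rnorm(n, 0, 1e-4)
    base <- stats::median(lat)
    lat_out <- c(lat, 50)  # wild outlier
    fx <- data.frame(animal_id = "A", t = t0 + seq_len(n + 1), lat = lat_out,
                     lon = 152.33)
    shifted <- median_positions(fx)$lat
    expect_lte(abs(shifted - base), diff(range(lat)) + 1e-12)
  }
})

test_that("open/canopy classification follows the stated conventions", {
  paddock <- square_ring(-27.55, 152.33, 0.01)
  canopy <- square_ring(-27.55, 152.33, 0.001)
  map <- canopy_map(paddock, list(canopy))
  pts <- data.frame(
    lat = c(-27.55, -27.545, -27.55, canopy[1, 1]),
    lon = c(152.33, 152.33, 152.33 + 0.001, canopy[1, 2]))
  # centroid of canopy; open point well away; point on canopy edge; vertex
  cls <- classify_open(pts, map)
  expect_equal(cls$in_open, c(FALSE, TRUE, FALSE, FALSE))
  expect_false(any(cls$out_of_paddock))
  expect_warning(classify_open(data.frame(lat = 0, lon = 0), map),
                 "outside the paddock")
})

test_that("ray casting agrees with a winding-number oracle on random points", {
  set.seed(11)
  for (trial in 1:10) {
    poly <- random_simple_polygon(centre = stats::runif(2, -1, 1),
                                  n = sample(5:11, 1))
    lat <- stats::runif(100, -2, 2)
    lon <- stats::runif(100, -2, 2)
    ours <- thermoherd:::.point_in_ring(lat, lon, poly)
    oracle <- mapply(winding_inside, lat, lon, MoreArgs = list(ring = poly))
    expect_equal(ours, unname(oracle))
  }
})

test_that("movement summaries: open time, distances, partition, exclusion", {
  t0 <- as.POSIXct("2022-11-22 08:00:00", tz = TZ)
  # 12 consecutive daytime intervals, 9 in the open -> 1.5 h
  pos <- data.frame(animal_id = "A1", interval_start = t0 + 600 * (0:11),
                    lat = -27.55, lon = 152.33,
                    in_open = rep(c(TRUE, FALSE), c(9, 3)))
  ms <- movement_summary(pos)
  expect_equal(ms$time_in_open[ms$daypart == "day"], 1.5)
  expect_equal(ms$time_under_canopy[ms$daypart == "day"], 0.5)
  # stationary animal: zero distance, not excluded
  expect_equal(ms$distance[ms$daypart == "full"], 0)
  expect_false(any(ms$excluded))

  # zig-zag of 30 segments of 100 m -> 3.0 km by closed form
  step_deg <- 0.1 / (6371.0 * pi / 180)  # 100 m of meridian arc
  lat <- -27.55 + cumsum(c(0, rep(c(step_deg, -step_deg), 15)))
  pos <- data.frame(animal_id = "A1",
                    interval_start = t0 + 600 * (0:30),
                    lat = lat, lon = 152.33, in_open = TRUE)
  ms <- movement_summary(pos)
  expect_equal(ms$distance[ms$daypart == "full"], 3.0, tolerance = 1e-9)

  # full = day + night exactly on gap-free tracks spanning the boundary
  t0 <- as.POSIXct("2022-11-22 00:00:00", tz = TZ)
  set.seed(5)
  pos <- data.frame(animal_id = "A1", interval_start = t0 + 600 * (0:143),
                    lat = -27.55 + cumsum(stats::rnorm(144, 0, 1e-5)),
                    lon = 152.33 + cumsum(stats::rnorm(144, 0, 1e-5)),
                    in_open = TRUE)
  ms <- movement_summary(pos)
  expect_equal(ms$distance[ms$daypart == "full"],
               ms$distance[ms$daypart == "day"] +
                 ms$distance[ms$daypart == "night"])
  # partition of daytime intervals into open + canopy
  expect_equal(ms$time_in_open[ms$daypart == "day"] +
                 ms$time_under_canopy[ms$daypart == "day"],
               ms$n_intervals[ms$daypart == "day"] / 6)

  # implausible daily distance is flagged
  far <- data.frame(animal_id = "A1", interval_start = t0 + 600 * (0:20),
                    lat = -27.55 + 0.005 * (0:20 %% 2), lon = 152.33,
                    in_open = TRUE)  # ~556 m per segment, > 10 km total
  ms <- movement_summary(far)
  expect_true(all(ms$excluded))

  # no segment across a gap longer than the configured limit
  gap <- data.frame(animal_id = "A1",
                    interval_start = t0 + c(0, 600, 8000, 8600),
                    lat = c(0, 0.001, 0.5, 0.501), lon = 0, in_open = TRUE)
  ms <- movement_summary(gap)
  expect_equal(ms$distance[ms$daypart == "full"],
               haversine_km(0, 0, 0.001, 0) + haversine_km(0.5, 0, 0.501, 0))
})
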