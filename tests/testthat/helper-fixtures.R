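# Shared fixtures and independent oracles for the test suite.

TZ <- "Etc/GMT-10"

# One default-condition simulation + analysis, generated once and reused by
# several test files (trial scale: 2 x 28 days x 60 animals, hourly route).
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function(seed = 101L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- suppressWarnings(simulate_trials(sim_config(seed = seed)))
  .fixture_env[[key]]
}

default_analysis <- function(seed = 101L) {
  key <- paste0("an", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- suppressWarnings(
      herd_analysis(default_sim(seed)$streams))
  .fixture_env[[key]]
}

# a small config that exercises the full-resolution emission path:
# 2 animals, two 7-day windows, 0.1 Hz fixes
tiny_full_cfg <- function(seed = 7L, ...) {
  sim_config(seed = seed, n_animals = 2L, n_days = 7L,
             resolution = "full", gnss_hz = 0.1, ...)
}

# build a behaviour record stream from per-hour class counts
make_behavior <- function(animal_id, hour_start, counts) {
  labs <- rep(names(counts), unlist(counts))
  data.frame(animal_id = animal_id,
             t = hour_start + 5 * (seq_along(labs) - 1),
             label = factor(labs, levels = behavior_classes))
}

# axis-aligned square ring (lat, lon) centred at (clat, clon), half-side h deg
square_ring <- function(clat, clon, h) {
  cbind(lat = clat + c(-h, -h, h, h), lon = clon + c(-h, h, h, -h))
}

# independent point-in-polygon oracle: winding number by signed-angle sum
winding_inside <- function(lat, lon, ring) {
  n <- nrow(ring)
  total <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1
    a1 <- ring[i, 1] - lat; a2 <- ring[i, 2] - lon
    b1 <- ring[j, 1] - lat; b2 <- ring[j, 2] - lon
    total <- total + atan2(a1 * b2 - a2 * b1, a1 * b1 + a2 * b2)
  }
  abs(total) > pi
}

# random star-shaped (hence simple) polygon around a centre
random_simple_polygon <- function(centre = c(0, 0), n = 7, rmin = 0.2,
                                  rmax = 1) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(lat = centre[1] + r * sin(ang), lon = centre[2] + r * cos(ang))
}

# brute-force rank from the definition (midrank for ties)
brute_rank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# definitional product-moment correlation
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
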