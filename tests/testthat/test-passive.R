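# Deterministic ping-trace builder: blocks of pings at fixed coordinates
# with a constant inter-ping gap.
trace <- function(coords, counts, gap_min = 60, start = "2022-01-01 00:00:00") {
  lat <- rep(coords[, 1], counts)
  lon <- rep(coords[, 2], counts)
  n <- length(lat)
  tibble::tibble(
    patient_id = "P01",
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * gap_min * 60,
    latitude = lat,
    longitude = lon
  )
}

test_that("a single dwell spot is the home location", {
  gps <- trace(matrix(c(12.97, 77.59), 1), 10)
  locs <- find_significant_locations(gps)
  expect_equal(nrow(locs$locations), 1)
  expect_equal(locs$home_id, "loc1")
  expect_equal(locs$locations$latitude, 12.97, tolerance = 1e-9)
  expect_error(find_significant_locations(gps[0, ]), "empty")
})

test_that("two clouds 5 km apart split 70/30 give home at the heavier cloud", {
  skip_if_not_installed("geosphere")
  c1 <- c(12.9700, 77.5900)
  c2 <- c(13.0150, 77.5900)  # ~5 km north
  jitter <- withr::with_seed(8, matrix(rnorm(100 * 2, 0, 3e-4), ncol = 2))
  pts <- rbind(
    matrix(c1, 70, 2, byrow = TRUE),
    matrix(c2, 30, 2, byrow = TRUE)
  ) + jitter
  gps <- trace(pts, rep(1, 100))
  locs <- find_significant_locations(gps, seed = 2)
  expect_equal(nrow(locs$locations), 2)
  home <- locs$locations[locs$locations$id == locs$home_id, ]
  # centroid oracle: the per-cloud mean, distance checked with haversine
  cloud1_mean <- colMeans(pts[1:70, ])
  d <- geosphere::distHaversine(c(home$longitude, home$latitude),
                                c(cloud1_mean[2], cloud1_mean[1]))
  expect_lt(d, 50)
  expect_gt(home$dwell_minutes / sum(locs$locations$dwell_minutes), 0.6)
})

test_that("equal-dwell ties are broken by earliest first visit", {
  coords <- rbind(c(12.97, 77.59), c(13.01, 77.59), c(12.93, 77.59))
  gps <- trace(coords, c(20, 20, 20))
  locs <- find_significant_locations(gps, seed = 1)
  expect_equal(nrow(locs$locations), 3)
  home <- locs$locations[locs$locations$id == locs$home_id, ]
  expect_equal(home$latitude, 12.97, tolerance = 1e-6)  # first-visited cloud
})

test_that("daily summaries compute dwell-weighted fractions per local day", {
  # 10 equally spaced pings in one day, 7 at home, 3 elsewhere
  coords <- rbind(c(12.97, 77.59), c(13.01, 77.59))
  gps <- trace(coords[c(1, 1, 1, 1, 1, 1, 1, 2, 2, 2), ], rep(1, 10),
               gap_min = 60)
  locs <- find_significant_locations(gps, seed = 1)
  ds <- daily_summaries(gps, locs)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$home_time_pct, 70)
  expect_equal(ds$ping_count, 10L)

  # all pings at home
  gps_home <- trace(coords[1, , drop = FALSE], 10)
  locs_home <- find_significant_locations(gps_home)
  ds_home <- daily_summaries(gps_home, locs_home)
  expect_equal(ds_home$home_time_pct, 100)
  expect_equal(ds_home$frac_loc1, 1)

  # 50/50 split between two locations with equal gaps
  gps_half <- trace(coords[c(1, 2, 1, 2, 1, 2, 1, 2), ], rep(1, 8))
  locs_half <- find_significant_locations(gps_half, seed = 1)
  ds_half <- daily_summaries(gps_half, locs_half)
  fr <- unlist(ds_half[grep("frac_loc", names(ds_half))])
  expect_equal(unname(sort(fr)), c(0.5, 0.5))
})

test_that("fractions sum to one on ping days and blank days are preserved", {
  cfg <- synth_config(n_patients = 1, span_days = 20, seed = 2)
  p <- generate_patient(cfg, 1)
  locs <- find_significant_locations(p$gps, seed = 3)
  ds <- daily_summaries(p$gps, locs)
  frac_cols <- grep("^frac_", names(ds), value = TRUE)
  sums <- rowSums(ds[ds$ping_count > 0, frac_cols])
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(ds$home_time_pct >= 0 & ds$home_time_pct <= 100, na.rm = TRUE))

  # a day without pings is emitted blank inside an explicit span
  ds2 <- daily_summaries(p$gps, locs,
                         span = c(min(ds$date) - 1, max(ds$date)))
  expect_equal(ds2$ping_count[1], 0L)
  expect_true(is.na(ds2$home_time_pct[1]))
  expect_true(all(is.na(unlist(ds2[1, frac_cols]))))
})

test_that("uniformly doubling the ping rate leaves dwell fractions unchanged", {
  coords <- rbind(c(12.97, 77.59), c(13.01, 77.59))
  pattern <- c(1, 1, 2, 1, 2, 2, 1, 1)
  gps1 <- trace(coords[pattern, ], rep(1, 8), gap_min = 40)
  gps2 <- trace(coords[rep(pattern, each = 2), ], rep(1, 16), gap_min = 20)
  locs <- find_significant_locations(gps1, seed = 1)
  f1 <- daily_summaries(gps1, locs)
  f2 <- daily_summaries(gps2, locs)
  cols <- grep("^frac_loc", names(f1), value = TRUE)
  expect_equal(unlist(f2[1, cols]), unlist(f1[1, cols]), tolerance = 1e-9)
})

test_that("raised pre-relapse home-ping probability raises measured home time", {
  hits <- vapply(1:12, function(s) {
    cfg <- synth_config(n_patients = 1, span_days = 120,
                        relapse_spec = list(100L), seed = s)
    p <- generate_patient(cfg, 1)
    locs <- find_significant_locations(p$gps, seed = s)
    ds <- daily_summaries(p$gps, locs)
    rel <- ds$date >= p$relapse_dates - 30 & ds$date < p$relapse_dates
    ctrl <- ds$date < p$relapse_dates - 30
    mean(ds$home_time_pct[rel], na.rm = TRUE) >
      mean(ds$home_time_pct[ctrl], na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(hits), 11)
})
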