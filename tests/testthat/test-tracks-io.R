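test_that("argos tables parse, group by animal and time-sort", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,timestamp,lon,lat,location_class,semi_major,semi_minor,orientation",
    "w1,2019-02-01T00:00:00,-73.5,-43.0,3,100,50,10",
    "w1,2019-02-01T02:00:00,-73.6,-43.1,2,200,80,20",
    "w1,2019-02-01T01:00:00,-73.55,-43.05,1,150,60,15"), path)
  tr <- read_argos_table(path)
  expect_length(tr, 1)
  expect_equal(nrow(tr$w1$data), 3)
  expect_true(all(diff(tr$w1$data$timestamp) > 0))

  # interleaved animals -> two tracks, each internally sorted
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,timestamp,lon,lat,location_class",
    "a,2019-02-01T04:00:00,-73.5,-43.0,3",
    "b,2019-02-01T00:00:00,-73.0,-42.0,B",
    "a,2019-02-01T00:00:00,-73.5,-43.1,3",
    "b,2019-02-01T02:00:00,-73.1,-42.1,A"), path2)
  tr2 <- read_argos_table(path2)
  expect_setequal(names(tr2), c("a", "b"))
  expect_true(all(vapply(tr2, function(t) all(diff(t$data$timestamp) > 0),
                         logical(1))))
})

test_that("malformed argos tables are rejected with useful errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,lon,lat,location_class",
               "w1,2019-02-01T00:00:00,-73.5,95,3",
               "w1,2019-02-01T01:00:00,-73.5,-43,3"), path)
  expect_error(read_argos_table(path), "out of range")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,lon,lat", "w1,2019-02-01,1,2"), path2)
  expect_error(read_argos_table(path2), "location_class")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,lon,lat,location_class",
               "w1,2019-02-01T00:00:00,-73.5,-43,3",
               "w1,not-a-time,-73.5,-43,3"), path3)
  expect_error(read_argos_table(path3), "timestamp at line 3")

  # duplicate timestamps: first kept, with a message
  expect_message(
    tr <- make_track(c(-73.5, -73.5, -73.6), c(-43, -43.2, -43.1),
                     hours = c(0, 0, 1)),
    "duplicate")
  expect_equal(nrow(tr$data), 2)
  expect_equal(tr$data$lat[1], -43)
})

test_that("ellipse imputation fills per-class donor means and only gaps", {
  donor <- make_track(c(-73.5, -73.6), c(-43, -43.1), c(0, 1),
                      lc = c("3", "3"), sm = c(100, 300), sn = c(50, 150),
                      or = c(10, 30), id = "don")
  rec <- argos_track("rec", data.frame(
    timestamp = as.POSIXct("2019-03-01", tz = "UTC") + c(0, 3600, 7200),
    lon = c(-73, -73, -73), lat = c(-42, -42.1, -42.2),
    location_class = c("3", "3", "3"),
    semi_major = c(NA, 999, NA), semi_minor = c(NA, 111, NA),
    orientation = c(NA, 5, NA)))
  out <- impute_ellipses_by_class(list(rec), list(donor))[[1]]
  expect_equal(out$data$semi_major, c(200, 999, 200))
  expect_equal(out$data$semi_minor, c(100, 111, 100))
  expect_equal(out$data$orientation, c(20, 5, 20))
  expect_equal(nrow(out$data), 3)  # count and order preserved

  rec_b <- argos_track("recB", data.frame(
    timestamp = as.POSIXct("2019-03-01", tz = "UTC") + c(0, 3600),
    lon = c(-73, -73), lat = c(-42, -42.1), location_class = c("B", "B")))
  expect_error(impute_ellipses_by_class(list(rec_b), list(donor)), "B")
})

test_that("speed filter keeps slow tracks and removes spikes", {
  # two points, 1 km apart, 1 h apart: 0.28 m/s, both kept
  slow <- make_track(c(-73.5, -73.5), c(-43, -43 + 1 / 111.2), c(0, 1))
  expect_equal(nrow(speed_filter(slow)$data), 2)

  # middle point displaced so both adjacent legs exceed 3 m/s
  spike <- make_track(c(-73.5, -73.2, -73.5), c(-43, -43, -43.01),
                      c(0, 1, 2))
  filt <- speed_filter(spike)
  expect_equal(nrow(filt$data), 2)
  expect_equal(filt$data$lon, c(-73.5, -73.5))

  # stationary track unchanged
  still <- make_track(rep(-73.5, 4), rep(-43, 4), 0:3)
  expect_equal(nrow(speed_filter(still)$data), 4)

  # irreparable 2-point sprint
  sprint <- make_track(c(-73.5, -72.5), c(-43, -43), c(0, 0.5))
  expect_error(speed_filter(sprint), "terminal")
})

test_that("speed filter is idempotent and output obeys vmax", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    tr <- make_track(-73.5 + cumsum(rnorm(n, 0, 0.03)),
                     -43 + cumsum(rnorm(n, 0, 0.03)),
                     cumsum(c(0, runif(n - 1, 0.5, 2))))
    f1 <- speed_filter(tr)
    sp <- ctcrwrisk:::implied_speeds(f1$data)
    expect_true(all(sp <= 3.0))
    f2 <- speed_filter(f1)
    expect_identical(f1$data, f2$data)
  }
})

test_that("projection matches geodesic distances and inverts exactly", {
  # 0.1 degrees of latitude is about 11.1 km
  tr <- make_track(c(-73.5, -73.5), c(-43, -42.9), c(0, 1))
  tr <- project_track(tr)
  dy <- abs(diff(tr$xy[, 2]))
  expect_equal(dy, 11.1, tolerance = 0.01)
  geo <- geosphere::distGeo(c(-73.5, -43), c(-73.5, -42.9)) / 1000
  expect_equal(dy, geo, tolerance = 0.01)

  # centre maps to the origin
  trc <- project_track(tr, center = c(-73.5, -43))
  expect_equal(unname(trc$xy[1, ]), c(0, 0), tolerance = 1e-12)

  # round trip: better than 1 m within 500 km of the centre
  set.seed(1)
  lon <- -73.5 + runif(50, -4, 4)
  lat <- -43 + runif(50, -4, 4)
  xy <- ctcrwrisk:::aeqd_forward(lon, lat, -73.5, -43)
  ll <- ctcrwrisk:::aeqd_inverse(xy[, 1], xy[, 2], -73.5, -43)
  expect_lt(max(abs(ll[, 1] - lon)), 1e-9)
  expect_lt(max(abs(ll[, 2] - lat)), 1e-9)

  # distant tracks warn about planar distortion
  far <- make_track(c(-73.5, -60), c(-43, -35), c(0, 100))
  expect_warning(project_track(far, center = c(-73.5, -43)), "1000 km")
})

test_that("vessel tables read, validate fleets, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vessel_id,fleet,timestamp,lon,lat",
               "v1,aquaculture,2020-01-01T00:00:00,-73.5,-43.0",
               "v1,aquaculture,2020-01-01T01:00:00,-73.6,-43.0",
               "v2,aquaculture,2020-01-01T00:30:00,-73.4,-42.9",
               "v2,aquaculture,2020-01-01T01:30:00,-73.3,-42.8"), path)
  rec <- read_vessel_table(path)
  expect_equal(nrow(rec), 4)
  expect_setequal(unique(rec$vessel_id), c("v1", "v2"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vessel_id,fleet,timestamp,lon,lat",
               "v1,navy,2020-01-01T00:00:00,-73.5,-43.0"), bad)
  expect_error(read_vessel_table(bad), "navy")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("vessel_id,fleet,timestamp,lon,lat", empty)
  expect_warning(out <- read_vessel_table(empty), "no records")
  expect_equal(nrow(out), 0)

  # generator output round-trips through the reader
  rec2 <- simulate_vessels(sim_config(seed = 3, n_vessels = 2,
                                      vessel_days = 1))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_vessel_table(rec2, p2)
  back <- read_vessel_table(p2)
  expect_equal(nrow(back), nrow(rec2))
  expect_equal(back$lon, rec2$lon[order(rec2$vessel_id, rec2$timestamp)],
               tolerance = 1e-6)
})

test_that("truncation keeps relocations at or before the cut-off", {
  tr <- make_track(seq(-73.5, -73.1, length.out = 5), rep(-43, 5), 0:4)
  cut <- tr$data$timestamp[3]
  expect_equal(nrow(truncate_after(tr, cut)$data), 3)
  expect_error(truncate_after(tr, tr$data$timestamp[1] - 10),
               "fewer than 2")
})

test_that("argos writer round-trips generator output", {
  cfg <- sim_config(seed = 9, n_locations = 40)
  sim <- suppressWarnings(simulate_track(cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_argos_table(sim$track, path)
  back <- read_argos_table(path)[[1]]
  expect_equal(nrow(back$data), 40)
  expect_equal(back$data$semi_major, sim$track$data$semi_major)
  expect_equal(back$data$lat, sim$track$data$lat, tolerance = 1e-6)
})
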