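# Telemetry ingestion, segments, interval statistics, projection.

test_that("tracks are validated, deduplicated and time-ordered", {
  # interleaved rows of two individuals, one duplicated timestamp
  df <- rbind(
    make_fixes("B", c(2, 0, 1), c(30, 10, 20), 0),
    make_fixes("A", c(1, 0, 1), c(200, 100, 999), 0))
  tr <- as_tracks(df)
  a <- track_of(tr, "A")
  expect_equal(nrow(a), 2)                       # duplicate collapsed
  expect_equal(a$x, c(100, 200))                 # first occurrence kept
  b <- track_of(tr, "B")
  expect_equal(b$x, c(10, 20, 30))               # manual sort oracle
  expect_true(all(diff(as.numeric(a$t)) > 0))
  expect_true(all(diff(as.numeric(b$t)) > 0))
})

test_that("schema and row-level errors are reported", {
  expect_error(as_tracks(data.frame(id = "A", x = 1, y = 1)), "missing required")
  bad <- data.frame(id = c("A", "A", "A"), t = c("2020-01-01", "nonsense", "2020-01-03"),
                    x = 1:3, y = 1:3)
  expect_error(as_tracks(bad), "row")
  expect_warning(
    tr <- as_tracks(rbind(make_fixes("A", 0:2, 0:2, 0), make_fixes("C", 0, 0, 0))),
    "fewer than 2|< 2")
  expect_equal(track_ids(tr), "A")
})

test_that("segments carry duration, distance, speed and compass heading", {
  tr <- as_tracks(make_fixes("A", 0:2, c(0, 0, 1000), c(0, 1000, 1000)))
  sg <- build_segments(tr)
  expect_equal(nrow(sg), 2)
  expect_equal(sg$dt_h, c(1, 1))
  expect_equal(sg$dist_m, c(1000, 1000))
  expect_equal(sg$speed_mh, c(1000, 1000))
  expect_equal(sg$heading_deg, c(0, 90))         # due north, due east
  # zero displacement: speed 0, heading flagged
  tr0 <- as_tracks(make_fixes("A", 0:1, c(5, 5), c(7, 7)))
  sg0 <- build_segments(tr0)
  expect_equal(sg0$speed_mh, 0)
  expect_false(sg0$heading_defined)
  expect_true(is.na(sg0$heading_deg))
})

test_that("segment count and telescoping time sum hold per individual", {
  set.seed(42)
  h <- cumsum(runif(10, 0.5, 3))
  tr <- as_tracks(make_fixes("A", h, cumsum(rnorm(10, 0, 400)), cumsum(rnorm(10, 0, 400))))
  sg <- build_segments(tr)
  expect_equal(nrow(sg), 9)
  expect_equal(sum(sg$dt_h), h[10] - h[1])
})

test_that("interval statistics use the population SD in hours", {
  tr <- as_tracks(make_fixes("A", c(0, 1, 2, 3, 10), rep(0, 5), 0:4))
  st <- interval_stats(tr)
  expect_equal(st$mean_dt_h, 2.5)
  expect_equal(st$sd_dt_h, sqrt(mean((c(1, 1, 1, 7) - 2.5)^2)), tolerance = 1e-12)
  # constant sampling
  st2 <- interval_stats(as_tracks(make_fixes("A", 0:3, 0:3, 0)))
  expect_equal(st2$mean_dt_h, 1)
  expect_equal(st2$sd_dt_h, 0)
})

test_that("round trip through the canonical CSV preserves fixes", {
  df <- data.frame(id = "A",
                   t = hours(0:3),
                   lon = 99.1 + (0:3) * 0.002, lat = 15.4 + (0:3) * 0.001)
  tr <- as_tracks(df)
  p <- tempfile(fileext = ".csv")
  write_tracks(tr, p)
  tr2 <- read_tracks(p)
  expect_equal(as.numeric(tr2$fixes$t), as.numeric(tr$fixes$t))
  expect_equal(tr2$fixes$x, tr$fixes$x, tolerance = 1e-6)
  expect_equal(tr2$fixes$y, tr$fixes$y, tolerance = 1e-6)
})

test_that("UTM projection is locally isometric against a geodesic oracle", {
  skip_if_not_installed("geosphere")
  set.seed(7)
  lon0 <- 99.2; lat0 <- 15.5
  for (k in 1:20) {
    dlon <- runif(1, -0.008, 0.008); dlat <- runif(1, -0.008, 0.008)
    prj <- project_utm(c(lon0, lon0 + dlon), c(lat0, lat0 + dlat))
    planar <- sqrt(diff(prj$x)^2 + diff(prj$y)^2)
    geo <- geosphere::distGeo(c(lon0, lat0), c(lon0 + dlon, lat0 + dlat))
    if (geo > 1) expect_lt(abs(planar - geo) / geo, 0.001)
  }
})
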