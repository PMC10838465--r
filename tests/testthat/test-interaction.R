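# Candidate filtering, ellipse intersection, lag classification,
# segment tracing and monthly summaries.

test_that("candidate filter is a superset of the brute-force intersecting set", {
  set.seed(21)
  pa <- random_ppas(60); pb <- random_ppas(60)
  cand <- candidate_pairs(pa, pb, max_lag_h = Inf)
  brute <- list()
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
    if (ellipse_intersects(pa[i, ], pb[j, ])$intersects)
      brute[[length(brute) + 1]] <- c(i, j)
  brute <- do.call(rbind, brute)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(brute) %in% key(as.matrix(cand[, c("i", "j")]))))
  # disabled filters return the full cross product
  pa2 <- pa; pa2$a <- 1e12
  expect_equal(nrow(candidate_pairs(pa2, pb, Inf)), 60 * 60)
})

test_that("temporal filter excludes disjoint tracking periods", {
  pa <- random_ppas(10)
  pb <- random_ppas(10)
  pb$t_start <- pb$t_start + 365 * 24 * 3600
  pb$t_end <- pb$t_end + 365 * 24 * 3600
  expect_equal(nrow(candidate_pairs(pa, pb, max_lag_h = 0)), 0)
})

test_that("ellipse intersection matches identity and separation bounds", {
  e <- build_ppa(0, 0, 2000, 0, 1, 4000)
  r <- ellipse_intersects(e, e)
  expect_true(r$intersects)
  expect_equal(r$area, pi * e$a * e$b, tolerance = 1e-3)
  far <- build_ppa(50000, 50000, 52000, 50000, 1, 4000)
  rf <- ellipse_intersects(e, far)
  expect_false(rf$intersects)
  expect_equal(rf$area, 0)
})

test_that("intersection decision and area agree with a Monte-Carlo oracle", {
  set.seed(33)
  pa <- random_ppas(12, box = 4000)
  pb <- random_ppas(12, box = 4000)
  for (k in 1:12) {
    e1 <- pa[k, ]; e2 <- pb[k, ]
    got <- ellipse_intersects(e1, e2)
    mc <- mc_overlap(e1, e2, n = 1e5)
    small <- min(pi * e1$a * e1$b, pi * e2$a * e2$b)
    if (mc$area > 0.001 * small || got$area > 0.001 * small) {
      expect_equal(got$intersects, mc$frac > 0)
      # MC standard error + discretization slack
      se <- sqrt(mc$frac * (1 - mc$frac) / 1e5) * pi * e1$a * e1$b
      expect_lt(abs(got$area - mc$area), 4 * se + 0.003 * small)
    }
  }
})

test_that("lag classification follows the closed threshold and bin rules", {
  cls <- classify_lag(c(0.5, 1, 1.5, 30, 180, 400), concurrent_threshold_h = 1,
                      lag_bins_h = c(24, 168))
  expect_equal(cls$kind, c("concurrent", "concurrent", "delayed", "delayed",
                           "delayed", "delayed"))
  expect_equal(cls$bin_h, c(NA, NA, NA, 24, 168, 168))
  # exact bin boundary is assigned to that bin (closed lower bound)
  expect_equal(classify_lag(24, 1, c(24, 168))$bin_h, 24)
  expect_error(classify_lag(1, -1), ">= 0")
})

test_that("segment tracing follows the continuity rule and exact duration", {
  mk_ev <- function(sa, ea, sb, eb) {
    data.frame(id_a = "A", id_b = "B", i = 1, j = 1,
               t_start_a = hours(sa), t_end_a = hours(ea),
               t_start_b = hours(sb), t_end_b = hours(eb),
               lag_h = abs(sa - sb), kind = "concurrent", bin_h = NA_real_,
               who_first = "a", area_m2 = 1,
               heading_a = 0, heading_b = 0, speed_a = 1, speed_b = 1,
               stringsAsFactors = FALSE)
  }
  # single event spanning 09:00-10:00
  one <- mk_ev(9, 10, 9, 10)
  s1 <- trace_segments(one, 1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$duration_h, 1)
  # three chained events covering 09:00-12:00 (interval-union oracle)
  three <- rbind(mk_ev(9, 10, 9, 10), mk_ev(10, 11, 10, 11), mk_ev(11, 12, 11, 12))
  s3 <- trace_segments(three, 1)
  expect_equal(nrow(s3), 1)
  expect_equal(s3$duration_h, 3)
  expect_equal(s3$n_events, 3)
  # a 5-hour hole breaks continuity
  broken <- rbind(mk_ev(9, 10, 9, 10), mk_ev(15, 16, 15, 16))
  sb <- trace_segments(broken, 1)
  expect_equal(nrow(sb), 2)
  expect_equal(sb$duration_h, c(1, 1))
  # empty input
  expect_equal(nrow(trace_segments(one[0, ], 1)), 0)
})

test_that("monthly summary splits durations at month boundaries exactly", {
  seg <- data.frame(segment = 1L,
                    t_min = as.POSIXct("2020-05-31 23:00:00", tz = "UTC"),
                    t_max = as.POSIXct("2020-06-01 02:00:00", tz = "UTC"),
                    duration_h = 3, n_events = 3L)
  class(seg) <- c("interaction_segments", "data.frame")
  ev0 <- structure(data.frame(kind = character(0), bin_h = numeric(0),
                              t_start_a = hours(numeric(0)), t_start_b = hours(numeric(0))),
                   class = c("interaction_events", "data.frame"))
  m <- monthly_summary(seg, ev0)
  expect_equal(m$concurrent$month, c("2020-05", "2020-06"))
  expect_equal(m$concurrent$duration_h, c(1, 2))
  expect_equal(m$concurrent$frequency, c(1, 0))   # counted where it starts
  expect_equal(sum(m$concurrent$duration_h), sum(seg$duration_h))
  # empty inputs give an all-empty table
  m0 <- monthly_summary(seg[0, ], ev0)
  expect_equal(nrow(m0$concurrent), 0)
  expect_equal(nrow(m0$delayed), 0)
})

test_that("total concurrent duration is invariant to month binning", {
  set.seed(14)
  sim <- simulate_dyad("co_movement", days = 40, seed = 14)
  fit <- ortega(sim$tracks)
  d <- fit$dyads[[1]]
  expect_equal(sum(d$monthly$concurrent$duration_h), sum(d$segments$duration_h),
               tolerance = 1e-9)
})

test_that("dyad analysis is symmetric in A and B", {
  set.seed(4)
  sim <- simulate_dyad("co_movement", days = 4, jitter_m = 200, seed = 4)
  pp <- build_ppas(build_segments(sim$tracks))
  pa <- pp[pp$id == "A", ]; pb <- pp[pp$id == "B", ]
  class(pa) <- class(pb) <- c("ppa_set", "data.frame")
  ev_ab <- interaction_events(pa, pb)
  ev_ba <- interaction_events(pb, pa)
  expect_equal(nrow(ev_ab), nrow(ev_ba))
  expect_equal(sort(ev_ab$lag_h), sort(ev_ba$lag_h))
  s_ab <- trace_segments(ev_ab, 1); s_ba <- trace_segments(ev_ba, 1)
  expect_equal(s_ab$duration_h, s_ba$duration_h)
})
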