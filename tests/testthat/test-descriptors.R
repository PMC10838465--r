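# Movement-difference descriptors, KDE profiles and pattern signatures.

mk_events <- function(h1, h2, s1, s2, kind = "concurrent", lag = 0.5) {
  n <- length(h1)
  data.frame(id_a = "A", id_b = "B", i = seq_len(n), j = seq_len(n),
             t_start_a = hours(seq_len(n)), t_end_a = hours(seq_len(n) + 1),
             t_start_b = hours(seq_len(n)), t_end_b = hours(seq_len(n) + 1),
             lag_h = lag, kind = kind, bin_h = NA_real_, who_first = "a",
             area_m2 = 1, heading_a = h1, heading_b = h2,
             speed_a = s1, speed_b = s2, stringsAsFactors = FALSE)
}

test_that("heading difference is circular and symmetric; flagged events excluded", {
  ev <- mk_events(c(10, 0, 90, NA), c(350, 0, 270, 45), c(5, 3, 2, 2), c(1, 3, 9, 2))
  d <- describe_events(ev)
  expect_equal(d$d_heading, c(20, 0, 180))       # wraparound, equal, head-on
  expect_equal(d$d_speed, c(4, 0, 7))
  expect_equal(attr(d, "n_excluded"), 1)
  # symmetry in the two animals
  ev_sw <- mk_events(c(350, 0, 270), c(10, 0, 90), c(1, 3, 9), c(5, 3, 2))
  expect_equal(describe_events(ev_sw)$d_heading, c(20, 0, 180))
  # invariant to global rotation of both tracks
  rot <- (c(10, 0, 90) + 33) %% 360
  rot2 <- (c(350, 0, 270) + 33) %% 360
  expect_equal(describe_events(mk_events(rot, rot2, 1:3, 1:3))$d_heading,
               c(20, 0, 180))
})

test_that("KDE profile integrates to one and flattens for uniform input", {
  set.seed(2)
  v <- runif(4000, 0, 180)
  k <- kde_profile(v, "direction")
  expect_equal(k$n, 4000)
  integral <- sum(k$density) * diff(k$grid[1:2])
  expect_equal(integral, 1, tolerance = 0.05)
  # roughly flat in the interior (KDE bias near the edges excluded)
  mid <- k$density[k$grid > 30 & k$grid < 150]
  expect_lt(max(mid) / min(mid), 1.5)
  # degenerate spread concentrates at the value
  k2 <- kde_profile(rep(90, 50), "direction")
  expect_equal(k2$grid[which.max(k2$density)], 90, tolerance = 1)
  # n < 2 reports instead of estimating
  k3 <- kde_profile(42, "speed")
  expect_null(k3$density)
  expect_match(k3$note, "fewer than 2")
})

test_that("segment signatures label following vs encounter heuristically", {
  # 7-h parallel run -> following; 1-h divergent run -> encounter
  ev <- rbind(mk_events(rep(10, 7), rep(12, 7), rep(500, 7), rep(520, 7)),
              mk_events(100, 250, 400, 900))
  ev$t_start_a <- hours(c(1:7, 20)); ev$t_end_a <- hours(c(2:8, 21))
  ev$t_start_b <- ev$t_start_a; ev$t_end_b <- ev$t_end_a
  seg <- trace_segments(ev, 1)
  expect_equal(nrow(seg), 2)
  sig <- segment_signature(seg, describe_events(ev), sampling_interval_h = 1)
  expect_equal(sig$label, c("following", "encounter"))
  expect_true(isTRUE(attr(sig, "heuristic")))
  expect_equal(sig$duration_h, c(7, 1))
})

test_that("follower dyads concentrate heading differences near zero", {
  set.seed(6)
  sim <- simulate_dyad("co_movement", days = 15, jitter_m = 30, seed = 6)
  fit <- ortega(sim$tracks)
  d <- describe_events(fit$dyads[[1]]$events)
  d <- d[d$kind == "concurrent", ]
  # simultaneous PPA pairs compare the same movement step of leader and
  # follower: the difference is jitter only
  sim0 <- d[d$lag_h < 0.5, ]
  expect_gte(mean(sim0$d_heading < 45), 0.8)
  # lag +/- 1 h pairs compare adjacent steps and add one turning angle, so
  # the full concurrent set is wider but still biased toward parallel
  expect_lt(median(d$d_heading), 45)
})

test_that("avoidance flag marks low-frequency dyads", {
  tab <- data.frame(dyad = c("a|b", "a|c", "b|c"),
                    n_concurrent_segments = c(0, 14, 9))
  fl <- flag_avoidance(tab, quantile = 0.25)
  expect_equal(fl$avoidance_flag, c(TRUE, FALSE, FALSE))
})
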