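# Proximity buffer/time-window baseline and the method comparison.

test_that("buffer and time-window rules decide contacts", {
  tr <- as_tracks(rbind(
    make_fixes("A", c(0, 1, 2), c(0, 0, 0), 0),
    make_fixes("B", c(0, 1.75, 2), c(100, 100, 300), 0)))
  # simultaneous fixes 100 m apart, buffer 200 -> contact; the 300 m pair
  # at t = 2 stays outside the buffer
  expect_equal(nrow(proximity_events(tr, "A", "B", 200, 0)), 1)
  # all six 100 m fix pairs fall inside a 2 h window
  expect_equal(nrow(proximity_events(tr, "A", "B", 250, 120)), 6)
  # fixes 45 min apart: excluded at tau = 30, included at tau = 60
  ev30 <- proximity_events(tr, "A", "B", 200, 30)
  ev60 <- proximity_events(tr, "A", "B", 200, 60)
  expect_false(any(abs(as.numeric(ev30$t_a) - as.numeric(ev30$t_b)) == 45 * 60))
  expect_true(any(abs(as.numeric(ev60$t_a) - as.numeric(ev60$t_b)) == 45 * 60))
})

test_that("contact runs chain within one sampling interval", {
  tr <- as_tracks(rbind(
    make_fixes("A", c(9, 10, 11, 20), c(0, 0, 0, 0), 0),
    make_fixes("B", c(9, 10, 11, 20), c(50, 50, 50, 50), 0)))
  ct <- proximity_events(tr, "A", "B", 200, 0)
  runs <- proximity_segments(ct, 1)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$duration_h, c(2, 0))    # 09-11 chained; isolated contact
  expect_equal(runs$n_contacts, c(3, 1))
  expect_equal(nrow(proximity_segments(ct[0, ], 1)), 0)
})

test_that("contact counts are non-decreasing in buffer and window", {
  set.seed(8)
  sim <- simulate_dyad("co_movement", days = 5, jitter_m = 400, offset_h = 0.25, seed = 8)
  counts <- sapply(c(200, 500, 1000, 2000), function(d)
    nrow(proximity_events(sim$tracks, "A", "B", d, 30)))
  expect_true(all(diff(counts) >= 0))
  counts_tau <- sapply(c(0, 30, 60), function(tau)
    nrow(proximity_events(sim$tracks, "A", "B", 500, tau)))
  expect_true(all(diff(counts_tau) >= 0))
})

test_that("desynchronized collars defeat proximity but not the PPA method", {
  set.seed(19)
  sim <- simulate_dyad("co_movement", days = 10, jitter_m = 50,
                       offset_h = 0.5, seed = 19)
  # tau = 0 requires equal timestamps: none exist under the half-interval shift
  expect_equal(nrow(proximity_events(sim$tracks, "A", "B", 2000, 0)), 0)
  fit <- ortega(sim$tracks)
  expect_gte(coverage_fraction(sim$truth, fit$dyads[[1]]$segments), 0.9)
})

test_that("Mann-Whitney comparison handles regular and degenerate samples", {
  # disjoint samples: U = 0 for the first sample (all 9 pairs lose)
  cmp <- compare_methods(c(1, 2, 3), c(10, 20, 30))
  expect_equal(cmp$U, 0)
  expect_lt(cmp$p_value, 0.1)
  # identical samples: no median difference
  cmp2 <- compare_methods(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(cmp2$p_value, 0.9)
  # empty samples produce a report, not a p-value
  cmp3 <- compare_methods(numeric(0), c(1, 2))
  expect_true(is.na(cmp3$p_value))
  expect_match(cmp3$note, "no interactions")
  cmp4 <- compare_methods(numeric(0), numeric(0))
  expect_match(cmp4$note, "either method")
})

test_that("the sweep covers the full parameter grid in long format", {
  set.seed(23)
  sim <- simulate_dyad("co_movement", days = 3, jitter_m = 100, seed = 23)
  sw <- proximity_sweep(sim$tracks, "A", "B")
  expect_setequal(unique(sw$delta_m), c(200, 500, 1000, 2000))
  expect_setequal(unique(sw$tau_min), c(0, 30, 60))
  expect_equal(nrow(unique(sw[, c("delta_m", "tau_min")])), 12)
})
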