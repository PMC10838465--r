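# EWMA speed budget and PPA ellipse construction/filtering.

# independent scalar-loop oracle for the truncated EWMA sum
ewma_oracle <- function(v, lambda, n, eps) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    if (lambda == 1) { out[i] <- v[i]; next }
    s <- 0
    for (k in 0:(n - 1)) {
      if (i - k < 1) break
      s <- s + lambda * (1 - lambda)^k * v[i - k]
    }
    out[i] <- s
  }
  pmax(eps * out, v)
}

test_that("EWMA branches match the stated closed forms", {
  # lambda = 1 gives eps * v exactly
  expect_equal(ewma_max_speed(1000, ewma_params(1, 1, 1.25))$v_max, 1250)
  # direct evaluation of the weighted sum, with the validity floor
  r <- ewma_max_speed(c(4, 2, 8), ewma_params(0.5, 3, 1))
  expect_equal(r$smoothed[3], 0.5 * 8 + 0.25 * 2 + 0.125 * 4)  # 5.0
  expect_equal(r$v_max[3], 8)                                   # floored
  expect_true(r$floored[3])
  # constant speeds: truncated weights sum < 1, so the floor binds at v
  r2 <- ewma_max_speed(rep(7, 20), ewma_params(0.3, 5, 1))
  expect_true(all(r2$smoothed <= 7 + 1e-12))
  expect_equal(r2$v_max, rep(7, 20))
})

test_that("EWMA agrees with an independent summation oracle across random draws", {
  set.seed(11)
  for (rep in 1:50) {
    m <- sample(3:40, 1)
    v <- runif(m, 0, 3000)
    lam <- runif(1, 0.05, 1)
    n <- sample(1:12, 1)
    eps <- runif(1, 1, 1.6)
    got <- ewma_max_speed(v, ewma_params(lam, n, eps))$v_max
    expect_equal(got, ewma_oracle(v, lam, n, eps), tolerance = 1e-12)
  }
})

test_that("EWMA weights are lambda(1-lambda)^k, positive and decreasing", {
  lam <- 0.37; n <- 8
  # recover weight k by feeding a unit impulse at position m-k
  for (k in 0:(n - 1)) {
    v <- rep(0, n + 2); v[n + 2 - k] <- 1
    s <- ewma_max_speed(v, ewma_params(lam, n, 1))$smoothed[n + 2]
    expect_equal(s, lam * (1 - lam)^k, tolerance = 1e-14)
  }
})

test_that("EWMA rejects invalid inputs", {
  expect_error(ewma_params(0), "lambda")
  expect_error(ewma_params(1.5), "lambda")
  expect_error(ewma_max_speed(c(1, NA), ewma_params()), "finite")
})

test_that("PPA ellipse has the closed-form geometry", {
  p <- build_ppa(0, 0, 2000, 0, dt_h = 1, v_max = 4000)
  expect_equal(p$a, 2000)
  expect_equal(p$cfoc, 1000)
  expect_equal(p$b, sqrt(3) * 1000, tolerance = 1e-12)
  # polygon area converges to pi*a*b (< 0.1% at the default 100 vertices)
  area100 <- polygon_area(ortegar:::ppa_boundary(p, 1, 100))
  expect_lt(abs(area100 - pi * p$a * p$b) / (pi * p$a * p$b), 1e-3)
  area1000 <- polygon_area(ortegar:::ppa_boundary(p, 1, 1000))
  expect_lt(abs(area1000 - pi * p$a * p$b) / (pi * p$a * p$b), 1e-5)
  # both foci inside the boundary
  expect_true(all(point_in_convex(c(0, 2000), c(0, 0),
                                  ortegar:::ppa_boundary(p, 1, 100), tol = 1e-6)))
})

test_that("degenerate and circular limits behave", {
  d <- build_ppa(0, 0, 1000, 0, dt_h = 1, v_max = 1000)  # v_max*dt == dist
  expect_true(d$degenerate)
  expect_equal(d$b, 0)
  circ <- build_ppa(500, 500, 500, 500, dt_h = 1, v_max = 800)  # coincident foci
  expect_equal(circ$a, 400)
  expect_equal(circ$b, 400)
  expect_error(build_ppa(0, 0, 5000, 0, 1, 1000), "infeasib")
})

test_that("build_ppas floors the budget so every PPA is feasible", {
  set.seed(3)
  tr <- as_tracks(make_fixes("A", 0:30, cumsum(rnorm(31, 0, 800)), cumsum(rnorm(31, 0, 800))))
  pp <- build_ppas(build_segments(tr), ewma_params(0.5, 10, 1.25))
  expect_true(all(pp$a >= pp$cfoc - 1e-9))
  for (i in seq_len(nrow(pp))) {
    bd <- ortegar:::ppa_boundary(pp, i, 100)
    expect_true(all(point_in_convex(c(pp$x1[i], pp$x2[i]), c(pp$y1[i], pp$y2[i]), bd, tol = 1e-3)))
  }
})

test_that("gap rule removes exactly the PPAs from injected gaps", {
  # constant 1-h sampling with a single 10-h gap: sd ~ small, gap removed
  h <- c(0:10, 20, 21:25)
  tr <- as_tracks(make_fixes("A", h, seq_along(h) * 100, 0))
  pp <- build_ppas(build_segments(tr), ewma_params(1, 1, 1.25))
  flt <- filter_gap_ppas(pp, interval_stats(tr), k = 3)
  expect_equal(sum(attr(flt, "dropped")), 1)
  expect_true(all(flt$dt_h < 10))
  # gap-free data: identity
  tr2 <- as_tracks(make_fixes("A", 0:10, (0:10) * 200, 0))
  pp2 <- build_ppas(build_segments(tr2), ewma_params(1, 1, 1.25))
  flt2 <- filter_gap_ppas(pp2, interval_stats(tr2), k = 3)
  expect_equal(nrow(flt2), nrow(pp2))
  expect_equal(sum(attr(flt2, "dropped")), 0)
})

test_that("gap rule separates planted gaps from jittered regular sampling", {
  set.seed(5)
  dt <- abs(rnorm(60, 1, 0.02))          # near-1h intervals
  gap_pos <- c(10, 22, 35, 44, 53)
  dt[gap_pos] <- 8                        # five planted 8-h gaps
  h <- cumsum(c(0, dt))
  tr <- as_tracks(make_fixes("A", h, seq_along(h) * 50, 0))
  pp <- build_ppas(build_segments(tr), ewma_params(1, 1, 1.25))
  flt <- filter_gap_ppas(pp, interval_stats(tr), k = 3)
  expect_equal(sum(attr(flt, "dropped")), 5)
  expect_equal(nrow(flt), nrow(pp) - 5)
})
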