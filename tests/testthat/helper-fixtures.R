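# Shared fixture builders. Everything is generated in code; coordinates are
# planar metres unless a test needs geographic input.

hours <- function(h) as.POSIXct("2020-06-01 00:00:00", tz = "UTC") + h * 3600

# minimal planar track data frame
make_fixes <- function(id, h, x, y) {
  data.frame(id = id, t = hours(h), x = x, y = y, stringsAsFactors = FALSE)
}

# a simple two-individual planar track set
two_track_fixture <- function() {
  as_tracks(rbind(
    make_fixes("A", 0:5, (0:5) * 1000, 0),
    make_fixes("B", 0:5, (0:5) * 1000, 500)))
}

# random PPA set: n random short segments inside a box, fixed speed budget
random_ppas <- function(n, box = 10000, a_scale = 1500, t_jitter_h = 48) {
  x1 <- runif(n, 0, box); y1 <- runif(n, 0, box)
  ang <- runif(n, 0, 2 * pi)
  len <- runif(n, 100, 2000)
  x2 <- x1 + len * cos(ang); y2 <- y1 + len * sin(ang)
  dt <- 1
  vmax <- (len + runif(n, 50, a_scale)) / dt  # ensures 2a > dist
  t0 <- hours(runif(n, 0, t_jitter_h))
  a <- vmax * dt / 2
  cf <- len / 2
  out <- data.frame(id = "R", seg = seq_len(n),
                    t_start = t0, t_end = t0 + dt * 3600, dt_h = dt,
                    x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                    cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                    a = a, b = sqrt(pmax(a^2 - cf^2, 0)), cfoc = cf,
                    v_max = vmax, theta = atan2(y2 - y1, x2 - x1),
                    degenerate = FALSE, floored = FALSE,
                    speed_mh = len / dt, heading_deg = (atan2(x2 - x1, y2 - y1) * 180 / pi) %% 360,
                    stringsAsFactors = FALSE)
  class(out) <- c("ppa_set", "data.frame")
  out
}

# membership test straight from the focal definition of an ellipse
in_ellipse_foci <- function(px, py, e) {
  d1 <- sqrt((px - e$x1[1])^2 + (py - e$y1[1])^2)
  d2 <- sqrt((px - e$x2[1])^2 + (py - e$y2[1])^2)
  d1 + d2 <= 2 * e$a[1]
}

# Monte-Carlo intersection oracle: sample uniformly inside e1, count points
# inside e2 (both by the focal-distance definition, independent of any
# polygonal machinery)
mc_overlap <- function(e1, e2, n = 1e5) {
  u <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  ex <- e1$a[1] * u * cos(th); ey <- max(e1$b[1], 1e-9) * u * sin(th)
  ct <- cos(e1$theta[1]); st <- sin(e1$theta[1])
  px <- e1$cx[1] + ex * ct - ey * st
  py <- e1$cy[1] + ex * st + ey * ct
  frac <- mean(in_ellipse_foci(px, py, e2))
  list(frac = frac, area = frac * pi * e1$a[1] * e1$b[1])
}
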