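# Synthetic telemetry with ground-truth interaction structure: correlated
# random walks with home-range attraction, plus scripted co-movement,
# lagged-revisit and avoidance regimes between two individuals.

# correlated random walk with optional attraction to a range centre;
# returns an n x 2 position matrix. Step lengths ~ Gamma(shape, mean/shape);
# headings evolve by wrapped-normal turns, biased toward the centre bearing
# with weight `attraction` (enough to produce a stable home range).
crw_path <- function(n, start = c(0, 0), step_mean_m = 500, step_shape = 1.5,
                     turn_sd_deg = 40, center = start, attraction = 0.15) {
  if (step_mean_m <= 0 || step_shape <= 0) stop("step parameters must be > 0")
  if (attraction < 0 || turn_sd_deg < 0) stop("invalid motion parameters")
  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- start
  h <- stats::runif(1, 0, 2 * pi)
  steps <- stats::rgamma(n - 1, shape = step_shape,
                         scale = step_mean_m / step_shape)
  turns <- stats::rnorm(n - 1, 0, turn_sd_deg * pi / 180)
  for (i in seq_len(n - 1)) {
    bearing <- atan2(center[2] - pos[i, 2], center[1] - pos[i, 1])
    dh <- atan2(sin(bearing - h), cos(bearing - h))
    h <- h + attraction * dh + turns[i]
    pos[i + 1, ] <- pos[i, ] + steps[i] * c(cos(h), sin(h))
  }
  pos
}

# linear interpolation of a fix path at arbitrary times (numeric seconds);
# constant extrapolation outside the tracked span
interp_path <- function(t_ref, pos_ref, t_query) {
  x <- stats::approx(t_ref, pos_ref[, 1], xout = t_query, rule = 2)$y
  y <- stats::approx(t_ref, pos_ref[, 2], xout = t_query, rule = 2)$y
  cbind(x, y)
}

#' Simulate a two-individual scenario with ground truth
#'
#' Individual A is a correlated random walk with home-range attraction;
#' individual B follows the scripted regime:
#' \describe{
#'   \item{independent}{B is an independent walk around a centre
#'     `separation_m` to the east.}
#'   \item{co_movement}{B occupies A's path position at each of its own fix
#'     times (optionally offset by `offset_h`) plus Gaussian jitter — a
#'     follower dyad. Truth: one concurrent interval spanning the overlap of
#'     the two tracking spans.}
#'   \item{lagged_revisit}{B traverses A's path `lag_h` hours later (plus
#'     jitter). Truth: one delayed interval at lag `lag_h`.}
#'   \item{avoidance}{B walks its own range but each step is pushed away
#'     from A's concurrent position when within `avoid_radius_m`.}
#' }
#'
#' @param regime One of "independent", "co_movement", "lagged_revisit",
#'   "avoidance".
#' @param days Tracking duration (days).
#' @param interval_h Sampling interval (hours), default 1.
#' @param jitter_m SD of the Gaussian positional jitter added to B in the
#'   follower/revisit regimes (default 50 m).
#' @param lag_h Revisit lag (hours), default 24.
#' @param offset_h Time offset of B's fix grid relative to A's (hours);
#'   use half the sampling interval to desynchronise the two collars.
#' @param separation_m Distance between range centres for
#'   independent/avoidance (default 50 km for independent, 3 km for
#'   avoidance).
#' @param step_mean_m,step_shape,turn_sd_deg,attraction CRW motion
#'   parameters (defaults: 500 m mean hourly step, shape 1.5, 40 degree
#'   turning SD, attraction 0.15).
#' @param avoid_radius_m Repulsion radius for the avoidance regime (2000 m).
#' @param gap_schedule Optional data frame `id, t_start, t_end` (POSIXct):
#'   fixes inside a scheduled gap are removed.
#' @param seed Integer seed; fully determines the output.
#' @param t0 Start time (POSIXct or ISO string, UTC).
#' @return List with `tracks` (a `"tracks"` object, individuals "A" and
#'   "B") and `truth` (data frame `id_a, id_b, t_start, t_end, type,
#'   lag_h`).
#' @export
simulate_dyad <- function(regime = c("independent", "co_movement",
                                     "lagged_revisit", "avoidance"),
                          days = 30, interval_h = 1, jitter_m = 50,
                          lag_h = 24, offset_h = 0,
                          separation_m = NULL,
                          step_mean_m = 500, step_shape = 1.5,
                          turn_sd_deg = 40, attraction = 0.15,
                          avoid_radius_m = 2000,
                          gap_schedule = NULL, seed = 1,
                          t0 = "2020-01-01 00:00:00") {
  regime <- match.arg(regime)
  if (interval_h <= 0 || days <= 0) stop("days and interval_h must be > 0")
  set.seed(seed)
  t0 <- as.POSIXct(t0, tz = "UTC")
  n <- as.integer(days * 24 / interval_h) + 1L
  ta <- as.numeric(t0) + (seq_len(n) - 1) * interval_h * 3600
  posA <- crw_path(n, c(0, 0), step_mean_m, step_shape, turn_sd_deg,
                   center = c(0, 0), attraction = attraction)

  tb <- ta + offset_h * 3600
  truth_type <- NULL
  if (regime == "independent") {
    if (is.null(separation_m)) separation_m <- 50000
    posB <- crw_path(n, c(separation_m, 0), step_mean_m, step_shape,
                     turn_sd_deg, center = c(separation_m, 0),
                     attraction = attraction)
  } else if (regime == "co_movement") {
    posB <- interp_path(ta, posA, tb)
    if (jitter_m > 0)
      posB <- posB + matrix(stats::rnorm(2 * n, 0, jitter_m), n, 2)
    truth_type <- "concurrent"
  } else if (regime == "lagged_revisit") {
    tb <- ta + lag_h * 3600
    posB <- posA
    if (jitter_m > 0)
      posB <- posB + matrix(stats::rnorm(2 * n, 0, jitter_m), n, 2)
    truth_type <- "delayed"
  } else { # avoidance
    if (is.null(separation_m)) separation_m <- 3000
    ctrB <- c(separation_m, 0)
    posB <- matrix(NA_real_, n, 2)
    posB[1, ] <- ctrB
    h <- stats::runif(1, 0, 2 * pi)
    steps <- stats::rgamma(n - 1, step_shape, scale = step_mean_m / step_shape)
    turns <- stats::rnorm(n - 1, 0, turn_sd_deg * pi / 180)
    for (i in seq_len(n - 1)) {
      bearing <- atan2(ctrB[2] - posB[i, 2], ctrB[1] - posB[i, 1])
      dh <- atan2(sin(bearing - h), cos(bearing - h))
      h <- h + attraction * dh + turns[i]
      stp <- steps[i] * c(cos(h), sin(h))
      away <- posB[i, ] - posA[i, ]
      dd <- sqrt(sum(away^2))
      if (dd < avoid_radius_m && dd > 0)
        stp <- stp + (avoid_radius_m - dd) * away / dd
      posB[i + 1, ] <- posB[i, ] + stp
    }
  }

  df <- data.frame(
    id = rep(c("A", "B"), each = n),
    t = as.POSIXct(c(ta, tb), origin = "1970-01-01", tz = "UTC"),
    x = c(posA[, 1], posB[, 1]),
    y = c(posA[, 2], posB[, 2]),
    stringsAsFactors = FALSE)
  if (!is.null(gap_schedule)) {
    for (g in seq_len(nrow(gap_schedule))) {
      drop <- df$id == gap_schedule$id[g] &
        df$t > gap_schedule$t_start[g] & df$t < gap_schedule$t_end[g]
      df <- df[!drop, , drop = FALSE]
    }
  }
  tracks <- as_tracks(df)

  truth <- data.frame(id_a = character(0), id_b = character(0),
                      t_start = as.POSIXct(character(0), tz = "UTC"),
                      t_end = as.POSIXct(character(0), tz = "UTC"),
                      type = character(0), lag_h = numeric(0))
  if (!is.null(truth_type)) {
    ov0 <- max(min(ta), min(tb)); ov1 <- min(max(ta), max(tb))
    if (regime == "lagged_revisit") { ov0 <- min(tb); ov1 <- max(tb) }
    truth <- data.frame(
      id_a = "A", id_b = "B",
      t_start = as.POSIXct(ov0, origin = "1970-01-01", tz = "UTC"),
      t_end = as.POSIXct(ov1, origin = "1970-01-01", tz = "UTC"),
      type = truth_type,
      lag_h = if (regime == "lagged_revisit") lag_h else 0,
      stringsAsFactors = FALSE)
  }
  list(tracks = tracks, truth = truth)
}

#' Canned three-stage dispersal scenario
#'
#' Emulates a mother-young style timeline: stage 1 the pair co-moves
#' (follower with jitter); stage 2 the young only partially accompanies the
#' mother (scripted co-movement bouts covering about a third of the time,
#' own range otherwise); stage 3 the ranges separate and the young only
#' revisits the mother's path with a one-day lag in occasional bouts.
#'
#' @param seed Integer seed.
#' @param days_per_stage Length-3 integer vector (default 30 days each).
#' @param interval_h Sampling interval (hours).
#' @param jitter_m Follower jitter SD (m).
#' @param t0 Start time.
#' @return List `tracks`, `truth`, `stages` (data frame with stage
#'   boundaries).
#' @export
stage_scenario <- function(seed = 1, days_per_stage = c(30, 30, 30),
                           interval_h = 1, jitter_m = 50,
                           t0 = "2020-01-01 00:00:00") {
  stopifnot(length(days_per_stage) == 3)
  set.seed(seed)
  t0 <- as.POSIXct(t0, tz = "UTC")
  per <- as.integer(days_per_stage * 24 / interval_h)
  n <- sum(per) + 1L
  tt <- as.numeric(t0) + (seq_len(n) - 1) * interval_h * 3600
  posA <- crw_path(n, c(0, 0), 500, 1.5, 40, center = c(0, 0))

  s1 <- per[1]; s2 <- per[2]
  stage <- c(rep(1L, s1), rep(2L, s2), rep(3L, per[3] + 1L))

  # stage-2 bouts: first 2 days of every 6-day block are co-movement
  day_idx <- floor((seq_len(n) - 1) * interval_h / 24)
  bout2 <- stage == 2L & ((day_idx - days_per_stage[1]) %% 6) < 2
  # stage-3 bouts: first day of every 10-day block is a lagged revisit
  bout3 <- stage == 3L & ((day_idx - sum(days_per_stage[1:2])) %% 10) < 1

  follow <- stage == 1L | bout2
  posB <- matrix(NA_real_, n, 2)
  jit <- matrix(stats::rnorm(2 * n, 0, jitter_m), n, 2)
  ctrB3 <- c(15000, 0)                    # the young's new range centre
  lag_s <- 24 * 3600
  ownB <- crw_path(n, c(4000, 0), 500, 1.5, 40, center = c(4000, 0))
  own3 <- crw_path(n, ctrB3, 500, 1.5, 40, center = ctrB3)
  for (i in seq_len(n)) {
    posB[i, ] <-
      if (follow[i]) posA[i, ] + jit[i, ]
      else if (bout3[i]) interp_path(tt, posA, tt[i] - lag_s)[1, ] + jit[i, ]
      else if (stage[i] == 3L) own3[i, ]
      else ownB[i, ]
  }

  df <- data.frame(id = rep(c("A", "B"), each = n),
                   t = as.POSIXct(rep(tt, 2), origin = "1970-01-01", tz = "UTC"),
                   x = c(posA[, 1], posB[, 1]), y = c(posA[, 2], posB[, 2]),
                   stringsAsFactors = FALSE)
  tracks <- as_tracks(df)

  runs_to_intervals <- function(mask, type, lag) {
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(id_a = "A", id_b = "B",
               t_start = as.POSIXct(tt[starts[keep]], origin = "1970-01-01", tz = "UTC"),
               t_end = as.POSIXct(tt[pmin(ends[keep] + 1, n)], origin = "1970-01-01", tz = "UTC"),
               type = type, lag_h = lag, stringsAsFactors = FALSE)
  }
  truth <- rbind(runs_to_intervals(follow, "concurrent", 0),
                 runs_to_intervals(bout3, "delayed", 24))
  bounds <- as.POSIXct(c(tt[1], tt[s1 + 1], tt[s1 + s2 + 1], tt[n]),
                       origin = "1970-01-01", tz = "UTC")
  stages <- data.frame(stage = 1:3, start = bounds[1:3], end = bounds[2:4])
  list(tracks = tracks, truth = truth, stages = stages)
}

#' Fraction of truth time covered by detected segments
#'
#' Sums, over the truth intervals, the length of their intersection with the
#' union of detected segment intervals, divided by the total truth length.
#'
#' @param truth Truth table with `t_start`, `t_end` (POSIXct).
#' @param segments `"interaction_segments"` (needs `t_min`, `t_max`).
#' @return Fraction in \[0, 1\] (NA when truth is empty).
#' @export
coverage_fraction <- function(truth, segments) {
  if (is.null(truth) || !nrow(truth)) return(NA_real_)
  ts0 <- as.numeric(segments$t_min); ts1 <- as.numeric(segments$t_max)
  tot <- 0; cov <- 0
  for (k in seq_len(nrow(truth))) {
    a <- as.numeric(truth$t_start[k]); b <- as.numeric(truth$t_end[k])
    tot <- tot + (b - a)
    if (!length(ts0)) next
    lo <- pmax(ts0, a); hi <- pmin(ts1, b)
    w <- which(hi > lo)
    if (!length(w)) next
    # merge the clipped intervals to avoid double counting
    o <- order(lo[w])
    l <- lo[w][o]; h <- hi[w][o]
    cur_l <- l[1]; cur_h <- h[1]
    for (m in seq_along(l)[-1]) {
      if (l[m] <= cur_h) cur_h <- max(cur_h, h[m])
      else { cov <- cov + (cur_h - cur_l); cur_l <- l[m]; cur_h <- h[m] }
    }
    cov <- cov + (cur_h - cur_l)
  }
  cov / tot
}
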