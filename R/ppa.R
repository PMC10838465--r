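# PPA engine: EWMA maximum-speed estimation and potential path area
# ellipses between consecutive fixes, with gap-based removal.

#' EWMA speed-limit parameters
#'
#' The per-segment maximum speed that bounds each potential path area is an
#' exponentially weighted moving average of recent observed speeds,
#' `s_i = sum_{k=0}^{n-1} lambda (1-lambda)^k v_{i-k}` (or `s_i = v_i` when
#' `lambda = 1`), scaled by a multiplicative error term:
#' `v_max = epsilon * s_i`. The error term absorbs natural variability in
#' animal movement; 1.25 allows the speed budget to exceed the smoothed
#' average by 25%.
#'
#' @param lambda Smoothing constant in (0, 1]. 1 uses only the current speed.
#' @param n Window length: number of past speeds entering the average.
#' @param epsilon Multiplicative error term, >= 1.
#' @param renormalize If TRUE, truncated head-of-track weights are rescaled
#'   to sum to the full-window weight total; default FALSE (the truncated
#'   sum is used as-is).
#' @return An `"ewma_params"` list.
#' @export
ewma_params <- function(lambda = 0.5, n = 10, epsilon = 1.25,
                        renormalize = FALSE) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0 || lambda > 1)
    stop("lambda must be in (0, 1]")
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.numeric(epsilon) || epsilon < 1) stop("epsilon must be >= 1")
  structure(list(lambda = lambda, n = as.integer(n), epsilon = epsilon,
                 renormalize = isTRUE(renormalize)),
            class = "ewma_params")
}

#' EWMA maximum speed per segment
#'
#' Computes the smoothed speed and the speed budget `v_max` for each movement
#' segment of one individual. At the head of a track, where fewer than `n`
#' previous speeds exist, the sum runs over the available history only.
#' Because a valid PPA requires `v_max * dt >= dist`, the budget is floored
#' at the observed segment speed; segments where the floor was applied are
#' flagged (`floored`).
#'
#' @param speeds Numeric vector of observed segment speeds (m/h),
#'   time-ordered, one individual.
#' @param params An [ewma_params()] object.
#' @return Data frame `speed, smoothed, v_max, floored`.
#' @export
ewma_max_speed <- function(speeds, params = ewma_params()) {
  stopifnot(inherits(params, "ewma_params"))
  if (any(!is.finite(speeds)) || any(speeds < 0))
    stop("speeds must be finite and non-negative")
  m <- length(speeds)
  lam <- params$lambda
  if (lam == 1) {
    sm <- speeds
  } else {
    w <- lam * (1 - lam)^(0:(params$n - 1))
    sm <- vapply(seq_len(m), function(i) {
      k <- 0:min(params$n - 1, i - 1)
      s <- sum(w[k + 1] * speeds[i - k])
      if (params$renormalize) s <- s * sum(w) / sum(w[k + 1])
      s
    }, numeric(1))
  }
  vmax <- params$epsilon * sm
  floored <- vmax < speeds
  vmax[floored] <- speeds[floored]
  data.frame(speed = speeds, smoothed = sm, v_max = vmax, floored = floored)
}

#' Construct PPA ellipses for every movement segment
#'
#' The potential path area between two consecutive fixes is the ellipse with
#' the fixes at its foci and major axis `v_max * dt`: the planar projection
#' of the space-time prism bounded by the speed budget. Semi-axes are
#' `a = v_max*dt/2`, `c = dist/2`, `b = sqrt(a^2 - c^2)`. A segment whose
#' speed budget equals its observed speed yields a degenerate (zero-width)
#' ellipse, flagged.
#'
#' @param segments Segment table from [build_segments()] (any number of
#'   individuals; the EWMA runs per individual in time order).
#' @param params [ewma_params()].
#' @return Data frame of class `"ppa_set"`: one row per segment with
#'   `id, seg, t_start, t_end, dt_h, x1, y1, x2, y2, cx, cy, a, b, cfoc,
#'   v_max, theta, degenerate, floored`.
#' @export
build_ppas <- function(segments, params = ewma_params()) {
  parts <- lapply(unique(segments$id), function(i) {
    sg <- segments[segments$id == i, , drop = FALSE]
    sg <- sg[order(sg$t0), , drop = FALSE]
    ew <- ewma_max_speed(sg$speed_mh, params)
    a <- ew$v_max * sg$dt_h / 2
    cf <- sg$dist_m / 2
    if (any(a < cf - 1e-9))
      stop("geometric infeasibility: v_max * dt < dist")  # unreachable: floored
    b <- sqrt(pmax(a^2 - cf^2, 0))
    data.frame(id = i, seg = sg$seg,
               t_start = sg$t0, t_end = sg$t1, dt_h = sg$dt_h,
               x1 = sg$x0, y1 = sg$y0, x2 = sg$x1, y2 = sg$y1,
               cx = (sg$x0 + sg$x1) / 2, cy = (sg$y0 + sg$y1) / 2,
               a = a, b = b, cfoc = cf, v_max = ew$v_max,
               theta = atan2(sg$y1 - sg$y0, sg$x1 - sg$x0),
               degenerate = b <= a * 1e-12,
               floored = ew$floored,
               speed_mh = sg$speed_mh, heading_deg = sg$heading_deg,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  class(res) <- c("ppa_set", "data.frame")
  res
}

#' Single PPA ellipse from explicit inputs
#'
#' @param x1,y1,x2,y2 The two fixes (foci), metres.
#' @param dt_h Time budget in hours.
#' @param v_max Speed budget in m/h; must satisfy `v_max * dt_h >= dist`.
#' @return One-row `"ppa_set"` data frame.
#' @export
build_ppa <- function(x1, y1, x2, y2, dt_h, v_max) {
  dist <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (v_max * dt_h < dist - 1e-9)
    stop("geometric infeasibility: v_max * dt < distance between fixes")
  a <- v_max * dt_h / 2
  cf <- dist / 2
  t0 <- as.POSIXct("2000-01-01", tz = "UTC")
  res <- data.frame(id = "x", seg = 1L,
                    t_start = t0, t_end = t0 + dt_h * 3600, dt_h = dt_h,
                    x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                    cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                    a = a, b = sqrt(max(a^2 - cf^2, 0)), cfoc = cf,
                    v_max = v_max, theta = atan2(y2 - y1, x2 - x1),
                    degenerate = (a - cf) <= a * 1e-12, floored = FALSE,
                    speed_mh = dist / dt_h, heading_deg = NA_real_,
                    stringsAsFactors = FALSE)
  class(res) <- c("ppa_set", "data.frame")
  res
}

# boundary polygon of one ppa_set row; degenerate ellipses get a hair-width
# minor axis so the polygon machinery still applies
ppa_boundary <- function(ppa, i = 1, n = 100) {
  b <- max(ppa$b[i], 1e-6)
  ellipse_polygon(ppa$cx[i], ppa$cy[i], ppa$a[i], b, ppa$theta[i], n)
}

#' Remove PPAs generated by sampling gaps
#'
#' Very large PPAs produced by data gaps create spurious intersections and
#' are removed. The default rule drops a PPA whose time interval exceeds
#' `mean + k * sd` of the individual's sampling intervals (k = 3). The
#' literal rule `dt > k * sd` is selectable but degenerates when the
#' sampling is near-constant (sd ~ 0).
#'
#' @param ppas A `"ppa_set"`.
#' @param stats Interval statistics from [interval_stats()] for the same
#'   individuals.
#' @param k Gap multiplier (default 3).
#' @param rule `"mean_plus_k_sd"` (default) or `"k_sd"`.
#' @return Filtered `"ppa_set"`; attribute `dropped` holds the per-individual
#'   dropped counts.
#' @export
filter_gap_ppas <- function(ppas, stats, k = 3,
                            rule = c("mean_plus_k_sd", "k_sd")) {
  rule <- match.arg(rule)
  keep <- rep(TRUE, nrow(ppas))
  dropped <- stats::setNames(integer(length(unique(ppas$id))), unique(ppas$id))
  for (i in unique(ppas$id)) {
    st <- stats[stats$id == i, , drop = FALSE]
    if (!nrow(st)) stop(sprintf("no interval stats for individual %s", i))
    thr <- if (rule == "mean_plus_k_sd") st$mean_dt_h + k * st$sd_dt_h
           else k * st$sd_dt_h
    sel <- ppas$id == i
    gap <- sel & ppas$dt_h > thr + 1e-12
    keep[gap] <- FALSE
    dropped[i] <- sum(gap)
  }
  out <- ppas[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppa_set", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Export PPAs to CSV
#' @param ppas A `"ppa_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppas <- function(ppas, path) {
  out <- data.frame(
    id = ppas$id,
    t_start = format(ppas$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    t_end = format(ppas$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    a = ppas$a, b = ppas$b, cx = ppas$cx, cy = ppas$cy,
    orientation = ppas$theta, v_max = ppas$v_max,
    degenerate = ppas$degenerate, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export PPA polygons as GeoJSON
#'
#' Planar coordinates are written as-is; consumers should treat the CRS as
#' the projected frame of the track set.
#'
#' @param ppas A `"ppa_set"`.
#' @param path Output path.
#' @param vertices Boundary vertices per ellipse.
#' @return `path`, invisibly.
#' @export
ppas_geojson <- function(ppas, path, vertices = 100) {
  feats <- lapply(seq_len(nrow(ppas)), function(i) {
    p <- ppa_boundary(ppas, i, vertices)
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = ppas$id[i],
                           t_start = format(ppas$t_start[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                           t_end = format(ppas$t_end[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                           v_max = ppas$v_max[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
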