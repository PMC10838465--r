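# Movement-parameter difference descriptors at intersecting PPA pairs and
# kernel-density summaries supporting the behavioural-pattern signatures
# (following, encounter, latency, avoidance).

#' Movement-difference descriptors for intersection events
#'
#' For every intersecting PPA pair, the absolute circular heading difference
#' (in \[0, 180\] degrees) and the absolute speed difference (m/h) of the two
#' generating segments. Events where either segment has an undefined
#' (zero-displacement) heading are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param events An `"interaction_events"` table.
#' @return Data frame `event_row, kind, bin_h, lag_h, d_heading, d_speed`;
#'   attribute `n_excluded`.
#' @export
describe_events <- function(events) {
  ok <- is.finite(events$heading_a) & is.finite(events$heading_b)
  ev <- events[ok, , drop = FALSE]
  dh <- abs(ev$heading_a - ev$heading_b)
  dh <- pmin(dh, 360 - dh)
  out <- data.frame(event_row = which(ok), kind = ev$kind, bin_h = ev$bin_h,
                    lag_h = ev$lag_h, d_heading = dh,
                    d_speed = abs(ev$speed_a - ev$speed_b),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Kernel-density profile of a movement-difference parameter
#'
#' Gaussian KDE with Scott's-rule bandwidth. Direction profiles are
#' evaluated on \[0, 180\] degrees; speed profiles span the data range.
#' The sample size `n` is returned so plots can report the number of
#' intersecting PPA pairs behind each curve.
#'
#' @param values Numeric sample (heading or speed differences).
#' @param kind "direction" or "speed".
#' @param bw Bandwidth override; default `stats::bw.nrd` (Scott).
#' @param n_grid Grid size (default 512).
#' @return List `grid, density, n, bw` (`density` NULL when n < 2, with a
#'   `note`).
#' @export
kde_profile <- function(values, kind = c("direction", "speed"), bw = NULL,
                        n_grid = 512) {
  kind <- match.arg(kind)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2)
    return(list(grid = NULL, density = NULL, n = n, bw = NA_real_,
                note = "fewer than 2 values; no density estimated"))
  if (is.null(bw)) {
    bw <- if (stats::var(values) > 0) stats::bw.nrd(values)
          else max(abs(values[1]) * 0.01, 1e-6)  # degenerate spread
  }
  rng <- if (kind == "direction") c(0, 180)
         else range(values) + c(-3, 3) * bw
  d <- stats::density(values, bw = bw, from = rng[1], to = rng[2], n = n_grid)
  list(grid = d$x, density = d$y, n = n, bw = bw)
}

#' Quantitative signature (and advisory label) of interaction segments
#'
#' Summarises each traced segment by its mean heading difference, mean speed
#' difference, duration and lag, and optionally attaches a heuristic
#' behavioural label. The labels operationalise qualitative pattern
#' definitions — following (sustained concurrent movement with parallel
#' headings), encounter (short concurrent meeting), latency (delayed
#' response) — with configurable thresholds; they are advisory only, and the
#' unlabeled quantitative signature is always emitted.
#'
#' @param segments Concurrent `"interaction_segments"` (with `membership`
#'   attribute from [trace_segments()]).
#' @param descriptors Output of [describe_events()] on the same events.
#' @param sampling_interval_h Sampling interval (hours).
#' @param following_max_heading Mean heading-difference ceiling for
#'   "following" (degrees, default 45).
#' @param following_min_intervals Minimum duration for "following", in
#'   sampling intervals (default 3; shorter concurrent runs are
#'   "encounter").
#' @param label Attach heuristic labels (default TRUE).
#' @return Data frame `segment, duration_h, n_events, mean_d_heading,
#'   mean_d_speed, mean_lag_h, label`.
#' @export
segment_signature <- function(segments, descriptors, sampling_interval_h = 1,
                              following_max_heading = 45,
                              following_min_intervals = 3, label = TRUE) {
  mem <- attr(segments, "membership")
  out <- lapply(seq_len(nrow(segments)), function(s) {
    rows <- mem$event_row[mem$segment == segments$segment[s]]
    d <- descriptors[descriptors$event_row %in% rows, , drop = FALSE]
    data.frame(segment = segments$segment[s],
               duration_h = segments$duration_h[s],
               n_events = segments$n_events[s],
               mean_d_heading = if (nrow(d)) mean(d$d_heading) else NA_real_,
               mean_d_speed = if (nrow(d)) mean(d$d_speed) else NA_real_,
               mean_lag_h = if (nrow(d)) mean(d$lag_h) else NA_real_)
  })
  sig <- do.call(rbind, out)
  if (label) {
    long <- sig$duration_h >= following_min_intervals * sampling_interval_h
    parallel <- !is.na(sig$mean_d_heading) &
      sig$mean_d_heading < following_max_heading
    sig$label <- ifelse(long & parallel, "following",
                        ifelse(!long, "encounter", "unlabeled"))
    attr(sig, "heuristic") <- TRUE
  }
  sig
}

#' Flag candidate avoidance dyads
#'
#' Avoidance is a dyad-level, not segment-level, signature: dyads whose
#' concurrent-interaction frequency falls below a quantile of all dyads'
#' frequencies (while tracking overlapped) are flagged. Heuristic, advisory.
#'
#' @param dyad_table Data frame with a `n_concurrent_segments` column (one
#'   row per dyad), e.g. the edge table of [build_network()] including
#'   zero-frequency dyads.
#' @param quantile Frequency quantile below which a dyad is flagged
#'   (default 0.25).
#' @return Input with logical `avoidance_flag` column appended.
#' @export
flag_avoidance <- function(dyad_table, quantile = 0.25) {
  thr <- stats::quantile(dyad_table$n_concurrent_segments, quantile,
                         names = FALSE, type = 1)
  dyad_table$avoidance_flag <- dyad_table$n_concurrent_segments <= thr
  dyad_table
}
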