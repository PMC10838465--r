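# Interaction engine: intersecting PPA pairs across two individuals,
# concurrent/delayed classification by start-time lag, continuous-segment
# tracing, and calendar-month summaries.

#' Candidate PPA pairs by centroid distance and start-time lag
#'
#' Cheap exact pre-filter before the polygon intersection test. A pair
#' survives when the start-time difference is at most `max_lag_h` and the
#' centroid distance is at most `a_i + a_j`: two intersecting ellipses must
#' have centroid distance no larger than the sum of their semi-major axes,
#' so the returned set is a guaranteed superset of the truly intersecting
#' pairs.
#'
#' @param ppas_a,ppas_b `"ppa_set"` tables (typically gap-filtered).
#' @param max_lag_h Maximum |start-time difference| in hours (Inf disables).
#' @return Data frame `i, j, lag_h` of row indices into the two inputs.
#' @export
candidate_pairs <- function(ppas_a, ppas_b, max_lag_h = Inf) {
  na <- nrow(ppas_a); nb <- nrow(ppas_b)
  if (!na || !nb) return(data.frame(i = integer(0), j = integer(0), lag_h = numeric(0)))
  ta <- as.numeric(ppas_a$t_start)
  ord <- order(as.numeric(ppas_b$t_start))
  tb <- as.numeric(ppas_b$t_start)[ord]
  res_i <- vector("list", na)
  for (i in seq_len(na)) {
    if (is.finite(max_lag_h)) {
      lo <- findInterval(ta[i] - max_lag_h * 3600, tb, left.open = TRUE) + 1
      hi <- findInterval(ta[i] + max_lag_h * 3600, tb)
    } else {
      lo <- 1; hi <- nb
    }
    if (lo > hi) next
    j <- ord[lo:hi]
    d2 <- (ppas_b$cx[j] - ppas_a$cx[i])^2 + (ppas_b$cy[j] - ppas_a$cy[i])^2
    r <- ppas_a$a[i] + ppas_b$a[j] + 1e-9
    j <- j[d2 <= r^2]
    if (length(j))
      res_i[[i]] <- data.frame(i = i, j = j,
                               lag_h = abs(ta[i] - as.numeric(ppas_b$t_start)[j]) / 3600)
  }
  out <- do.call(rbind, res_i)
  if (is.null(out)) out <- data.frame(i = integer(0), j = integer(0), lag_h = numeric(0))
  rownames(out) <- NULL
  out
}

#' Do two PPA ellipses intersect?
#'
#' Exact test on the polygonal boundaries: the two regions overlap iff the
#' convex intersection polygon is non-empty. A shared boundary point counts
#' as intersecting. The overlap area is returned as a diagnostic.
#'
#' @param e1,e2 One-row `"ppa_set"` tables (or rows indexed from larger ones
#'   via `ppas[i, ]`).
#' @param vertices Boundary vertices per ellipse (default 100).
#' @return List `intersects` (logical), `area` (m^2).
#' @export
ellipse_intersects <- function(e1, e2, vertices = 100) {
  ellipse_overlap_xy(e1$cx[1], e1$cy[1], e1$a[1], e1$b[1], e1$theta[1],
                     e2$cx[1], e2$cy[1], e2$a[1], e2$b[1], e2$theta[1],
                     vertices)
}

#' Classify an intersection's start-time lag
#'
#' A lag at or below the concurrency threshold is a concurrent interaction;
#' anything longer is delayed and is assigned the largest lag bin whose
#' lower boundary does not exceed the lag (closed lower bound). A delayed
#' lag below the smallest bin gets bin NA.
#'
#' @param lag_h Lag(s) in hours, non-negative.
#' @param concurrent_threshold_h Concurrency threshold in hours (the data's
#'   sampling interval in the original application).
#' @param lag_bins_h Ascending lag-bin lower boundaries in hours
#'   (default 1 day, 1 week, 2 weeks, 3 weeks).
#' @return Data frame `kind` ("concurrent"/"delayed"), `bin_h`.
#' @export
classify_lag <- function(lag_h, concurrent_threshold_h = 1,
                         lag_bins_h = c(24, 168, 336, 504)) {
  if (concurrent_threshold_h < 0) stop("concurrent threshold must be >= 0")
  if (is.unsorted(lag_bins_h)) stop("lag_bins_h must be ascending")
  kind <- ifelse(lag_h <= concurrent_threshold_h + 1e-12, "concurrent", "delayed")
  bin <- rep(NA_real_, length(lag_h))
  del <- kind == "delayed"
  if (any(del)) {
    idx <- findInterval(lag_h[del] + 1e-12, lag_bins_h)
    bin[del] <- ifelse(idx >= 1, lag_bins_h[pmax(idx, 1)], NA_real_)
    bin[del][idx < 1] <- NA_real_
  }
  data.frame(kind = kind, bin_h = bin, stringsAsFactors = FALSE)
}

#' Intersection events between two individuals' PPAs
#'
#' Runs the candidate filter, the exact ellipse intersection test, and the
#' lag classification for one dyad. Each event carries the generating
#' segments' headings and speeds so movement-difference descriptors can be
#' attached later.
#'
#' @param ppas_a,ppas_b Gap-filtered `"ppa_set"` tables, one individual each.
#' @param concurrent_threshold_h Concurrency threshold (hours); default 1.
#' @param lag_bins_h Delayed lag-bin boundaries (hours).
#' @param max_lag_h Largest lag considered; default the top lag bin.
#' @param vertices Ellipse boundary vertices.
#' @param keep_area If TRUE (default) the intersection area is stored.
#' @return Data frame of class `"interaction_events"`, one row per
#'   spatially intersecting pair within the lag window.
#' @export
interaction_events <- function(ppas_a, ppas_b,
                               concurrent_threshold_h = 1,
                               lag_bins_h = c(24, 168, 336, 504),
                               max_lag_h = max(lag_bins_h),
                               vertices = 100, keep_area = TRUE) {
  cand <- candidate_pairs(ppas_a, ppas_b, max_lag_h)
  n <- nrow(cand)
  hit <- logical(n); area <- numeric(n)
  cxa <- ppas_a$cx; cya <- ppas_a$cy; aa <- ppas_a$a; ba <- ppas_a$b; tha <- ppas_a$theta
  cxb <- ppas_b$cx; cyb <- ppas_b$cy; ab <- ppas_b$a; bb <- ppas_b$b; thb <- ppas_b$theta
  for (k in seq_len(n)) {
    i <- cand$i[k]; j <- cand$j[k]
    r <- ellipse_overlap_xy(cxa[i], cya[i], aa[i], ba[i], tha[i],
                            cxb[j], cyb[j], ab[j], bb[j], thb[j], vertices)
    hit[k] <- r$intersects
    area[k] <- r$area
  }
  cand <- cand[hit, , drop = FALSE]
  area <- area[hit]
  i <- cand$i; j <- cand$j
  cls <- classify_lag(cand$lag_h, concurrent_threshold_h, lag_bins_h)
  ev <- data.frame(
    id_a = if (nrow(cand)) ppas_a$id[i] else character(0),
    id_b = if (nrow(cand)) ppas_b$id[j] else character(0),
    i = i, j = j,
    t_start_a = ppas_a$t_start[i], t_end_a = ppas_a$t_end[i],
    t_start_b = ppas_b$t_start[j], t_end_b = ppas_b$t_end[j],
    lag_h = cand$lag_h, kind = cls$kind, bin_h = cls$bin_h,
    who_first = ifelse(ppas_a$t_start[i] <= ppas_b$t_start[j], "a", "b"),
    area_m2 = if (keep_area) area else NA_real_,
    heading_a = ppas_a$heading_deg[i], heading_b = ppas_b$heading_deg[j],
    speed_a = ppas_a$speed_mh[i], speed_b = ppas_b$speed_mh[j],
    stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  class(ev) <- c("interaction_events", "data.frame")
  attr(ev, "concurrent_threshold_h") <- concurrent_threshold_h
  attr(ev, "lag_bins_h") <- lag_bins_h
  ev
}

#' Trace continuous interaction segments
#'
#' Partitions one dyad's events of one kind into maximal runs in which
#' consecutive events' time intervals (the union of both members' PPA
#' intervals) overlap or abut within one sampling interval. Segment
#' duration is the difference between the latest end and the earliest start
#' over the run.
#'
#' @param events An `"interaction_events"` table (will be subset to `kind`).
#' @param sampling_interval_h Sampling interval in hours; gaps up to this
#'   long still count as continuous.
#' @param kind "concurrent" (default) or "delayed".
#' @return Data frame of class `"interaction_segments"`: `segment, t_min,
#'   t_max, duration_h, n_events`; attribute `membership` maps each used
#'   event row to its segment.
#' @export
trace_segments <- function(events, sampling_interval_h = 1,
                           kind = "concurrent") {
  ev <- events[events$kind == kind, , drop = FALSE]
  empty <- data.frame(segment = integer(0), t_min = as.POSIXct(character(0), tz = "UTC"),
                      t_max = as.POSIXct(character(0), tz = "UTC"),
                      duration_h = numeric(0), n_events = integer(0))
  class(empty) <- c("interaction_segments", "data.frame")
  if (!nrow(ev)) return(empty)
  lo <- pmin(as.numeric(ev$t_start_a), as.numeric(ev$t_start_b))
  hi <- pmax(as.numeric(ev$t_end_a), as.numeric(ev$t_end_b))
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  seg <- integer(length(lo))
  cur <- 1L; cur_end <- hi[1]; seg[1] <- 1L
  tol <- sampling_interval_h * 3600 + 1e-6
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= cur_end + tol) {
      cur_end <- max(cur_end, hi[k])
    } else {
      cur <- cur + 1L
      cur_end <- hi[k]
    }
    seg[k] <- cur
  }
  out <- do.call(rbind, lapply(seq_len(cur), function(s) {
    sel <- seg == s
    data.frame(segment = s,
               t_min = as.POSIXct(min(lo[sel]), origin = "1970-01-01", tz = "UTC"),
               t_max = as.POSIXct(max(hi[sel]), origin = "1970-01-01", tz = "UTC"),
               duration_h = (max(hi[sel]) - min(lo[sel])) / 3600,
               n_events = sum(sel))
  }))
  rownames(out) <- NULL
  class(out) <- c("interaction_segments", "data.frame")
  membership <- integer(nrow(ev))
  membership[ord] <- seg
  attr(out, "membership") <- data.frame(event_row = which(events$kind == kind),
                                        segment = membership)
  out
}

# split an interval [t_min, t_max] (POSIXct) at calendar-month boundaries in
# tz; returns data.frame(month, hours)
split_by_month <- function(t_min, t_max, tz = "UTC") {
  if (t_max < t_min) stop("t_max < t_min")
  cuts <- as.numeric(t_min)
  cur <- as.POSIXlt(t_min, tz = tz)
  repeat {
    nxt <- cur
    nxt$mon <- nxt$mon + 1L
    nxt$mday <- 1L; nxt$hour <- 0L; nxt$min <- 0L; nxt$sec <- 0
    nxt <- as.POSIXlt(as.POSIXct(nxt), tz = tz)
    if (as.POSIXct(nxt) >= t_max) break
    cuts <- c(cuts, as.numeric(as.POSIXct(nxt)))
    cur <- nxt
  }
  cuts <- c(cuts, as.numeric(t_max))
  months <- format(as.POSIXct(cuts[-length(cuts)], origin = "1970-01-01", tz = "UTC"),
                   "%Y-%m", tz = tz)
  hours <- diff(cuts) / 3600
  agg <- tapply(hours, months, sum)
  data.frame(month = names(agg), hours = as.numeric(agg), stringsAsFactors = FALSE)
}

#' Monthly interaction summary for one dyad
#'
#' Concurrent interactions are summarised as a per-month segment count
#' (frequency, assigned to the month the segment starts in) and total
#' duration in hours, with a segment spanning a month boundary contributing
#' its duration split at the boundary. Delayed interactions are counted per
#' month and lag bin, either as all events or as the first event per
#' calendar day.
#'
#' @param segments Concurrent `"interaction_segments"`.
#' @param events `"interaction_events"` (both kinds).
#' @param tz Timezone defining calendar months.
#' @param delayed_counting "all" (default) or "first_per_day".
#' @return List with data frames `concurrent` (`month, frequency,
#'   duration_h`) and `delayed` (`month, bin_h, n`).
#' @export
monthly_summary <- function(segments, events, tz = "UTC",
                            delayed_counting = c("all", "first_per_day")) {
  delayed_counting <- match.arg(delayed_counting)
  if (nrow(segments)) {
    splits <- lapply(seq_len(nrow(segments)), function(k)
      split_by_month(segments$t_min[k], segments$t_max[k], tz))
    dur <- do.call(rbind, splits)
    dur <- stats::aggregate(hours ~ month, dur, sum)
    freq <- table(format(segments$t_min, "%Y-%m", tz = tz))
    conc <- merge(data.frame(month = names(freq), frequency = as.integer(freq),
                             stringsAsFactors = FALSE),
                  stats::setNames(dur, c("month", "duration_h")),
                  by = "month", all = TRUE)
    conc$frequency[is.na(conc$frequency)] <- 0L
    conc$duration_h[is.na(conc$duration_h)] <- 0
  } else {
    conc <- data.frame(month = character(0), frequency = integer(0),
                       duration_h = numeric(0), stringsAsFactors = FALSE)
  }
  del <- events[events$kind == "delayed", , drop = FALSE]
  if (nrow(del)) {
    # lags above the threshold but below the smallest bin: report as bin 0
    del$bin_h[is.na(del$bin_h)] <- 0
    tev <- pmin(del$t_start_a, del$t_start_b)
    if (delayed_counting == "first_per_day") {
      day <- format(tev, "%Y-%m-%d", tz = tz)
      keep <- !duplicated(data.frame(day, del$bin_h))
      del <- del[keep, , drop = FALSE]
      tev <- tev[keep]
    }
    tab <- stats::aggregate(list(n = rep(1L, nrow(del))),
                            by = list(month = format(tev, "%Y-%m", tz = tz),
                                      bin_h = del$bin_h), FUN = sum)
  } else {
    tab <- data.frame(month = character(0), bin_h = numeric(0), n = integer(0))
  }
  list(concurrent = conc, delayed = tab)
}
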