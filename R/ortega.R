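# Central analysis: from a track set to per-dyad interaction events,
# segments and monthly summaries, in one classed object.

#' Time-geographic interaction analysis of a track set
#'
#' Runs the full detection pipeline for every requested dyad: movement
#' segments, EWMA speed budgets, PPA ellipses, gap filtering, intersecting
#' PPA pairs with concurrent/delayed classification, continuous-segment
#' tracing, and monthly frequency/duration summaries.
#'
#' @param tracks A `"tracks"` object from [as_tracks()]/[read_tracks()].
#' @param dyads Data frame with columns `id_a`, `id_b`, or NULL (all
#'   unordered pairs).
#' @param ewma [ewma_params()] controlling the speed budget.
#' @param concurrent_threshold_h Start-time lag at or below which an
#'   intersection is concurrent; NULL (default) uses the mean sampling
#'   interval of the data, following the rule that ties concurrency to the
#'   temporal resolution.
#' @param lag_bins_h Delayed-interaction lag bins (hours); default 1 day,
#'   1, 2 and 3 weeks.
#' @param gap_k,gap_rule Gap-removal rule passed to [filter_gap_ppas()].
#' @param vertices Ellipse boundary vertices.
#' @param delayed_counting Passed to [monthly_summary()].
#' @return Object of class `"ortega"`: list with `tracks`, `ppas` (gap
#'   filtered), `dropped` (gap-removed PPA counts), `dyads` (named list
#'   `"A|B"` of `events`, `segments`, `monthly`), and `params`.
#' @seealso [summary.ortega()], [plot.ortega()], [build_network()]
#' @export
ortega <- function(tracks, dyads = NULL, ewma = ewma_params(),
                   concurrent_threshold_h = NULL,
                   lag_bins_h = c(24, 168, 336, 504),
                   gap_k = 3, gap_rule = "mean_plus_k_sd",
                   vertices = 100,
                   delayed_counting = "all") {
  stopifnot(inherits(tracks, "tracks"))
  ids <- track_ids(tracks)
  if (is.null(dyads)) {
    if (length(ids) < 2) stop("need at least two individuals")
    cmb <- utils::combn(sort(ids), 2)
    dyads <- data.frame(id_a = cmb[1, ], id_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  st <- tracks$stats
  interval_h <- mean(st$mean_dt_h)
  if (is.null(concurrent_threshold_h)) concurrent_threshold_h <- interval_h

  segs <- build_segments(tracks)
  ppas_all <- build_ppas(segs, ewma)
  ppas <- filter_gap_ppas(ppas_all, st, k = gap_k, rule = gap_rule)
  dropped <- attr(ppas, "dropped")

  res <- list()
  for (d in seq_len(nrow(dyads))) {
    a <- dyads$id_a[d]; b <- dyads$id_b[d]
    pa <- ppas[ppas$id == a, , drop = FALSE]
    pb <- ppas[ppas$id == b, , drop = FALSE]
    rownames(pa) <- rownames(pb) <- NULL
    class(pa) <- class(pb) <- c("ppa_set", "data.frame")
    ev <- interaction_events(pa, pb,
                             concurrent_threshold_h = concurrent_threshold_h,
                             lag_bins_h = lag_bins_h, vertices = vertices)
    seg <- trace_segments(ev, sampling_interval_h = interval_h,
                          kind = "concurrent")
    mon <- monthly_summary(seg, ev, tz = tracks$tz,
                           delayed_counting = delayed_counting)
    res[[paste(a, b, sep = "|")]] <-
      list(id_a = a, id_b = b, events = ev, segments = seg, monthly = mon)
  }
  structure(list(tracks = tracks, ppas = ppas, dropped = dropped,
                 dyads = res,
                 params = list(ewma = ewma,
                               concurrent_threshold_h = concurrent_threshold_h,
                               lag_bins_h = lag_bins_h, gap_k = gap_k,
                               gap_rule = gap_rule, vertices = vertices,
                               sampling_interval_h = interval_h)),
            class = "ortega")
}

#' @export
print.ortega <- function(x, ...) {
  cat(sprintf("Time-geographic interaction analysis: %d dyad(s), %d PPAs (%d gap-removed)\n",
              length(x$dyads), nrow(x$ppas), sum(x$dropped)))
  cat(sprintf("  concurrency threshold %.2f h; lag bins %s h\n",
              x$params$concurrent_threshold_h,
              paste(x$params$lag_bins_h, collapse = "/")))
  for (d in x$dyads) {
    nc <- sum(d$events$kind == "concurrent")
    nd <- sum(d$events$kind == "delayed")
    cat(sprintf("  %s-%s: %d concurrent event(s) in %d segment(s) (%.1f h total), %d delayed event(s)\n",
                d$id_a, d$id_b, nc, nrow(d$segments),
                sum(d$segments$duration_h), nd))
  }
  invisible(x)
}

#' Summarise an interaction analysis
#'
#' @param object An `"ortega"` object.
#' @param ... Unused.
#' @return Data frame, one row per dyad: event counts, segment count,
#'   total and median concurrent duration.
#' @export
summary.ortega <- function(object, ...) {
  out <- do.call(rbind, lapply(object$dyads, function(d) {
    data.frame(id_a = d$id_a, id_b = d$id_b,
               n_concurrent = sum(d$events$kind == "concurrent"),
               n_delayed = sum(d$events$kind == "delayed"),
               n_segments = nrow(d$segments),
               total_duration_h = sum(d$segments$duration_h),
               median_duration_h = if (nrow(d$segments))
                 stats::median(d$segments$duration_h) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot monthly concurrent interaction duration
#'
#' Barplot of the monthly concurrent duration for one dyad (base graphics).
#'
#' @param x An `"ortega"` object.
#' @param dyad Dyad key `"A|B"`; default the first.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ortega <- function(x, dyad = names(x$dyads)[1], ...) {
  d <- x$dyads[[dyad]]
  if (is.null(d)) stop(sprintf("unknown dyad: %s", dyad))
  m <- d$monthly$concurrent
  if (!nrow(m)) {
    graphics::plot.new()
    graphics::title(main = sprintf("%s: no concurrent interaction", dyad))
    return(invisible(x))
  }
  graphics::barplot(m$duration_h, names.arg = m$month, las = 2,
                    ylab = "concurrent duration (h)",
                    main = sprintf("Dyad %s", dyad), ...)
  invisible(x)
}

#' Extract concurrent segments of every dyad
#' @param fit An `"ortega"` object.
#' @return Named list `"A|B"` -> `"interaction_segments"`, as
#'   [build_network()] expects.
#' @export
dyad_segments <- function(fit) {
  stopifnot(inherits(fit, "ortega"))
  lapply(fit$dyads, function(d) d$segments)
}

# ---- orchestration -------------------------------------------------------

default_config <- function() {
  list(input = NULL, output_dir = "ortega_run",
       id_col = "id", time_col = "t", lon_col = "lon", lat_col = "lat",
       x_col = "x", y_col = "y", tz = "UTC",
       lambda = 0.5, n = 10, epsilon = 1.25,
       concurrent_threshold_h = NULL, lag_bins_h = c(24, 168, 336, 504),
       gap_k = 3, gap_rule = "mean_plus_k_sd", vertices = 100,
       hull_retain = 0.95,
       proximity_deltas_m = c(200, 500, 1000, 2000),
       proximity_taus_min = c(0, 30, 60),
       seed = 1)
}

resolve_config <- function(config) {
  cfg <- default_config()
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (k in names(config)) cfg[[k]] <- config[[k]]
  cfg
}

load_input_tracks <- function(cfg) {
  if (inherits(cfg$input, "tracks")) return(cfg$input)
  if (is.null(cfg$input)) stop("config has no `input` (path or tracks object)")
  read_tracks(cfg$input, id_col = cfg$id_col, time_col = cfg$time_col,
              lon_col = cfg$lon_col, lat_col = cfg$lat_col,
              x_col = cfg$x_col, y_col = cfg$y_col, tz = cfg$tz)
}

#' Run the end-to-end interaction analysis and write an output bundle
#'
#' Reads (or receives) tracks, runs [ortega()], home ranges, descriptors
#' and the network, and writes every table plus the resolved configuration
#' and a manifest under `output_dir`.
#'
#' @param config A list (or path to a JSON file) overriding the defaults:
#'   `input` (telemetry CSV path or a `"tracks"` object), `output_dir`,
#'   column names, `lambda`, `n`, `epsilon`, `concurrent_threshold_h`,
#'   `lag_bins_h`, `gap_k`, `gap_rule`, `vertices`, `hull_retain`, `seed`.
#' @return The `"ortega"` object, invisibly; side effect: files under
#'   `output_dir`.
#' @export
run_interaction <- function(config) {
  cfg <- resolve_config(config)
  set.seed(cfg$seed)
  tracks <- load_input_tracks(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  fit <- ortega(tracks,
                ewma = ewma_params(cfg$lambda, cfg$n, cfg$epsilon),
                concurrent_threshold_h = cfg$concurrent_threshold_h,
                lag_bins_h = cfg$lag_bins_h, gap_k = cfg$gap_k,
                gap_rule = cfg$gap_rule, vertices = cfg$vertices)

  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  write_tracks(tracks, file.path(cfg$output_dir, "tracks.csv"))
  paths <- c(paths, file.path(cfg$output_dir, "tracks.csv"))
  write_ppas(fit$ppas, file.path(cfg$output_dir, "ppas.csv"))
  paths <- c(paths, file.path(cfg$output_dir, "ppas.csv"))

  for (key in names(fit$dyads)) {
    d <- fit$dyads[[key]]
    tag <- gsub("|", "_", key, fixed = TRUE)
    ev <- d$events
    ev_out <- data.frame(dyad = key,
                         t_start_a = format(ev$t_start_a, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                         t_start_b = format(ev$t_start_b, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                         lag_h = ev$lag_h, kind = ev$kind, bin_h = ev$bin_h,
                         intersection_area_m2 = ev$area_m2,
                         who_first = ev$who_first, stringsAsFactors = FALSE)
    wr(ev_out, sprintf("events_%s.csv", tag))
    sg <- d$segments
    sg_out <- data.frame(dyad = key,
                         t_min = format(sg$t_min, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                         t_max = format(sg$t_max, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                         duration_h = sg$duration_h, n_events = sg$n_events,
                         stringsAsFactors = FALSE)
    wr(sg_out, sprintf("segments_%s.csv", tag))
    wr(d$monthly$concurrent, sprintf("monthly_concurrent_%s.csv", tag))
    wr(d$monthly$delayed, sprintf("monthly_delayed_%s.csv", tag))
    desc <- describe_events(ev)
    wr(desc, sprintf("descriptors_%s.csv", tag))
    if (nrow(sg))
      wr(segment_signature(sg, desc, fit$params$sampling_interval_h),
         sprintf("signatures_%s.csv", tag))
  }

  hr_rows <- list()
  for (i in track_ids(tracks)) {
    f <- track_of(tracks, i)
    hr <- tryCatch(hull95(f$x, f$y, f$t, cfg$hull_retain),
                   error = function(e) NULL)
    if (!is.null(hr))
      hr_rows[[i]] <- data.frame(id = i, area_km2 = hr$area_km2,
                                 n_used = hr$n_used, wkt = homerange_wkt(hr),
                                 stringsAsFactors = FALSE)
  }
  if (length(hr_rows)) wr(do.call(rbind, hr_rows), "homeranges.csv")

  net <- build_network(dyad_segments(fit), tracks)
  paths <- c(paths, export_network(net, cfg$output_dir))

  cfg_out <- cfg; cfg_out$input <- if (is.character(cfg$input)) cfg$input else "(in-memory tracks)"
  jsonlite::write_json(cfg_out, file.path(cfg$output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(sort(basename(c(paths, file.path(cfg$output_dir, "config.json")))),
             file.path(cfg$output_dir, "manifest.txt"))
  message(sprintf("run_interaction: wrote %d file(s) to %s",
                  length(paths) + 2, cfg$output_dir))
  invisible(fit)
}

#' Compare the time-geographic method with the proximity baseline
#'
#' For one dyad, computes interaction-duration distributions from the
#' time-geographic pipeline at each time window (used as the concurrency
#' threshold) and from the proximity baseline over the (buffer, window)
#' grid, and runs the Mann-Whitney test per grid cell against the matching
#' time-geographic distribution.
#'
#' @param config As [run_interaction()]; also uses `proximity_deltas_m`,
#'   `proximity_taus_min`, and optional `dyad = c(id_a, id_b)` (default:
#'   first two individuals).
#' @return List with `ortega_durations` (per window), `proximity` (sweep
#'   table), and `tests` (data frame of Mann-Whitney reports); written as
#'   CSV under `output_dir`, invisibly returned.
#' @export
run_compare <- function(config) {
  cfg <- resolve_config(config)
  set.seed(cfg$seed)
  tracks <- load_input_tracks(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- if (!is.null(cfg$dyad)) cfg$dyad else track_ids(tracks)[1:2]

  taus <- cfg$proximity_taus_min
  ortega_dur <- list()
  for (tau in taus) {
    fit <- ortega(tracks, dyads = data.frame(id_a = ids[1], id_b = ids[2]),
                  ewma = ewma_params(cfg$lambda, cfg$n, cfg$epsilon),
                  concurrent_threshold_h = tau / 60,
                  lag_bins_h = cfg$lag_bins_h, gap_k = cfg$gap_k,
                  gap_rule = cfg$gap_rule, vertices = cfg$vertices)
    ortega_dur[[as.character(tau)]] <- fit$dyads[[1]]$segments$duration_h
  }
  sweep <- proximity_sweep(tracks, ids[1], ids[2],
                           deltas_m = cfg$proximity_deltas_m,
                           taus_min = taus,
                           sampling_interval_h = mean(tracks$stats$mean_dt_h))
  tests <- list()
  for (tau in taus) for (delta in cfg$proximity_deltas_m) {
    pd <- sweep$duration_h[sweep$tau_min == tau & sweep$delta_m == delta &
                             !is.na(sweep$duration_h)]
    cmp <- compare_methods(ortega_dur[[as.character(tau)]], pd)
    tests[[length(tests) + 1]] <- data.frame(
      delta_m = delta, tau_min = tau,
      n_ortega = cmp$n_a, n_proximity = cmp$n_b,
      median_ortega_h = cmp$median_a, median_proximity_h = cmp$median_b,
      U = cmp$U, p_value = cmp$p_value,
      note = if (is.null(cmp$note)) "" else cmp$note,
      stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  od <- do.call(rbind, lapply(names(ortega_dur), function(tau)
    if (length(ortega_dur[[tau]]))
      data.frame(tau_min = as.numeric(tau), duration_h = ortega_dur[[tau]])
    else data.frame(tau_min = as.numeric(tau), duration_h = NA_real_)))
  utils::write.csv(od, file.path(cfg$output_dir, "compare_ortega_durations.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep, file.path(cfg$output_dir, "compare_proximity_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(tests, file.path(cfg$output_dir, "compare_tests.csv"),
                   row.names = FALSE)
  invisible(list(ortega_durations = ortega_dur, proximity = sweep,
                 tests = tests))
}
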