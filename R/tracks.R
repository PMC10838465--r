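# Telemetry ingestion: validation, projection, per-individual ordering,
# movement segments and sampling-interval statistics.

#' Build a track set from a telemetry data frame
#'
#' Validates and normalises raw telemetry into the canonical per-individual
#' representation used by every downstream step. Fixes are sorted in time
#' within each individual, exact-duplicate timestamps are collapsed to their
#' first occurrence, and geographic coordinates are projected to UTM metres.
#' Individuals with fewer than two fixes are dropped with a warning (no
#' movement segment can be formed for them).
#'
#' @param df Data frame with an id column, a timestamp column and either
#'   lon/lat (degrees) or x/y (metres) columns.
#' @param id_col,time_col,lon_col,lat_col,x_col,y_col Column names.
#' @param tz Timezone used for calendar (monthly) binning downstream.
#'   Timestamps themselves are parsed as UTC unless they carry an offset.
#' @param zone,hemisphere Optional UTM zone override; default from the data
#'   centroid.
#' @return An object of class `"tracks"`: list with `fixes` (data.frame
#'   `id, t, x, y, lon, lat`), `stats` (per-individual sampling-interval mean
#'   and population SD, hours), `crs`, and `tz`.
#' @export
as_tracks <- function(df, id_col = "id", time_col = "t",
                      lon_col = "lon", lat_col = "lat",
                      x_col = "x", y_col = "y",
                      tz = "UTC", zone = NULL, hemisphere = NULL) {
  if (!is.data.frame(df)) stop("`df` must be a data.frame")
  if (!all(c(id_col, time_col) %in% names(df)))
    stop(sprintf("missing required column(s): %s",
                 paste(setdiff(c(id_col, time_col), names(df)), collapse = ", ")))
  has_geo <- all(c(lon_col, lat_col) %in% names(df)) &&
    any(is.finite(suppressWarnings(as.numeric(df[[lon_col]]))))
  has_xy <- all(c(x_col, y_col) %in% names(df))
  if (!has_geo && !has_xy)
    stop(sprintf("need either %s/%s or %s/%s columns", lon_col, lat_col, x_col, y_col))

  id <- as.character(df[[id_col]])
  t <- df[[time_col]]
  if (!inherits(t, "POSIXct")) {
    s <- as.character(t)
    tt <- as.POSIXct(rep(NA_real_, length(s)), origin = "1970-01-01", tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      miss <- is.na(tt)
      if (!any(miss)) break
      tt[miss] <- as.POSIXct(strptime(s[miss], fmt, tz = "UTC"))
    }
    bad <- which(is.na(tt) & !is.na(t))
    if (length(bad))
      stop(sprintf("unparseable timestamp at row(s): %s",
                   paste(utils::head(bad, 5), collapse = ", ")))
    t <- tt
  } else {
    attr(t, "tzone") <- "UTC"
  }
  if (any(is.na(t))) stop(sprintf("missing timestamp at row(s): %s",
                                  paste(utils::head(which(is.na(t)), 5), collapse = ", ")))

  if (has_geo) {
    lon <- as.numeric(df[[lon_col]]); lat <- as.numeric(df[[lat_col]])
    prj <- project_utm(lon, lat, zone = zone, hemisphere = hemisphere)
    x <- prj$x; y <- prj$y
    crs <- list(type = "utm", zone = prj$zone, hemisphere = prj$hemisphere)
  } else {
    x <- as.numeric(df[[x_col]]); y <- as.numeric(df[[y_col]])
    lon <- if (lon_col %in% names(df)) as.numeric(df[[lon_col]]) else rep(NA_real_, length(x))
    lat <- if (lat_col %in% names(df)) as.numeric(df[[lat_col]]) else rep(NA_real_, length(x))
    crs <- list(type = "planar", zone = NA_integer_, hemisphere = NA_character_)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite coordinates")

  fixes <- data.frame(id = id, t = t, x = x, y = y, lon = lon, lat = lat,
                      stringsAsFactors = FALSE)
  fixes <- fixes[order(fixes$id, fixes$t), , drop = FALSE]
  dup <- duplicated(fixes[, c("id", "t")])   # keep first occurrence
  fixes <- fixes[!dup, , drop = FALSE]

  n_per <- table(fixes$id)
  short <- names(n_per)[n_per < 2]
  if (length(short)) {
    warning(sprintf("dropping individual(s) with < 2 fixes: %s",
                    paste(short, collapse = ", ")))
    fixes <- fixes[!fixes$id %in% short, , drop = FALSE]
  }
  if (!nrow(fixes)) stop("no individual has >= 2 fixes")
  rownames(fixes) <- NULL

  tr <- structure(list(fixes = fixes, stats = NULL, crs = crs, tz = tz),
                  class = "tracks")
  tr$stats <- interval_stats(tr)
  tr
}

#' Read telemetry from a delimited text file
#'
#' @inheritParams as_tracks
#' @param path CSV/TSV path; timestamps ISO-8601.
#' @param sep Field separator (default comma).
#' @return A [as_tracks()] `"tracks"` object.
#' @export
read_tracks <- function(path, id_col = "id", time_col = "t",
                        lon_col = "lon", lat_col = "lat",
                        x_col = "x", y_col = "y",
                        tz = "UTC", sep = ",", zone = NULL, hemisphere = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_tracks(df, id_col = id_col, time_col = time_col,
            lon_col = lon_col, lat_col = lat_col, x_col = x_col, y_col = y_col,
            tz = tz, zone = zone, hemisphere = hemisphere)
}

#' Write a track set to the canonical telemetry CSV
#'
#' Columns `id, t, x, y, lon, lat`; timestamps ISO-8601 UTC to the second,
#' coordinates with enough digits to round-trip below 1e-6 m.
#'
#' @param tracks A `"tracks"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "tracks"))
  f <- tracks$fixes
  out <- data.frame(
    id = f$id,
    t = format(f$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = sprintf("%.8f", f$x),
    y = sprintf("%.8f", f$y),
    lon = ifelse(is.na(f$lon), "", sprintf("%.10f", f$lon)),
    lat = ifelse(is.na(f$lat), "", sprintf("%.10f", f$lat)),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.tracks <- function(x, ...) {
  s <- x$stats
  cat(sprintf("Track set: %d individual(s), %d fixes\n",
              nrow(s), nrow(x$fixes)))
  cat(sprintf("  CRS: %s%s\n", x$crs$type,
              if (identical(x$crs$type, "utm"))
                sprintf(" zone %d%s", x$crs$zone, x$crs$hemisphere) else ""))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %d fixes, interval %.2f h (sd %.2f)\n",
                s$id[i], s$n[i], s$mean_dt_h[i], s$sd_dt_h[i]))
  invisible(x)
}

#' Individual IDs present in a track set
#' @param tracks A `"tracks"` object.
#' @return Character vector of IDs.
#' @export
track_ids <- function(tracks) unique(tracks$fixes$id)

#' Fixes of one individual
#' @param tracks A `"tracks"` object.
#' @param id Individual ID.
#' @return Data frame of that individual's fixes, time-ordered.
#' @export
track_of <- function(tracks, id) {
  f <- tracks$fixes[tracks$fixes$id == id, , drop = FALSE]
  if (!nrow(f)) stop(sprintf("unknown individual: %s", id))
  rownames(f) <- NULL
  f
}

#' Sampling-interval statistics per individual
#'
#' Arithmetic mean and population standard deviation of the consecutive-fix
#' intervals, in hours. Recompute after any filtering of fixes.
#'
#' @param tracks A `"tracks"` object (or a single individual's fix data frame).
#' @return Data frame `id, n, mean_dt_h, sd_dt_h`.
#' @export
interval_stats <- function(tracks) {
  fixes <- if (inherits(tracks, "tracks")) tracks$fixes else tracks
  ids <- unique(fixes$id)
  out <- lapply(ids, function(i) {
    t <- fixes$t[fixes$id == i]
    if (length(t) < 2) stop(sprintf("individual %s has < 2 fixes", i))
    dt <- diff(as.numeric(t)) / 3600
    m <- mean(dt)
    s <- sqrt(mean((dt - m)^2))   # population SD
    data.frame(id = i, n = length(t), mean_dt_h = m, sd_dt_h = s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Movement segments between consecutive fixes
#'
#' One segment per consecutive fix pair of each individual, with duration,
#' Euclidean step length, speed and heading. Heading is degrees clockwise
#' from north in \[0, 360); it is undefined (NA, `heading_defined = FALSE`)
#' for zero-displacement segments, whose speed is 0.
#'
#' @param tracks A `"tracks"` object.
#' @param id Optional single individual; default all.
#' @return Data frame `id, seg, t0, t1, x0, y0, x1, y1, dt_h, dist_m,
#'   speed_mh, heading_deg, heading_defined`.
#' @export
build_segments <- function(tracks, id = NULL) {
  stopifnot(inherits(tracks, "tracks"))
  ids <- if (is.null(id)) track_ids(tracks) else id
  out <- lapply(ids, function(i) {
    f <- track_of(tracks, i)
    n <- nrow(f)
    if (n < 2) stop(sprintf("individual %s has < 2 fixes", i))
    j <- seq_len(n - 1)
    dt <- (as.numeric(f$t[j + 1]) - as.numeric(f$t[j])) / 3600
    dx <- f$x[j + 1] - f$x[j]
    dy <- f$y[j + 1] - f$y[j]
    dist <- sqrt(dx^2 + dy^2)
    hd <- (atan2(dx, dy) * 180 / pi) %% 360
    defined <- dist > 0
    hd[!defined] <- NA_real_
    data.frame(id = i, seg = j, t0 = f$t[j], t1 = f$t[j + 1],
               x0 = f$x[j], y0 = f$y[j], x1 = f$x[j + 1], y1 = f$y[j + 1],
               dt_h = dt, dist_m = dist, speed_mh = dist / dt,
               heading_deg = hd, heading_defined = defined,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
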