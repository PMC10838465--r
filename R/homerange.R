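# Home ranges as 95% convex hulls, with areas and dyadic overlap.

#' Percentage convex hull home range
#'
#' Trims the `floor((1 - retain) * n)` points farthest (Euclidean) from the
#' mean centre, then takes the convex hull of the remainder — the standard
#' "95% convex hull" activity-space estimator. Ties on trimming distance
#' retain the earlier timestamp.
#'
#' @param x,y Planar coordinates in metres.
#' @param t Optional timestamps (used only to break trimming ties).
#' @param retain Fraction of points to keep (default 0.95).
#' @return Object of class `"homerange"`: list with `polygon` (CCW vertex
#'   matrix, metres), `area_km2`, `n_used`, `n_dropped`, `center`.
#' @export
hull95 <- function(x, y, t = NULL, retain = 0.95) {
  stopifnot(length(x) == length(y), retain > 0, retain <= 1)
  n <- length(x)
  n_drop <- floor((1 - retain) * n)
  if (is.null(t)) t <- seq_len(n)
  ctr <- c(mean(x), mean(y))
  d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  keep_idx <- order(d, as.numeric(t))[seq_len(n - n_drop)]
  xk <- x[keep_idx]; yk <- y[keep_idx]
  if (length(xk) < 3) stop("fewer than 3 points after trimming")
  hull <- convex_hull(xk, yk)
  if (nrow(hull) < 3 || polygon_area(hull) == 0)
    stop("degenerate geometry: points are collinear")
  structure(list(polygon = hull,
                 area_km2 = polygon_area(hull) / 1e6,
                 n_used = length(xk), n_dropped = n_drop,
                 center = ctr),
            class = "homerange")
}

#' @export
print.homerange <- function(x, ...) {
  cat(sprintf("Home range: %.3f km^2 hull of %d points (%d trimmed)\n",
              x$area_km2, x$n_used, x$n_dropped))
  invisible(x)
}

#' Directed home-range overlap proportion
#'
#' For a dyad (x, y), the overlapped area of x and y divided by the area of
#' y's home range — note the asymmetry: the result is the fraction of y's
#' range shared with x.
#'
#' @param hx,hy `"homerange"` objects.
#' @return Fraction in \[0, 1\], or NA (with a warning) if `hy` has zero area.
#' @export
overlap_proportion <- function(hx, hy) {
  stopifnot(inherits(hx, "homerange"), inherits(hy, "homerange"))
  ay <- polygon_area(hy$polygon)
  if (ay <= 0) {
    warning("reference home range has zero area; overlap undefined")
    return(NA_real_)
  }
  min(convex_overlap_area(hx$polygon, hy$polygon) / ay, 1)
}

#' Home ranges over time windows
#'
#' Computes [hull95()] per calendar month (default) or per user-specified
#' window; windows with too few usable points are skipped and reported.
#'
#' @param tracks A `"tracks"` object.
#' @param id Individual.
#' @param windows `"month"`, or a data frame with POSIXct `start`, `end`
#'   columns and an optional `label`.
#' @param retain Hull retain fraction.
#' @param min_points Minimum points required in a window (default 10).
#' @return List with `ranges` (named list of `"homerange"`), `table`
#'   (window, area_km2, n_used) and `skipped` (labels of skipped windows).
#' @export
windowed_ranges <- function(tracks, id, windows = "month", retain = 0.95,
                            min_points = 10) {
  f <- track_of(tracks, id)
  tz <- tracks$tz
  if (identical(windows, "month")) {
    lab <- format(f$t, "%Y-%m", tz = tz)
    groups <- split(seq_len(nrow(f)), lab)
  } else {
    stopifnot(is.data.frame(windows), all(c("start", "end") %in% names(windows)))
    lbl <- if ("label" %in% names(windows)) windows$label
           else paste(windows$start, windows$end, sep = "/")
    groups <- lapply(seq_len(nrow(windows)), function(w)
      which(f$t >= windows$start[w] & f$t < windows$end[w]))
    names(groups) <- lbl
  }
  ranges <- list(); skipped <- character(0)
  for (w in names(groups)) {
    idx <- groups[[w]]
    if (length(idx) < max(min_points, 3)) { skipped <- c(skipped, w); next }
    hr <- tryCatch(hull95(f$x[idx], f$y[idx], f$t[idx], retain),
                   error = function(e) NULL)
    if (is.null(hr)) { skipped <- c(skipped, w); next }
    ranges[[w]] <- hr
  }
  tab <- if (length(ranges))
    data.frame(window = names(ranges),
               area_km2 = vapply(ranges, function(h) h$area_km2, numeric(1)),
               n_used = vapply(ranges, function(h) h$n_used, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(window = character(0), area_km2 = numeric(0), n_used = numeric(0))
  list(ranges = ranges, table = tab, skipped = skipped)
}

#' Export a home-range polygon as WKT
#' @param hr A `"homerange"`.
#' @return WKT POLYGON string.
#' @export
homerange_wkt <- function(hr) {
  p <- rbind(hr$polygon, hr$polygon[1, , drop = FALSE])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.3f %.3f", p[, 1], p[, 2]), collapse = ", "))
}
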