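# Exact convex geometry: ellipse discretization, shoelace area,
# Sutherland-Hodgman clipping, point-in-convex-polygon. Every shape the
# method manipulates (PPA ellipse, convex hull) is convex, so clipping is
# exact up to the ellipse discretization.

#' Polygonal approximation of an ellipse
#'
#' Vertices at `n` equal parametric angles, counter-clockwise, major axis
#' rotated by `theta` radians from the x axis.
#'
#' @param cx,cy Centre.
#' @param a,b Semi-major and semi-minor axes (same length unit as centre).
#' @param theta Major-axis orientation, radians counter-clockwise from +x.
#' @param n Number of vertices (default 100).
#' @return `n` x 2 numeric matrix.
#' @export
ellipse_polygon <- function(cx, cy, a, b, theta = 0, n = 100) {
  stopifnot(n >= 3, a >= 0, b >= 0)
  u <- unit_circle(n)
  ct <- cos(theta); st <- sin(theta)
  ex <- a * u[, 1]; ey <- b * u[, 2]
  cbind(cx + ex * ct - ey * st, cy + ex * st + ey * ct)
}

# cached unit-circle templates so repeated ellipse discretization is cheap
.unit_circle_cache <- new.env(parent = emptyenv())
unit_circle <- function(n) {
  key <- as.character(n)
  u <- .unit_circle_cache[[key]]
  if (is.null(u)) {
    tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    u <- cbind(cos(tt), sin(tt))
    .unit_circle_cache[[key]] <- u
  }
  u
}

# scalar-argument ellipse-overlap kernel used by the event loop: avoids any
# data.frame indexing on the hot path
ellipse_overlap_xy <- function(cx1, cy1, a1, b1, t1,
                               cx2, cy2, a2, b2, t2, n = 100) {
  if (sqrt((cx2 - cx1)^2 + (cy2 - cy1)^2) > a1 + a2 + 1e-9)
    return(list(intersects = FALSE, area = 0))
  p1 <- ellipse_polygon(cx1, cy1, a1, max(b1, 1e-6), t1, n)
  p2 <- ellipse_polygon(cx2, cy2, a2, max(b2, 1e-6), t2, n)
  ov <- clip_convex(p1, p2)
  list(intersects = nrow(ov) >= 3, area = polygon_area(ov))
}

#' Polygon area by the shoelace formula
#' @param p N x 2 vertex matrix (any consistent orientation).
#' @return Non-negative area.
#' @export
polygon_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# signed area: > 0 for counter-clockwise vertex order
signed_area <- function(p) {
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

ensure_ccw <- function(p) if (signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p

#' Clip one convex polygon by another (Sutherland-Hodgman)
#'
#' Exact intersection of two convex polygons. Both inputs may be in either
#' orientation; they are normalised to counter-clockwise internally.
#'
#' @param subject,clip N x 2 vertex matrices of convex polygons.
#' @return Vertex matrix of the intersection polygon (0 rows if disjoint).
#' @export
clip_convex <- function(subject, clip) {
  out <- ensure_ccw(subject)
  cl <- ensure_ccw(clip)
  nc <- nrow(cl)
  for (i in seq_len(nc)) {
    if (is.null(nrow(out)) || nrow(out) == 0) break
    a <- cl[i, ]
    b <- cl[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # cross((b-a),(p-a)): >= 0 means p on the inside (left) of a CCW edge
    s <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1], 1L)
    in1 <- s >= 0
    in2 <- in1[nxt]
    crossing <- xor(in1, in2)
    sel_v <- which(in1)
    sel_c <- which(crossing)
    if (length(sel_c)) {
      tpar <- s[sel_c] / (s[sel_c] - s[nxt][sel_c])
      ix <- out[sel_c, 1] + tpar * (out[nxt, 1][sel_c] - out[sel_c, 1])
      iy <- out[sel_c, 2] + tpar * (out[nxt, 2][sel_c] - out[sel_c, 2])
    } else {
      ix <- iy <- numeric(0)
    }
    # vertex k precedes the crossing on edge (k, k+1)
    keys <- c(2 * sel_v - 1, 2 * sel_c)
    pts <- rbind(out[sel_v, , drop = FALSE], cbind(ix, iy))
    out <- pts[order(keys), , drop = FALSE]
  }
  if (is.null(nrow(out))) out <- matrix(numeric(0), ncol = 2)
  dimnames(out) <- NULL
  out
}

#' Area of intersection of two convex polygons
#' @param p1,p2 Vertex matrices.
#' @return Non-negative overlap area.
#' @export
convex_overlap_area <- function(p1, p2) polygon_area(clip_convex(p1, p2))

#' Test whether a point lies in a convex polygon
#'
#' @param px,py Point coordinates (vectors allowed).
#' @param poly Vertex matrix (convex).
#' @param tol Boundary tolerance in coordinate units (points within `tol`
#'   outside an edge still count as inside).
#' @return Logical vector.
#' @export
point_in_convex <- function(px, py, poly, tol = 1e-9) {
  p <- ensure_ccw(poly)
  n <- nrow(p)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ex <- p[j, 1] - p[i, 1]; ey <- p[j, 2] - p[i, 2]
    s <- ex * (py - p[i, 2]) - ey * (px - p[i, 1])
    inside <- inside & (s >= -tol * sqrt(ex^2 + ey^2))
  }
  inside
}

#' Convex hull of a point set, counter-clockwise
#' @param x,y Coordinates.
#' @return Vertex matrix in counter-clockwise order.
#' @export
convex_hull <- function(x, y) {
  idx <- grDevices::chull(x, y)       # returns clockwise order
  ensure_ccw(cbind(x[idx], y[idx]))
}
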