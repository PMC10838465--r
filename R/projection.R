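# WGS84 transverse Mercator (UTM) forward projection.
# Series formulas accurate to well under a metre anywhere inside a zone,
# which is far below GPS collar error.

.WGS84 <- list(a = 6378137, f = 1 / 298.257223563)

#' UTM zone number for a longitude
#'
#' @param lon Longitude in decimal degrees.
#' @return Integer zone in 1..60.
#' @export
utm_zone <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1L), 60L))
}

#' Project geographic coordinates to UTM metres
#'
#' Forward transverse Mercator on the WGS84 ellipsoid with the standard UTM
#' scale factor 0.9996 and false easting 500 km (false northing 10,000 km in
#' the southern hemisphere). The zone defaults to that of the centroid of the
#' input so that one consistent planar frame covers the whole data set, as
#' Euclidean PPA geometry requires.
#'
#' @param lon,lat Numeric vectors of decimal degrees.
#' @param zone UTM zone; default the zone of the mean longitude.
#' @param hemisphere "N" or "S"; default from the mean latitude.
#' @return List with numeric vectors `x`, `y` (metres) and the `zone` and
#'   `hemisphere` used.
#' @export
project_utm <- function(lon, lat, zone = NULL, hemisphere = NULL) {
  stopifnot(length(lon) == length(lat))
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite lon/lat")
  if (any(abs(lat) > 84)) stop("latitude outside UTM domain (|lat| > 84)")
  if (is.null(zone)) zone <- utm_zone(mean(lon))
  if (is.null(hemisphere)) hemisphere <- if (mean(lat) >= 0) "N" else "S"

  a <- .WGS84$a; f <- .WGS84$f
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lam0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180

  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
    (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
    (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
    (35 * e2^3 / 3072) * sin(6 * phi))

  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
    (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
    (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
    (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (hemisphere == "S") y <- y + 1e7

  list(x = x, y = y, zone = zone, hemisphere = hemisphere)
}
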