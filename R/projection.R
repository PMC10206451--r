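# WGS84 transverse-Mercator (UTM) projection, Snyder-series form.
# Implemented here because all downstream distances are Euclidean metres
# on a planar grid and the fix tables may arrive in geographic lon/lat.

.WGS84 <- list(a = 6378137, f = 1 / 298.257223563, k0 = 0.9996)

#' Projection specification
#'
#' Coordinates are analysed on a planar metre grid. Fix tables may be
#' supplied either already planar (`crs_planar()`) or in geographic
#' WGS84 lon/lat, in which case they are projected to a UTM zone
#' (`crs_utm()`). A spec can also be given as a string: `"planar"` or
#' `"utm:15N"`.
#'
#' @param zone UTM zone number (1-60).
#' @param north `TRUE` for the northern hemisphere.
#' @return an object of class `fw_crs`.
#' @export
crs_utm <- function(zone, north = TRUE) {
  assert_that(is.numeric(zone) && zone >= 1 && zone <= 60,
              "UTM zone must be between 1 and 60", "fishwolf_config_error")
  structure(list(type = "utm", zone = as.integer(zone), north = isTRUE(north)),
            class = "fw_crs")
}

#' @rdname crs_utm
#' @export
crs_planar <- function() structure(list(type = "planar"), class = "fw_crs")

#' @rdname crs_utm
#' @param x string or `fw_crs` object.
#' @export
as_fw_crs <- function(x) {
  if (inherits(x, "fw_crs")) return(x)
  assert_that(is.character(x) && length(x) == 1,
              "projection spec must be an fw_crs or a string like 'utm:15N' or 'planar'",
              "fishwolf_config_error")
  if (identical(tolower(x), "planar")) return(crs_planar())
  m <- regmatches(x, regexec("^utm:([0-9]{1,2})([NnSs])$", x))[[1]]
  assert_that(length(m) == 3,
              sprintf("unknown projection spec '%s' (use 'planar' or 'utm:<zone><N|S>')", x),
              "fishwolf_config_error")
  crs_utm(as.integer(m[[2]]), toupper(m[[3]]) == "N")
}

# meridian arc length from the equator
.merid_arc <- function(phi, a, e2) {
  e4 <- e2^2; e6 <- e2^3
  a * ((1 - e2 / 4 - 3 * e4 / 64 - 5 * e6 / 256) * phi -
       (3 * e2 / 8 + 3 * e4 / 32 + 45 * e6 / 1024) * sin(2 * phi) +
       (15 * e4 / 256 + 45 * e6 / 1024) * sin(4 * phi) -
       (35 * e6 / 3072) * sin(6 * phi))
}

#' Project WGS84 lon/lat to UTM metres
#'
#' @param lon,lat numeric vectors of geographic coordinates (degrees).
#' @param crs an `fw_crs` of type `"utm"`.
#' @return a two-column matrix `x` (easting) / `y` (northing) in metres.
#' @export
project_lonlat <- function(lon, lat, crs) {
  crs <- as_fw_crs(crs)
  assert_that(crs$type == "utm", "projection target must be a UTM spec",
              "fishwolf_config_error")
  assert_that(all(is.finite(lon)) && all(is.finite(lat)) &&
              all(abs(lat) <= 90) && all(abs(lon) <= 360),
              "lon/lat out of range or non-finite", "fishwolf_config_error")
  a <- .WGS84$a; f <- .WGS84$f; k0 <- .WGS84$k0
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  lon0 <- (-183 + 6 * crs$zone) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- cos(phi) * (lam - lon0)
  M <- .merid_arc(phi, a, e2)
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                 (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 5e5
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
             (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (!crs$north) y <- y + 1e7
  cbind(x = x, y = y)
}

#' Inverse-project UTM metres to WGS84 lon/lat
#'
#' @param x,y easting/northing in metres.
#' @inheritParams project_lonlat
#' @return a two-column matrix `lon` / `lat` in degrees.
#' @export
unproject_xy <- function(x, y, crs) {
  crs <- as_fw_crs(crs)
  assert_that(crs$type == "utm", "projection source must be a UTM spec",
              "fishwolf_config_error")
  a <- .WGS84$a; f <- .WGS84$f; k0 <- .WGS84$k0
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  lon0 <- (-183 + 6 * crs$zone) * pi / 180
  xs <- x - 5e5
  ys <- if (crs$north) y else y - 1e7
  M <- ys / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  C1 <- ep2 * cos(phi1)^2
  T1 <- tan(phi1)^2
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- xs / (N1 * k0)
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
     (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- lon0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
                 (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}
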