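#' Solar elevation angle
#'
#' Geometric solar elevation (no atmospheric refraction) from time and
#' position, using the NOAA low-precision solar ephemeris (accurate to a
#' small fraction of a degree, ample for diel classification).
#'
#' @param time `POSIXct` (UTC) times.
#' @param lat,lon position in decimal degrees.
#' @return elevation above the horizon, degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct")
  if (any(is.na(lat)) || any(is.na(lon)) || any(is.na(time)))
    stop("missing time or position (metadata error)")
  rad <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  T  <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M  <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e  <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  C  <- sin(M * rad) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
        sin(2 * M * rad) * (0.019993 - 0.000101 * T) +
        sin(3 * M * rad) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * rad)
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps  <- eps0 + 0.00256 * cos(omega * rad)
  decl <- asin(sin(eps * rad) * sin(lambda * rad)) / rad
  y <- tan(eps * rad / 2)^2
  eqtime <- 4 / rad * (y * sin(2 * L0 * rad) - 2 * e * sin(M * rad) +
    4 * e * y * sin(M * rad) * cos(2 * L0 * rad) -
    0.5 * y^2 * sin(4 * L0 * rad) - 1.25 * e^2 * sin(2 * M * rad))
  mins_utc <- (as.numeric(time) %% 86400) / 60
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  elev <- asin(sin(lat * rad) * sin(decl * rad) +
               cos(lat * rad) * cos(decl * rad) * cos(ha * rad)) / rad
  elev
}

#' Classify pings into day, night or twilight
#'
#' Twilight pings must be removed before estimating the epipelagic boundary:
#' during dusk and dawn the mesopelagic community migrates through the upper
#' limit of the OMZ and the 98% cumulative-backscatter depth is undefined.
#' Twilight is delimited by solar-elevation bands: day when the sun is above
#' `day_min_elev` (default 0 degrees, the horizon), night when below
#' `night_max_elev` (default -12 degrees, nautical twilight), twilight in
#' between.
#'
#' @param time,lat,lon ping time (UTC `POSIXct`) and position.
#' @param day_min_elev,night_max_elev band limits, degrees.
#' @return character vector in `c("day", "night", "twilight")`.
#' @export
classify_diel <- function(time, lat, lon, day_min_elev = 0,
                          night_max_elev = -12) {
  elev <- solar_elevation(time, lat, lon)
  out <- rep("twilight", length(elev))
  out[elev > day_min_elev] <- "day"
  out[elev < night_max_elev] <- "night"
  out
}

#' Assign diel labels to every ping of an echogram
#'
#' @param e an [echogram] or [bifrequency] object.
#' @param ... passed to [classify_diel()].
#' @return the object with `pings$diel` filled in.
#' @export
assign_diel <- function(e, ...) {
  if (inherits(e, "bifrequency")) {
    e$e38 <- assign_diel(e$e38, ...)
    e$e120 <- assign_diel(e$e120, ...)
    return(e)
  }
  stopifnot(inherits(e, "echogram"))
  e$pings$diel <- classify_diel(e$pings$time, e$pings$lat, e$pings$lon, ...)
  e
}
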