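#' Dissolved-oxygen profile
#'
#' A depth-ordered set of dissolved-oxygen samples from either a continuous
#' CTD-O2 cast (typical sensor precision 0.03 mL L^-1) or discrete Niskin
#' bottles with Winkler titration (precision 0.1 mL L^-1, standard levels
#' 0, 10, 25, 50, 75, 100 and 150 m).
#'
#' @param depth_m sample depths, metres, strictly increasing, >= 2 levels.
#' @param do_ml_l dissolved oxygen, mL L^-1, >= 0.
#' @param station_id station identifier.
#' @param lat,lon,time station position and time (optional but needed for
#'   matching against acoustic pings).
#' @param source `"ctdo_continuous"` or `"niskin_discrete"`.
#' @param zone `"inshore"`, `"offshore"` or `NA` (an input label; the
#'   inshore/offshore split is supplied, not computed).
#' @param diel `"day"`, `"night"` or `NA`.
#' @return an object of class `"do_profile"`.
#' @export
do_profile <- function(depth_m, do_ml_l, station_id = "S1",
                       lat = NA_real_, lon = NA_real_,
                       time = as.POSIXct(NA),
                       source = c("ctdo_continuous", "niskin_discrete"),
                       zone = NA_character_, diel = NA_character_) {
  source <- match.arg(source)
  if (length(depth_m) < 2) stop("a profile needs at least 2 levels")
  if (length(do_ml_l) != length(depth_m))
    stop("depth and DO vectors must have equal length")
  if (any(diff(depth_m) <= 0)) stop("depths must be strictly increasing")
  if (any(do_ml_l < 0, na.rm = TRUE)) stop("DO concentrations must be >= 0")
  structure(list(station_id = station_id, lat = lat, lon = lon, time = time,
                 depth_m = as.numeric(depth_m), do_ml_l = as.numeric(do_ml_l),
                 source = source, zone = zone, diel = diel,
                 precision_ml_l = if (source == "ctdo_continuous") 0.03 else 0.1),
            class = "do_profile")
}

#' @export
print.do_profile <- function(x, ...) {
  cat(sprintf("<do_profile> %s (%s), %d levels %.0f-%.0f m, DO %.2f-%.2f mL/L\n",
              x$station_id, x$source, length(x$depth_m), min(x$depth_m),
              max(x$depth_m), min(x$do_ml_l), max(x$do_ml_l)))
  invisible(x)
}

#' Depth of a dissolved-oxygen isovalue
#'
#' Depth of the first (shallowest) downward crossing of `iso` (default
#' 0.8 mL L^-1, the validated acoustic-boundary proxy), linearly
#' interpolated between the bracketing samples.  A profile that never
#' crosses the isovalue -- e.g. a cast that does not reach the base of the
#' oxycline -- yields `NA`.
#'
#' @param p a [do_profile].
#' @param iso isovalue, mL L^-1.
#' @return depth, metres, or `NA` when the profile never crosses.
#' @export
z_isovalue <- function(p, iso = 0.8) {
  stopifnot(inherits(p, "do_profile"))
  d <- p$depth_m; o <- p$do_ml_l
  n <- length(d)
  for (i in seq_len(n)) {
    if (!is.na(o[i]) && o[i] == iso) return(d[i])
    if (i < n && !is.na(o[i]) && !is.na(o[i + 1]) &&
        o[i] > iso && o[i + 1] < iso) {
      return(d[i] + (d[i + 1] - d[i]) * (o[i] - iso) / (o[i] - o[i + 1]))
    }
  }
  NA_real_
}

#' Vertical dissolved-oxygen gradient profile
#'
#' The profile is linearly interpolated onto a uniform grid (default 1 m)
#' and differentiated with centred differences (one-sided at the ends).
#' Depth is positive downward, so oxycline gradients are negative.
#'
#' @param p a [do_profile].
#' @param grid_step grid spacing, metres.
#' @return data frame of class `"do_gradient"`: `depth_m`, `do_ml_l`
#'   (interpolated), `gradient` (mL L^-1 m^-1).
#' @export
vertical_gradient <- function(p, grid_step = 1) {
  stopifnot(inherits(p, "do_profile"), grid_step > 0)
  grid <- seq(min(p$depth_m), max(p$depth_m), by = grid_step)
  if (length(grid) < 2)
    grid <- c(min(p$depth_m), max(p$depth_m))
  doi <- stats::approx(p$depth_m, p$do_ml_l, xout = grid, ties = mean)$y
  g <- pracma::gradient(doi, grid)
  out <- data.frame(depth_m = grid, do_ml_l = doi, gradient = g)
  class(out) <- c("do_gradient", "data.frame")
  out
}

#' Convert an oxygen quantity from umol/kg to mL/L
#'
#' Bookkeeping conversion used to express gradient criteria in sensor
#' units: `value [umol kg^-1] x density [kg L^-1] x molar volume
#' [L mol^-1] x 1e-3` gives mL L^-1 (the same factor applies per metre for
#' gradients).  With the nominal seawater density 1.025 kg L^-1 and the
#' real-gas molar volume of O2 (22.392 L mol^-1), -0.9 umol kg^-1 m^-1
#' maps to about -0.02 mL L^-1 m^-1.
#'
#' @param value quantity in umol kg^-1 (per metre, for a gradient).
#' @param density seawater density, kg L^-1.
#' @param molar_volume molar volume of O2, L mol^-1.
#' @return the value in mL L^-1 (per metre).
#' @export
convert_o2_units <- function(value, density = 1.025, molar_volume = 22.392) {
  if (density <= 0) stop("density must be > 0")
  value * density * molar_volume * 1e-3
}

#' Oxycline features of a dissolved-oxygen profile
#'
#' Extracts the oxycline structure.  The oxycline splits at the depth of
#' the most negative DO gradient (`z_max_grad`).  The base of the lower
#' oxycline (`z_bot_oxy`, the top of the OMZ) is the deeper of two
#' criteria: (A) the shallowest depth where DO drops below `omz_conc`
#' (default 0.5 mL L^-1), and (B) the deepest depth where the vertical
#' gradient is weaker (more negative) than `grad_crit` (default
#' -0.02 mL L^-1 m^-1, i.e. -0.9 umol kg^-1 m^-1).  The lower oxycline is
#' the interval `[z_max_grad, z_bot_oxy]`.  A profile that satisfies
#' neither criterion (e.g. one that does not reach the oxycline base)
#' returns partial features with `z_bot_oxy = NA`.
#'
#' @param p a [do_profile].
#' @param iso isovalue for `z_iso`, mL L^-1.
#' @param omz_conc OMZ concentration criterion, mL L^-1.
#' @param grad_crit gradient criterion, mL L^-1 m^-1 (negative).
#' @param grid_step gradient grid spacing, metres.
#' @return an object of class `"oxycline_features"`: `z_iso`, `z_max_grad`,
#'   `z_bot_oxy`, `lower_oxycline` (length-2 interval or `NA`s).
#' @export
oxycline_features <- function(p, iso = 0.8, omz_conc = 0.5,
                              grad_crit = -0.02, grid_step = 1) {
  g <- vertical_gradient(p, grid_step)
  z_max_grad <- g$depth_m[which.min(g$gradient)]
  zA <- z_isovalue(p, omz_conc)
  below <- g$depth_m[!is.na(g$gradient) & g$gradient <= grad_crit]
  zB <- if (length(below)) max(below) else NA_real_
  z_bot <- if (is.na(zA) && is.na(zB)) NA_real_ else max(zA, zB, na.rm = TRUE)
  structure(list(station_id = p$station_id,
                 z_iso = z_isovalue(p, iso),
                 z_max_grad = z_max_grad,
                 z_bot_oxy = z_bot,
                 lower_oxycline = c(z_max_grad, z_bot)),
            class = "oxycline_features")
}

#' @export
print.oxycline_features <- function(x, ...) {
  cat(sprintf("<oxycline_features> %s: z_iso %.1f m, max-gradient %.1f m, bottom oxycline %s\n",
              x$station_id, x$z_iso, x$z_max_grad,
              if (is.na(x$z_bot_oxy)) "undefined" else sprintf("%.1f m", x$z_bot_oxy)))
  invisible(x)
}

#' Read and write dissolved-oxygen profiles (long CSV)
#'
#' Long format, one row per sample: `station_id`, `time_iso`, `lat`, `lon`,
#' `source`, `zone`, `depth_m`, `do_ml_l`.
#'
#' @param profiles list of [do_profile] objects.
#' @param path CSV file.
#' @return `read_do_profiles`: a list of [do_profile]; `write_do_profiles`:
#'   invisibly, `path`.
#' @export
write_do_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(station_id = p$station_id,
               time_iso = if (is.na(p$time)) "" else .time_iso(p$time),
               lat = p$lat, lon = p$lon, source = p$source,
               zone = ifelse(is.na(p$zone), "", p$zone),
               depth_m = p$depth_m, do_ml_l = p$do_ml_l)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_do_profiles
#' @export
read_do_profiles <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(station_id = "character",
                                              time_iso = "character"))
  lapply(split(tab, factor(tab$station_id, levels = unique(tab$station_id))),
         function(d) {
           d <- d[order(d$depth_m), ]
           do_profile(d$depth_m, d$do_ml_l, station_id = d$station_id[1],
                      lat = d$lat[1], lon = d$lon[1],
                      time = if (nzchar(d$time_iso[1]))
                        as.POSIXct(d$time_iso[1],
                                   format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
                      else as.POSIXct(NA),
                      source = d$source[1],
                      zone = if (!is.na(d$zone[1]) && nzchar(d$zone[1]))
                        d$zone[1] else NA_character_)
         })
}

#' Write oxycline features to CSV
#'
#' @param features list of [oxycline_features()] results.
#' @param path CSV file.
#' @return invisibly, `path`.
#' @export
write_oxycline_features <- function(features, path) {
  rows <- do.call(rbind, lapply(features, function(f)
    data.frame(station_id = f$station_id, z_iso = f$z_iso,
               z_max_grad = f$z_max_grad, z_bot_oxy = f$z_bot_oxy)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
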