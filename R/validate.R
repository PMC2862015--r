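#' Match an acoustic boundary series to an oceanographic station
#'
#' The acoustic boundary exhibits submesoscale variability (internal waves
#' can displace it by tens of metres over ~100 m horizontally), so a
#' station comparison averages the boundary depth over the closest
#' `min_pings` pings (default 300) recorded within `max_radius_km`
#' (default 5 km) of the station.  Stations with fewer valid pings in
#' range are excluded -- an analysis result, not an error.  When the probe
#' track is visible on the echogram, the exact crossing depth can be
#' supplied via `exact_z` instead of the ping average.
#'
#' @param z a [zveec_series()].
#' @param station a [do_profile] with position metadata.
#' @param min_pings pings required and averaged.
#' @param max_radius_km search radius, km (great-circle, spherical Earth of
#'   radius 6371 km).
#' @param exact_z optional exact boundary depth at the station (visible
#'   probe-track mode); overrides the ping average.
#' @return an object of class `"station_match"`: `station_id`,
#'   `z_veec_mean`, `n_pings` (pings averaged), `n_within` (valid pings in
#'   range), `included`, `visible_track`, `do_at_zveec`.
#' @export
match_station <- function(z, station, min_pings = 300, max_radius_km = 5,
                          exact_z = NULL) {
  stopifnot(inherits(z, "zveec_series"), inherits(station, "do_profile"))
  if (is.na(station$lat) || is.na(station$lon))
    stop("station must be georeferenced")
  ok <- z$valid & !is.na(z$z_veec_m)
  dist <- .gc_km(z$lon[ok], z$lat[ok], station$lon, station$lat)
  within <- dist <= max_radius_km
  n_within <- sum(within)
  visible <- !is.null(exact_z)
  if (visible) {
    zm <- exact_z; included <- TRUE; n_used <- 0L
  } else if (n_within >= min_pings) {
    ord <- order(dist[within])
    zm <- mean(z$z_veec_m[ok][within][ord][seq_len(min_pings)])
    included <- TRUE; n_used <- as.integer(min_pings)
  } else {
    zm <- NA_real_; included <- FALSE; n_used <- 0L
  }
  structure(list(station_id = station$station_id, z_veec_mean = zm,
                 n_pings = n_used, n_within = n_within,
                 max_radius_km = max_radius_km, included = included,
                 visible_track = visible,
                 do_at_zveec = if (included) do_at_zveec(station, zm)
                               else NA_real_),
            class = "station_match")
}

#' @export
print.station_match <- function(x, ...) {
  cat(sprintf("<station_match> %s: %s (valid pings within %g km: %d)\n",
              x$station_id,
              if (x$included) sprintf("Z_VEEC %.1f m, DO %.2f mL/L",
                                      x$z_veec_mean, x$do_at_zveec)
              else "excluded", x$max_radius_km, x$n_within))
  invisible(x)
}

#' Match every station of a survey
#'
#' @param z a [zveec_series()].
#' @param stations list of [do_profile] objects.
#' @param ... passed to [match_station()].
#' @return data frame with one row per station: `station_id`, `included`,
#'   `z_veec_mean`, `n_within`, `do_at_zveec`, `z_iso` (the 0.8 mL L^-1
#'   isovalue depth), `z_bot_oxy`, `source`, `zone`, `diel`.
#' @export
match_stations <- function(z, stations, ...) {
  rows <- lapply(stations, function(s) {
    m <- match_station(z, s, ...)
    f <- oxycline_features(s)
    data.frame(station_id = s$station_id, included = m$included,
               z_veec_mean = m$z_veec_mean, n_within = m$n_within,
               do_at_zveec = m$do_at_zveec, z_iso = f$z_iso,
               z_bot_oxy = f$z_bot_oxy, source = s$source,
               zone = ifelse(is.na(s$zone), NA_character_, s$zone),
               diel = ifelse(is.na(s$diel), NA_character_, s$diel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dissolved oxygen at a given depth
#'
#' Linear interpolation of the profile at depth `z`; `NA` when `z` lies
#' outside the sampled depth range.
#'
#' @param station a [do_profile].
#' @param z depth, metres.
#' @return DO concentration, mL L^-1, or `NA`.
#' @export
do_at_zveec <- function(station, z) {
  stopifnot(inherits(station, "do_profile"))
  if (is.na(z) || z < min(station$depth_m) || z > max(station$depth_m))
    return(NA_real_)
  stats::approx(station$depth_m, station$do_ml_l, xout = z, ties = mean)$y
}

#' Ordinary least-squares regression summary
#'
#' Classical OLS of `y` on `x` with the slope F statistic, its two-sided
#' p-value and R^2 -- the summary shape used to validate the acoustic
#' boundary against DO-derived depths.
#'
#' @param x,y numeric vectors, finite, `n >= 3`; `x` must have nonzero
#'   variance.
#' @return an object of class `"regression_result"`: `slope`, `intercept`,
#'   `n`, `F`, `p`, `r_squared`.
#' @export
ols_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::var(x) == 0) stop("zero variance in x (degenerate error)")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  Fst <- unname(s$fstatistic)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(x), F = Fst[1],
                 p = stats::pf(Fst[1], Fst[2], Fst[3], lower.tail = FALSE),
                 r_squared = s$r.squared),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> slope %.3f, intercept %.3f, n %d, F %.2f, p %.3g, R2 %.3f\n",
              x$slope, x$intercept, x$n, x$F, x$p, x$r_squared))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA of `values` across `groups` (used for the
#' day/night and inshore/offshore effect tests on DO at the boundary).
#'
#' @param values numeric observations.
#' @param groups group labels, at least two distinct, each nonempty.
#' @return list `F`, `p`, `df` (numerator, denominator degrees of freedom).
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tabulate(groups) == 0)) stop("every group must be nonempty")
  if (length(values) - nlevels(groups) < 1)
    stop("no residual degrees of freedom (degenerate error)")
  a <- stats::anova(stats::lm(values ~ groups))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       df = c(a$Df[1], a$Df[2]))
}

#' Cellwise difference between two gridded depth fields
#'
#' Differences a DO-derived depth grid and an acoustic depth grid on a
#' common grid and summarises the valid differences (mean and box-plot
#' quartiles), as used to compare interpolated maps of the upper OMZ.
#'
#' @param z_iso_grid,z_veec_grid [depth_grid] objects (or plain matrices)
#'   on identical grids; the difference is `z_iso - z_veec`.
#' @return list `grid` (a [depth_grid] of differences, or matrix),
#'   `summary` (named vector: mean, q1, median, q3).
#' @export
difference_map <- function(z_iso_grid, z_veec_grid) {
  get_z <- function(g) if (inherits(g, "depth_grid")) g$z else as.matrix(g)
  z1 <- get_z(z_iso_grid); z2 <- get_z(z_veec_grid)
  if (!identical(dim(z1), dim(z2)))
    stop("grids must be identical (alignment error)")
  if (inherits(z_iso_grid, "depth_grid") &&
      inherits(z_veec_grid, "depth_grid") &&
      (!isTRUE(all.equal(z_iso_grid$lon, z_veec_grid$lon)) ||
       !isTRUE(all.equal(z_iso_grid$lat, z_veec_grid$lat))))
    stop("grids must share lon/lat axes (alignment error)")
  d <- z1 - z2
  v <- d[is.finite(d)]
  out_grid <- if (inherits(z_iso_grid, "depth_grid")) {
    g <- z_iso_grid; g$z <- d; g$valid <- is.finite(d); g
  } else d
  list(grid = out_grid,
       summary = c(mean = mean(v), q1 = unname(stats::quantile(v, 0.25)),
                   median = stats::median(v),
                   q3 = unname(stats::quantile(v, 0.75))))
}

#' Write matched pairs and regression summaries to CSV
#'
#' @param matches data frame from [match_stations()].
#' @param regressions named list of [ols_regression()] results, one row per
#'   case in the output (columns: case, y, x, slope, intercept, n, F, p,
#'   r_squared).
#' @param path CSV file.
#' @return invisibly, `path`.
#' @export
write_regression_summary <- function(regressions, path,
                                     y = "Z_VEEC", x = "Z_0.8") {
  rows <- do.call(rbind, lapply(names(regressions), function(nm) {
    r <- regressions[[nm]]
    data.frame(case = nm, y = y, x = x, slope = r$slope,
               intercept = r$intercept, n = r$n, F = r$F, p = r$p,
               r_squared = r$r_squared)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_regression_summary
#' @export
write_matched_pairs <- function(matches, path) {
  utils::write.csv(matches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
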