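#' Specification of a synthetic coastal survey scene
#'
#' Describes a bi-frequency survey with known ground truth, emulating an
#' eastern-boundary upwelling transect: an oxycline depth field Z*(x) made
#' of a large-scale trend plus mesoscale/submesoscale sinusoidal
#' undulations (and an optional Gaussian filament ridge); a zooplankton
#' scattering layer above Z* with an organism accumulation just above the
#' layer base and a sharp (~2 m) taper below it; fish schools that
#' backscatter ~35 dB above the zooplankton and slightly more at 38 than
#' 120 kHz; an optional night-time mesopelagic layer merged into the
#' epipelagic band; range-dependent background noise; and dissolved-oxygen
#' profiles whose 0.8 mL L^-1 isoline lies exactly at Z*.
#'
#' Defaults describe the reference scene used throughout the package's
#' checks: 5000 pings at 1 ping s^-1 and 10 knots, oxycline trending from
#' 20 to 120 m with 15 km / 5 m and 3 km / 1.5 m undulations, a 4 m
#' per-ping layer-base jitter (internal waves and patchiness), zooplankton
#' at -85/-75 dB (38/120 kHz), fish schools at -50 dB, and 96 stations.
#'
#' @param n_pings number of pings.
#' @param ping_rate_hz pings per second.
#' @param speed_knots vessel speed.
#' @param start_time first ping time (UTC); the default is local daytime at
#'   the default position.
#' @param lat0,lon0,heading_deg transect start and constant heading.
#' @param transducer_depth_m,max_depth_m,native_bin_m vertical sampling:
#'   transducer immersion, deepest sample, native sample height.
#' @param z_range oxycline trend endpoints `c(start, end)`, m.
#' @param undulations list of `list(wavelength_km, amplitude_m)` sinusoids.
#' @param filament optional `list(centre_km, width_km, amplitude_m)`
#'   Gaussian shoaling ridge.
#' @param zveec_noise_sd_m sd of the per-ping layer-base jitter, m.
#' @param layer_top_m top of the scattering layer, m below surface.
#' @param zoo_sv38,zoo_sv120 mean zooplankton Sv, dB.
#' @param speckle_db sd of the lognormal cell speckle, dB.
#' @param accumulation_factor,accumulation_width_m relative density excess
#'   and e-folding width of the organism accumulation above the layer base.
#' @param taper_m width of the layer-base cut-off, m.
#' @param n_schools,school_sv38,school_diff_db,school_half_pings,school_half_m,school_depth_frac
#'   fish-school count, 38 kHz Sv, `Sv120 - Sv38` range (<= 0), ellipse
#'   half-axes (pings, m) and depth placement as a fraction of the local
#'   layer base.
#' @param mesopelagic `"none"` or `"night_merged"` (migrators merged into
#'   the epipelagic band during night pings).
#' @param meso_factor relative density added above the base at night.
#' @param deep_scatterer add sparse strong non-fish scatterers below the
#'   layer (the condition under which a 99% threshold becomes erratic).
#' @param deep_prob,deep_frac,deep_offset_m per-ping probability, linear
#'   energy fraction range and depth-below-base range of the deep blobs.
#' @param noise_on render range-dependent background noise.
#' @param alpha38,alpha120,offset38,offset120 noise-model parameters per
#'   frequency (dB m^-1 absorption; dB offset at 1 m).
#' @param do_surface,do_floor,do_scale_m logistic DO profile family:
#'   surface and OMZ-core concentrations (mL L^-1) and transition scale (m).
#' @param n_stations number of DO stations along the track.
#' @param seed RNG seed; generation is bitwise-deterministic given the spec.
#' @return an object of class `"scene_spec"`.
#' @export
scene_spec <- function(n_pings = 5000, ping_rate_hz = 1, speed_knots = 10,
                       start_time = as.POSIXct("2008-02-10 16:30:00",
                                               tz = "UTC"),
                       lat0 = -8, lon0 = -79.5, heading_deg = 270,
                       transducer_depth_m = 3.4, max_depth_m = 150,
                       native_bin_m = 0.25,
                       z_range = c(20, 120),
                       undulations = list(list(wavelength_km = 15,
                                               amplitude_m = 5),
                                          list(wavelength_km = 3,
                                               amplitude_m = 1.5)),
                       filament = NULL,
                       zveec_noise_sd_m = 4,
                       layer_top_m = 5, zoo_sv38 = -85, zoo_sv120 = -75,
                       speckle_db = 3,
                       accumulation_factor = 8, accumulation_width_m = 3,
                       taper_m = 2,
                       n_schools = 8, school_sv38 = -50,
                       school_diff_db = c(-3, 0),
                       school_half_pings = 15, school_half_m = 4,
                       school_depth_frac = c(0.25, 0.75),
                       mesopelagic = c("none", "night_merged"),
                       meso_factor = 1,
                       deep_scatterer = FALSE, deep_prob = 0.5,
                       deep_frac = c(0.005, 0.018),
                       deep_offset_m = c(15, 35),
                       noise_on = TRUE,
                       alpha38 = 0.0098, alpha120 = 0.0267,
                       offset38 = -145, offset120 = -140,
                       do_surface = 5, do_floor = 0.3, do_scale_m = 5,
                       n_stations = 96, seed = 42) {
  mesopelagic <- match.arg(mesopelagic)
  spec <- as.list(environment())
  if (diff(range(spec$school_diff_db)) < 0 || max(spec$school_diff_db) > 0)
    stop("fish must have Sv120 - Sv38 <= 0 dB (spec error)")
  if (max(z_range) > max_depth_m - 10)
    stop("oxycline must stay within the sampled depth range (spec error)")
  structure(spec, class = "scene_spec")
}

# track geometry and the deterministic oxycline field Z*(x)
.scene_track <- function(spec) {
  np <- spec$n_pings
  step_m <- spec$speed_knots * 1852 / 3600 / spec$ping_rate_hz
  x_km <- (seq_len(np) - 1) * step_m / 1000
  pos <- geosphere::destPoint(c(spec$lon0, spec$lat0), spec$heading_deg,
                              x_km * 1000, r = 6371000)
  time <- spec$start_time + (seq_len(np) - 1) / spec$ping_rate_hz
  z <- spec$z_range[1] +
    (spec$z_range[2] - spec$z_range[1]) * x_km / max(x_km[np], 1e-9)
  for (u in spec$undulations)
    z <- z + u$amplitude_m * sin(2 * pi * x_km / u$wavelength_km)
  if (!is.null(spec$filament))
    z <- z - spec$filament$amplitude_m *
      exp(-((x_km - spec$filament$centre_km) / spec$filament$width_km)^2)
  z <- pmin(pmax(z, spec$layer_top_m + 5), spec$max_depth_m - 10)
  list(x_km = x_km, lon = pos[, 1], lat = pos[, 2], time = time, z_star = z)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# logistic DO family with Z_0.8 anchored at z08
.logistic_do <- function(z, z08, spec) {
  A <- spec$do_surface - spec$do_floor
  p <- (0.8 - spec$do_floor) / A
  mu <- z08 - spec$do_scale_m * log(1 / p - 1)
  spec$do_floor + A / (1 + exp((z - mu) / spec$do_scale_m))
}

#' Generate a synthetic bi-frequency survey with ground truth
#'
#' Renders the scene described by a [scene_spec()]: per-cell zooplankton
#' occupancy above the jittered layer base (with accumulation and taper),
#' elliptical fish schools with a shared-across-frequency speckle so their
#' dB difference stays in the fish band, optional night mesopelagic
#' density, optional sparse deep scatterers with a zooplankton-like
#' frequency response, lognormal speckle, and an additive range-dependent
#' noise field.  Output is deterministic for a given spec (seeded, RNG
#' state restored afterwards).
#'
#' @param spec a [scene_spec()].
#' @return list with elements
#'   \describe{
#'     \item{echograms}{a [bifrequency] pair at native resolution, diel
#'       labels assigned;}
#'     \item{stations}{list of [do_profile] (continuous CTD-O2 casts);}
#'     \item{truth}{list: `pings` data frame (`index`, `x_km`, `z_star`,
#'       `layer_base`), `fish_mask` (native-grid logical matrix),
#'       `stations` data frame (`station_id`, `x_km`, `z08`);}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(spec$seed, {
    tr <- .scene_track(spec)
    np <- spec$n_pings
    nb <- floor((spec$max_depth_m - spec$transducer_depth_m) /
                  spec$native_bin_m)
    ranges <- (seq_len(nb) - 0.5) * spec$native_bin_m
    zc <- spec$transducer_depth_m + ranges
    base <- tr$z_star + stats::rnorm(np, 0, spec$zveec_noise_sd_m)
    base <- pmin(pmax(base, spec$layer_top_m + 3), max(zc) - 5)
    diel <- classify_diel(tr$time, tr$lat, tr$lon)

    rel <- outer(base, zc, `-`)               # > 0 above the layer base
    A <- spec$accumulation_factor; aw <- spec$accumulation_width_m
    # accumulation hugs the base from above; below it only a thin tail of
    # stragglers at background density, cut off over taper_m
    occ <- ifelse(rel >= 0, 1 + A * exp(-rel / aw),
                  pmax(0, 1 + rel / spec$taper_m))
    occ[, zc < spec$layer_top_m] <- 0
    if (spec$mesopelagic == "night_merged" && any(diel == "night")) {
      # at night the migratory community shares the vertical range of the
      # resident epipelagic community: a density multiplier on the profile
      occ[diel == "night", ] <- (1 + spec$meso_factor) *
        occ[diel == "night", ]
    }

    sp38 <- matrix(stats::rnorm(np * nb, 0, spec$speckle_db), np, nb)
    sp120 <- matrix(stats::rnorm(np * nb, 0, spec$speckle_db), np, nb)
    lin38 <- occ * 10^((spec$zoo_sv38 + sp38) / 10)
    lin120 <- occ * 10^((spec$zoo_sv120 + sp120) / 10)
    zoo120_sum <- rowSums(lin120)       # fish-free column energy at 120 kHz

    fish_mask <- matrix(FALSE, np, nb)
    if (spec$n_schools > 0 && np > 2 * spec$school_half_pings + 2) {
      pc <- round(stats::runif(spec$n_schools, 1 + spec$school_half_pings,
                               np - spec$school_half_pings))
      dfrac <- stats::runif(spec$n_schools, spec$school_depth_frac[1],
                            spec$school_depth_frac[2])
      delta <- stats::runif(spec$n_schools, spec$school_diff_db[1],
                            spec$school_diff_db[2])
      for (k in seq_len(spec$n_schools)) {
        dc <- max(spec$layer_top_m + spec$school_half_m + 1,
                  dfrac[k] * base[pc[k]])
        prng <- max(1, pc[k] - spec$school_half_pings):
                min(np, pc[k] + spec$school_half_pings)
        inside <- outer(((prng - pc[k]) / spec$school_half_pings)^2,
                        ((zc - dc) / spec$school_half_m)^2, `+`) <= 1
        if (!any(inside)) next
        spf <- matrix(stats::rnorm(length(inside), 0, spec$speckle_db),
                      nrow(inside))
        add38 <- 10^((spec$school_sv38 + spf) / 10) * inside
        lin38[prng, ] <- lin38[prng, ] + add38
        lin120[prng, ] <- lin120[prng, ] + add38 * 10^(delta[k] / 10)
        fish_mask[prng, ] <- fish_mask[prng, ] | inside
      }
    }

    if (spec$deep_scatterer) {
      hit <- stats::runif(np) < spec$deep_prob
      zd <- base + stats::runif(np, spec$deep_offset_m[1],
                                spec$deep_offset_m[2])
      fr <- stats::runif(np, spec$deep_frac[1], spec$deep_frac[2])
      for (i in which(hit)) {
        jd <- which(zc >= zd[i] & zc < zd[i] + 1.5)
        if (!length(jd) || max(zd[i]) > max(zc) - 2) next
        # fraction is relative to the zooplankton column: fish cells are
        # excluded from the cumulation channel downstream
        blob120 <- fr[i] / (1 - fr[i]) * zoo120_sum[i]
        lin120[i, jd] <- lin120[i, jd] + blob120 / length(jd)
        # zooplankton-like response: 10 dB weaker at 38 kHz
        lin38[i, jd] <- lin38[i, jd] + blob120 / length(jd) / 10
      }
    }

    if (spec$noise_on) {
      n38 <- 10^(noise_field(ranges, suppressWarnings(
        noise_model(spec$alpha38, spec$offset38))) / 10)
      n120 <- 10^(noise_field(ranges, suppressWarnings(
        noise_model(spec$alpha120, spec$offset120))) / 10)
      lin38 <- sweep(lin38, 2, n38, `+`)
      lin120 <- sweep(lin120, 2, n120, `+`)
    }

    pings <- data.frame(index = seq_len(np) - 1L, time = tr$time,
                        lat = tr$lat, lon = tr$lon, diel = diel)
    mk <- function(lin, f) echogram(linear_to_db(lin),
                                    c(0, ranges + spec$native_bin_m / 2) +
                                      spec$transducer_depth_m,
                                    frequency = f, pings = pings,
                                    transducer_depth = spec$transducer_depth_m)
    b <- bifrequency(mk(lin38, 38), mk(lin120, 120))

    st_idx <- round(seq(1, np, length.out = spec$n_stations))
    stations <- generate_stations(spec, spec$n_stations, niskin = FALSE)
    truth <- list(
      pings = data.frame(index = pings$index, x_km = tr$x_km,
                         z_star = tr$z_star, layer_base = base),
      fish_mask = fish_mask,
      stations = data.frame(station_id = vapply(stations, `[[`, "",
                                                "station_id"),
                            x_km = tr$x_km[st_idx],
                            z08 = tr$z_star[st_idx]))
    list(echograms = b, stations = stations, truth = truth, spec = spec)
  })
}

#' Generate dissolved-oxygen stations along the scene track
#'
#' Stations are evenly spaced along the track; each samples the logistic
#' DO profile anchored so that its 0.8 mL L^-1 isoline sits exactly at the
#' local (smooth) oxycline field Z*.  Continuous casts sample every metre
#' from the surface to `max_depth_m`; discrete Niskin casts sample the
#' standard bottle levels 0, 10, 25, 50, 75, 100, 150 m, which degrades
#' the precision of the interpolated isoline depth.
#'
#' @param spec a [scene_spec()].
#' @param n number of stations (>= 1).
#' @param niskin discrete bottle sampling instead of a continuous cast.
#' @return list of [do_profile] objects with increasing station ids.
#' @export
generate_stations <- function(spec, n = spec$n_stations, niskin = FALSE) {
  stopifnot(inherits(spec, "scene_spec"), n >= 1)
  tr <- .scene_track(spec)
  idx <- round(seq(1, spec$n_pings, length.out = n))
  depths <- if (niskin) c(0, 10, 25, 50, 75, 100, 150)
            else seq(0, spec$max_depth_m, by = 1)
  depths <- depths[depths <= spec$max_depth_m]
  x_half <- max(tr$x_km) / 2
  lapply(seq_len(n), function(i) {
    k <- idx[i]
    do_profile(depths, .logistic_do(depths, tr$z_star[k], spec),
               station_id = sprintf("ST%03d", i),
               lat = tr$lat[k], lon = tr$lon[k], time = tr$time[k],
               source = if (niskin) "niskin_discrete" else "ctdo_continuous",
               zone = if (tr$x_km[k] > x_half) "offshore" else "inshore",
               diel = classify_diel(tr$time[k], tr$lat[k], tr$lon[k]))
  })
}

#' Coarsen a native-grid cell mask to a resampled grid
#'
#' Maps a logical ping x native-bin mask (e.g. the generator's ground-truth
#' fish mask) onto the elementary-cell grid produced by
#' [resample_echogram()]: an output cell is flagged when any (`rule =
#' "any"`) or most (`rule = "majority"`) of its member native bins are.
#'
#' @param mask logical matrix on the native grid.
#' @param native_edges native depth edges (below surface), m.
#' @param cell_height output cell height, m.
#' @param rule `"any"` or `"majority"`.
#' @return logical matrix on the resampled grid.
#' @export
resample_mask <- function(mask, native_edges, cell_height = 0.75,
                          rule = c("any", "majority")) {
  rule <- match.arg(rule)
  centres <- (utils::head(native_edges, -1) + utils::tail(native_edges, -1)) / 2
  k_first <- ceiling(native_edges[1] / cell_height - 1e-9)
  k_last <- floor(native_edges[length(native_edges)] / cell_height + 1e-9)
  out_edges <- (k_first:k_last) * cell_height
  grp <- findInterval(centres, out_edges)
  keep <- grp >= 1 & grp <= length(out_edges) - 1
  ncell <- length(out_edges) - 1L
  M <- matrix(0, ncol(mask), ncell)
  M[cbind(which(keep), grp[keep])] <- 1
  cnt <- mask %*% M
  tot <- matrix(1, nrow(mask), ncol(mask)) %*% M
  if (rule == "any") cnt > 0 else cnt > tot / 2
}
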