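#' Regular lon/lat depth grid
#'
#' @param lon,lat cell-centre axes, uniformly spaced per axis.
#' @param z depth matrix, metres (>= 0), dimensions
#'   `length(lon) x length(lat)`; `NA` marks invalid cells.
#' @return an object of class `"depth_grid"`.
#' @export
depth_grid <- function(lon, lat, z) {
  z <- as.matrix(z)
  stopifnot(length(lon) == nrow(z), length(lat) == ncol(z))
  if (length(lon) > 2 && diff(range(diff(lon))) > 1e-8 * abs(mean(diff(lon))))
    stop("lon spacing must be uniform")
  if (length(lat) > 2 && diff(range(diff(lat))) > 1e-8 * abs(mean(diff(lat))))
    stop("lat spacing must be uniform")
  if (any(z < 0, na.rm = TRUE)) stop("depths must be >= 0")
  structure(list(lon = lon, lat = lat, z = z, valid = is.finite(z)),
            class = "depth_grid")
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("<depth_grid> %d x %d cells (%.4g x %.4g deg), %.1f%% valid, z %.1f-%.1f m\n",
              length(x$lon), length(x$lat),
              mean(diff(x$lon)), mean(diff(x$lat)), 100 * mean(x$valid),
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE)))
  invisible(x)
}

#' Interpolate a boundary-depth series onto a regular grid
#'
#' Linear interpolation on a Delaunay triangulation of the ping positions;
#' grid cells outside the convex hull of the data are invalid.  At least
#' three non-collinear points are required (a single straight transect is
#' degenerate and cannot be gridded).
#'
#' @param z a [zveec_series()] or a data frame with `lon`, `lat` and a
#'   depth column `z_veec_m` (or `z`).
#' @param resolution_deg grid resolution, degrees (both axes).
#' @return a [depth_grid].
#' @export
grid_zveec <- function(z, resolution_deg = 0.05) {
  if (inherits(z, "zveec_series")) {
    d <- z[z$valid & !is.na(z$z_veec_m), c("lon", "lat", "z_veec_m")]
  } else {
    d <- as.data.frame(z)
    if (is.null(d$z_veec_m)) d$z_veec_m <- d$z
  }
  if (nrow(d) < 3) stop("need at least 3 points (gridding error)")
  # collinearity check via the rank of centred coordinates
  cc <- cbind(d$lon - mean(d$lon), d$lat - mean(d$lat))
  if (qr(cc)$rank < 2)
    stop("points are collinear; cannot triangulate (gridding error)")
  xo <- seq(min(d$lon), max(d$lon), by = resolution_deg)
  yo <- seq(min(d$lat), max(d$lat), by = resolution_deg)
  g <- interp::interp(d$lon, d$lat, d$z_veec_m, xo = xo, yo = yo,
                      method = "linear", duplicate = "mean")
  depth_grid(g$x, g$y, pmax(g$z, 0))
}

#' Horizontal habitat mask (polygons)
#'
#' A mask is a list of polygons in geographic coordinates; each polygon is
#' a list of rings (two-column lon/lat matrices, first ring the outer
#' boundary, additional rings holes).  Point membership uses the even-odd
#' rule.  `read_habitat_mask` reads GeoJSON `Polygon`/`MultiPolygon`
#' geometries (bare, as a `Feature` or in a `FeatureCollection`).
#'
#' @param polygons list of polygons as described above (a single matrix is
#'   promoted to one single-ring polygon).
#' @return an object of class `"habitat_mask"`.
#' @export
habitat_mask <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(list(polygons))
  if (is.list(polygons) && length(polygons) && is.matrix(polygons[[1]]))
    polygons <- list(polygons)
  polygons <- lapply(polygons, function(poly) lapply(poly, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    # drop an explicit closing vertex; rings are implicitly closed
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    r
  }))
  structure(list(polygons = polygons), class = "habitat_mask")
}

#' @rdname habitat_mask
#' @param path GeoJSON file.
#' @export
read_habitat_mask <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(j$type %||% stop("not a GeoJSON object"),
    FeatureCollection = lapply(j$features, `[[`, "geometry"),
    Feature = list(j$geometry),
    Polygon = , MultiPolygon = list(j),
    stop("unsupported GeoJSON type: ", j$type))
  ring <- function(r) do.call(rbind, lapply(r, function(pt)
    c(pt[[1]], pt[[2]])))
  polys <- list()
  for (g in geoms) {
    if (g$type == "Polygon") {
      polys <- c(polys, list(lapply(g$coordinates, ring)))
    } else if (g$type == "MultiPolygon") {
      polys <- c(polys, lapply(g$coordinates, function(p) lapply(p, ring)))
    } else stop("unsupported geometry type: ", g$type)
  }
  habitat_mask(polys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Point-in-mask test (even-odd rule over all rings)
#'
#' @param lon,lat point coordinates (vectors).
#' @param mask a [habitat_mask].
#' @return logical vector.
#' @export
point_in_mask <- function(lon, lat, mask) {
  stopifnot(inherits(mask, "habitat_mask"))
  count <- integer(length(lon))
  for (poly in mask$polygons) for (r in poly) {
    count <- count + as.integer(
      sp::point.in.polygon(lon, lat, r[, 1], r[, 2]) > 0)
  }
  count %% 2L == 1L
}

# spherical area (km^2) of a lon/lat rectangle cell
.cell_area_km2 <- function(lon_w, lon_e, lat_s, lat_n, R = 6371) {
  rad <- pi / 180
  R^2 * (lon_e - lon_w) * rad * (sin(lat_n * rad) - sin(lat_s * rad))
}

#' Integrate a depth grid into a habitat volume
#'
#' The oxygenated habitat volume above the OMZ: the sum over valid, masked
#' grid cells of `z` (km) times the spherical cell area (km^2).  Cells
#' straddling the mask boundary contribute by the fraction of their area
#' inside the polygon, estimated on an `nsub x nsub` subgrid of the cell.
#' The water surface is taken as the upper bound of the volume (no
#' bathymetry clipping by default); a bathymetry grid of the same shape
#' may optionally clip `z`.
#'
#' @param g a [depth_grid].
#' @param mask a [habitat_mask].
#' @param nsub subgrid points per cell axis for fractional boundary cells.
#' @param bathymetry optional matrix of bottom depths (m) conformable with
#'   `g$z`; when given, `z` is clipped to the bottom.
#' @return list `volume_km3`, `area_km2` (masked valid area), `n_cells`
#'   (cells with nonzero contribution).
#' @export
habitat_volume <- function(g, mask, nsub = 4, bathymetry = NULL) {
  stopifnot(inherits(g, "depth_grid"), inherits(mask, "habitat_mask"))
  z <- g$z
  if (!is.null(bathymetry)) z <- pmin(z, bathymetry)
  dlon <- mean(diff(g$lon)); dlat <- mean(diff(g$lat))
  idx <- which(is.finite(z), arr.ind = TRUE)
  if (nrow(idx) == 0) { warning("no valid cells"); return(list(volume_km3 = 0, area_km2 = 0, n_cells = 0L)) }
  lonc <- g$lon[idx[, 1]]; latc <- g$lat[idx[, 2]]
  # subgrid offsets at sub-cell centres
  off <- (seq_len(nsub) - 0.5) / nsub - 0.5
  frac <- numeric(nrow(idx))
  for (i in seq_len(nsub)) for (j in seq_len(nsub)) {
    frac <- frac + point_in_mask(lonc + off[i] * dlon,
                                 latc + off[j] * dlat, mask)
  }
  frac <- frac / nsub^2
  area <- .cell_area_km2(lonc - dlon / 2, lonc + dlon / 2,
                         latc - dlat / 2, latc + dlat / 2)
  contrib <- frac * area
  vol <- sum(z[idx] / 1000 * contrib)
  if (vol == 0) warning("grid and mask do not intersect")
  list(volume_km3 = vol, area_km2 = sum(contrib),
       n_cells = sum(contrib > 0))
}

#' Meridional profile of a depth grid near the coast
#'
#' For each latitude band of the grid, the mean and standard deviation of
#' valid cells lying within `offshore_limit_km` of the supplied coastline
#' polyline -- the standard summary of alongshore boundary-depth structure.
#'
#' @param g a [depth_grid].
#' @param coastline two-column lon/lat matrix (polyline vertices).
#' @param offshore_limit_km offshore cut-off, km.
#' @return data frame `lat`, `mean_z`, `sd_z`, `n`.
#' @export
meridional_profile <- function(g, coastline, offshore_limit_km = 200) {
  stopifnot(inherits(g, "depth_grid"))
  if (missing(coastline) || is.null(coastline))
    stop("a coastline polyline is required (parameter error)")
  coastline <- as.matrix(coastline)
  pts <- cbind(rep(g$lon, length(g$lat)), rep(g$lat, each = length(g$lon)))
  dk <- geosphere::dist2Line(pts, coastline, distfun = geosphere::distHaversine)[, 1] / 1000
  near <- matrix(dk <= offshore_limit_km, length(g$lon), length(g$lat))
  out <- data.frame(lat = g$lat, mean_z = NA_real_, sd_z = NA_real_,
                    n = 0L)
  for (j in seq_along(g$lat)) {
    v <- g$z[near[, j] & g$valid[, j], j]
    v <- v[is.finite(v)]
    out$n[j] <- length(v)
    if (length(v)) {
      out$mean_z[j] <- mean(v)
      out$sd_z[j] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  out
}

#' Write a depth grid to NetCDF
#'
#' Variables `z_m(lon, lat)` and `valid(lon, lat)` on coordinate
#' dimensions `lon`, `lat`.
#'
#' @param g a [depth_grid].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_depth_grid <- function(g, path) {
  stopifnot(inherits(g, "depth_grid"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  vz <- ncdf4::ncvar_def("z_m", "m", list(dlon, dlat),
                         9.969209968386869e36, prec = "double")
  vv <- ncdf4::ncvar_def("valid", "", list(dlon, dlat), prec = "integer")
  nc <- ncdf4::nc_create(path, list(vz, vv))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, "z_m", g$z)
  ncdf4::ncvar_put(nc, "valid", g$valid * 1L)
  invisible(path)
}
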