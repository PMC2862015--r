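zigzag_points <- function(n = 200, cycles = 6, lon0 = -79.5, lat0 = -8.5) {
  # a multi-transect survey covering a lon/lat box
  lat <- lat0 + seq(0, 0.9, length.out = n)
  lon <- lon0 + 0.45 + 0.45 * sin(seq(0, cycles * pi, length.out = n))
  data.frame(lon = lon, lat = lat)
}

rect_mask <- function(w, e, s, n) {
  habitat_mask(cbind(c(w, e, e, w), c(s, s, n, n)))
}

test_that("gridding reproduces constant and planar fields inside the hull", {
  pts <- zigzag_points()
  pts$z <- 50
  g <- grid_zveec(pts, resolution_deg = 0.05)
  expect_equal(g$z[g$valid], rep(50, sum(g$valid)))
  pts$z <- 10 + 30 * (pts$lon + 80) + 20 * (pts$lat + 9)   # planar
  g2 <- grid_zveec(pts, resolution_deg = 0.05)
  want <- outer(g2$lon, g2$lat, function(lo, la)
    10 + 30 * (lo + 80) + 20 * (la + 9))
  expect_lt(max(abs(g2$z - want)[g2$valid]), 1e-6)
})

test_that("a Gaussian ridge is recovered within one grid cell", {
  pts <- zigzag_points(1200, cycles = 16)
  ridge_lat <- -8.1
  pts$z <- 60 - 35 * exp(-((pts$lat - ridge_lat) / 0.08)^2)
  g <- grid_zveec(pts, resolution_deg = 0.02)
  prof <- apply(g$z, 2, function(col) mean(col, na.rm = TRUE))
  expect_lte(abs(g$lat[which.min(prof)] - ridge_lat), 0.02 + 1e-9)
})

test_that("degenerate inputs are gridding errors", {
  expect_error(grid_zveec(data.frame(lon = 1:2, lat = 1:2, z = 1:2)),
               "3 points")
  expect_error(grid_zveec(data.frame(lon = 1:5, lat = rep(2, 5), z = 1:5)),
               "collinear")
})

test_that("habitat volume integrates depth x spherical area", {
  # rectangle whose spherical area is exactly 1000 km^2
  R <- 6371; rad <- pi / 180
  s <- -9; n <- -8
  dlam <- 1000 / (R^2 * (sin(n * rad) - sin(s * rad)))
  w <- -79.5; e <- w + dlam / rad
  mask <- rect_mask(w, e, s, n)
  lon <- seq(w - 0.01, e + 0.01, by = 0.005)
  lat <- seq(s - 0.01, n + 0.01, by = 0.02)
  g <- depth_grid(lon, lat, matrix(50, length(lon), length(lat)))
  v <- habitat_volume(g, mask, nsub = 5)
  expect_equal(v$area_km2, 1000, tolerance = 0.005)
  expect_equal(v$volume_km3, 50, tolerance = 0.005 * 50)  # 0.05 km x 1000 km2
  # empty intersection
  expect_warning(v0 <- habitat_volume(g, rect_mask(0, 1, 0, 1)),
                 "intersect")
  expect_equal(v0$volume_km3, 0)
})

test_that("volume agrees with a Monte-Carlo area oracle on an irregular mask", {
  set.seed(99)
  ang <- seq(0, 2 * pi, length.out = 8)[-8]
  r <- 0.3 + 0.2 * runif(7)
  poly <- cbind(-79 + r * cos(ang), -8.5 + r * sin(ang) * 0.8)
  mask <- habitat_mask(poly)
  lon <- seq(-79.6, -78.4, by = 0.01); lat <- seq(-9.2, -7.8, by = 0.01)
  g <- depth_grid(lon, lat, matrix(80, length(lon), length(lat)))
  v <- habitat_volume(g, mask, nsub = 4)
  # MC: sample uniformly on the sphere patch (lon uniform, sin(lat) uniform)
  nmc <- 2e5
  R <- 6371; rad <- pi / 180
  slon <- runif(nmc, min(lon), max(lon))
  ssin <- runif(nmc, sin(min(lat) * rad), sin(max(lat) * rad))
  slat <- asin(ssin) / rad
  box_area <- R^2 * (max(lon) - min(lon)) * rad *
    (sin(max(lat) * rad) - sin(min(lat) * rad))
  mc_area <- box_area * mean(point_in_mask(slon, slat, mask))
  expect_equal(v$volume_km3, 0.08 * mc_area, tolerance = 0.01 * v$volume_km3)
})

test_that("volume is additive and monotone over masks", {
  lon <- seq(-80, -79, by = 0.02); lat <- seq(-9, -8, by = 0.02)
  set.seed(4)
  z <- matrix(runif(length(lon) * length(lat), 20, 120), length(lon))
  g <- depth_grid(lon, lat, z)
  mA <- rect_mask(-79.9, -79.5, -8.9, -8.4)
  mB <- rect_mask(-79.5, -79.1, -8.9, -8.4)
  mAB <- habitat_mask(list(list(mA$polygons[[1]][[1]]),
                           list(mB$polygons[[1]][[1]])))
  vA <- habitat_volume(g, mA)$volume_km3
  vB <- habitat_volume(g, mB)$volume_km3
  vAB <- habitat_volume(g, mAB)$volume_km3
  expect_equal(vAB, vA + vB, tolerance = 1e-6)
  big <- rect_mask(-79.9, -79.1, -8.95, -8.1)
  expect_gte(habitat_volume(g, big)$volume_km3, vAB - 1e-9)
})

test_that("volume is stable under grid refinement for piecewise-constant z", {
  mask <- rect_mask(-79.8, -79.2, -8.8, -8.2)
  vols <- vapply(c(0.04, 0.02, 0.01), function(res) {
    lon <- seq(-80, -79, by = res); lat <- seq(-9, -8, by = res)
    g <- depth_grid(lon, lat, matrix(60, length(lon), length(lat)))
    habitat_volume(g, mask, nsub = 4)$volume_km3
  }, 0)
  expect_lt(max(abs(vols / vols[3] - 1)), 0.005)
})

test_that("GeoJSON masks parse for every common container", {
  ring <- list(list(-80, -9), list(-79, -9), list(-79, -8), list(-80, -8),
               list(-80, -9))
  gj <- list(type = "FeatureCollection",
             features = list(list(type = "Feature", properties = NULL,
                                  geometry = list(type = "Polygon",
                                                  coordinates = list(ring)))))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, null = "null")
  m <- read_habitat_mask(path)
  expect_true(point_in_mask(-79.5, -8.5, m))
  expect_false(point_in_mask(-78.5, -8.5, m))
  # a polygon with a hole: even-odd rule
  hole <- cbind(c(-79.7, -79.3, -79.3, -79.7), c(-8.7, -8.7, -8.3, -8.3))
  m2 <- habitat_mask(list(list(m$polygons[[1]][[1]], hole)))
  expect_false(point_in_mask(-79.5, -8.5, m2))
  expect_true(point_in_mask(-79.9, -8.9, m2))
})

test_that("the meridional profile summarises near-coast cells per latitude", {
  lon <- seq(-80, -78, by = 0.05); lat <- seq(-10, -8, by = 0.05)
  coast <- cbind(rep(-78, 21), seq(-10, -8, length.out = 21))
  g <- depth_grid(lon, lat, matrix(50, length(lon), length(lat)))
  p <- meridional_profile(g, coast, offshore_limit_km = 150)
  expect_true(all(abs(p$mean_z[p$n > 0] - 50) < 1e-9))
  expect_true(all(p$sd_z[p$n > 0] == 0))
  # cells further than the cut-off are excluded
  expect_lt(max(p$n), length(lon))
  # deepening northward stays monotone
  zlin <- outer(rep(1, length(lon)), seq(40, 90, length.out = length(lat)))
  g2 <- depth_grid(lon, lat, zlin)
  p2 <- meridional_profile(g2, coast, offshore_limit_km = 150)
  expect_true(all(diff(p2$mean_z[p2$n > 0]) > 0))
  expect_error(meridional_profile(g2, NULL), "coastline")
})
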