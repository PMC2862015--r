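mk_series <- function(n, lat, lon, z, t0 = "2008-02-10 17:00:00") {
  out <- data.frame(index = seq_len(n) - 1L,
                    time = as.POSIXct(t0, tz = "UTC") + seq_len(n),
                    lat = lat, lon = lon, diel = "day",
                    distance_km = seq(0, by = 0.005, length.out = n),
                    z_veec_m = z, valid = TRUE)
  class(out) <- c("zveec_series", "data.frame")
  out
}

station_at <- function(lat, lon) {
  do_profile(seq(0, 150, 5), 0.3 + 4.7 / (1 + exp((seq(0, 150, 5) - 45) / 5)),
             station_id = "S", lat = lat, lon = lon)
}

test_that("station matching averages the closest pings and applies the rules", {
  st <- station_at(-8, -79)
  # ping distance to the station grows with the index
  z <- mk_series(500, -8, -79 + (0:499) * 2e-5, rnorm(500, 50, 2))
  m <- match_station(z, st)
  expect_true(m$included)
  expect_equal(m$n_pings, 300)
  expect_equal(m$z_veec_mean, mean(z$z_veec_m[1:300]))  # the closest 300
  # 299 valid pings within range -> excluded
  z2 <- mk_series(299, -8, -79, rnorm(299, 50, 2))
  expect_false(match_station(z2, st)$included)
  # a station 10 km off the transect -> excluded
  st_far <- station_at(-8, -79 + 10 / (111.32 * cos(-8 * pi / 180)))
  expect_false(match_station(z, st_far)$included)
  # visible probe-track mode bypasses the averaging
  mv <- match_station(z2, st, exact_z = 47.25)
  expect_true(mv$included && mv$visible_track)
  expect_equal(mv$z_veec_mean, 47.25)
})

test_that("matching is invariant to ping order and surplus duplicates", {
  set.seed(21)
  st <- station_at(-8, -79)
  lons <- -79 + runif(400, 0, 0.03)       # within ~3.3 km
  z <- mk_series(400, -8, sort(lons), runif(400, 40, 60))
  m1 <- match_station(z, st)
  perm <- sample(400)
  z2 <- z; z2$lat <- z$lat[perm]; z2$lon <- z$lon[perm]
  z2$z_veec_m <- z$z_veec_m[perm]
  m2 <- match_station(z2, st)
  expect_equal(m1$z_veec_mean, m2$z_veec_mean)
  # duplicating pings beyond the closest 300 changes nothing
  dist <- geosphere::distHaversine(cbind(z$lon, z$lat),
                                   c(st$lon, st$lat), r = 6371000) / 1000
  far <- order(dist)[301:400]
  z3 <- z; z3 <- rbind(z3, z3[far, ]); class(z3) <- class(z)
  z3$time <- as.POSIXct("2008-02-10 17:00:00", tz = "UTC") + seq_len(nrow(z3))
  expect_equal(match_station(z3, st)$z_veec_mean, m1$z_veec_mean)
})

test_that("DO at a depth interpolates and refuses extrapolation", {
  p <- do_profile(c(20, 30), c(1.0, 0.6))
  expect_equal(do_at_zveec(p, 25), 0.8)
  expect_equal(do_at_zveec(p, 20), 1.0)
  expect_true(is.na(do_at_zveec(p, 10)))
  expect_true(is.na(do_at_zveec(p, 35)))
})

test_that("OLS regression reports the standard summary", {
  x <- 1:10
  r <- suppressWarnings(ols_regression(x, x))  # exact fit
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  r2 <- suppressWarnings(ols_regression(x, 2 * x + 1))
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 1)
  expect_equal(r2$n, 10)
  expect_error(ols_regression(rep(1, 5), 1:5), "degenerate")
  expect_error(ols_regression(1:2, 1:2), "at least 3")
})

test_that("OLS recovers a unit slope from noisy proxy pairs", {
  set.seed(96)
  z08 <- runif(96, 20, 120)
  zv <- z08 + rnorm(96, 0, 5)
  r <- ols_regression(z08, zv)
  expect_true(abs(r$slope - 1) < 0.08)
  expect_gt(r$r_squared, 0.85)
  expect_lt(r$p, 1e-10)
})

test_that("one-way ANOVA behaves classically and matches the t-test", {
  set.seed(7)
  g <- rep(c("day", "night"), each = 15)
  v0 <- rnorm(30, 0.8, 0.05)
  a0 <- oneway_anova(v0, g)
  expect_gt(a0$p, 0.001)
  v1 <- c(rnorm(15, 0, 1), rnorm(15, 10, 1))   # 10 sigma apart
  expect_lt(oneway_anova(v1, g)$p, 1e-6)
  # two-group ANOVA F equals the squared pooled-variance t statistic
  tt <- t.test(v0[g == "day"], v0[g == "night"], var.equal = TRUE)
  a <- oneway_anova(v0, g)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  expect_equal(a$df, c(1, 28))
  expect_error(oneway_anova(v0, rep("day", 30)), "2 groups")
})

test_that("difference maps summarise cellwise offsets", {
  g1 <- depth_grid(1:4, 1:3, matrix(50, 4, 3))
  d0 <- difference_map(g1, g1)
  expect_true(all(d0$grid$z == 0))
  g2 <- depth_grid(1:4, 1:3, matrix(45, 4, 3))
  d5 <- difference_map(g1, g2)
  expect_equal(unname(d5$summary["mean"]), 5)
  expect_equal(unname(d5$summary["median"]), 5)
  g3 <- depth_grid(1:5, 1:3, matrix(45, 5, 3))
  expect_error(difference_map(g1, g3), "alignment")
})

test_that("regression and matched-pair CSV writers emit the summary shape", {
  r <- suppressWarnings(ols_regression(1:10, 2 * (1:10) + 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_regression_summary(list(all_stations = r), path)
  tab <- read.csv(path)
  expect_named(tab, c("case", "y", "x", "slope", "intercept", "n", "F",
                      "p", "r_squared"))
  expect_equal(tab$slope, 2)
})
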