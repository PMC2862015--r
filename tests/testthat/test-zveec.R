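test_that("the cumulative profile is a proper downward distribution", {
  # point mass: a single occupied cell at 20 m
  other <- rep(0, 50); other[20] <- 3e-7
  cp <- cumulative_profile(rep(NA_real_, 50), other, 0:50)
  expect_equal(cp$cum_fraction[19], 0)
  expect_equal(cp$cum_fraction[20], 1)
  expect_equal(zveec_from_profile(cp, 0.5), 19 + 0.5)  # inside the cell
  expect_equal(zveec_from_profile(cp, 0.5, interpolate = FALSE), 20)
  # uniform measure over 0-100 m: cum(z) = z / 100
  cp2 <- cumulative_profile(rep(NA_real_, 100), rep(1e-7, 100), 0:100)
  expect_equal(cp2$cum_fraction, (1:100) / 100)
  expect_equal(zveec_from_profile(cp2, 0.98), 98)
  expect_true(all(diff(cp2$cum_fraction) >= 0))
  expect_equal(cp2$cum_fraction[100], 1)
  expect_error(cumulative_profile(rep(NA_real_, 3), rep(NA_real_, 3), 0:3),
               "invalid ping")
})

test_that("fish down-weighting controls the crossing as hand-computed", {
  # uniform zooplankton s per 1 m cell over 0-50 m, one fish cell at 10 m
  # holding 1e4 x s: weighted total 50s + 1e-3 * 1e4 s = 60s
  s <- 1e-8
  other <- rep(s, 50)
  fish <- rep(NA_real_, 50); fish[10] <- 1e4 * s
  cp <- cumulative_profile(fish, other, 0:50, fish_weight = 1e-3)
  expect_equal(max(cp$cum_fraction), 1)
  # 0.98 * 60s = 58.8s; cum at 48 m is 58s, at 49 m is 59s -> 48.8 m
  expect_equal(zveec_from_profile(cp, 0.98), 48.8)
  # with weight 1 the crossing falls inside the 10 m fish cell
  cp1 <- cumulative_profile(fish, other, 0:50, fish_weight = 1)
  z1 <- zveec_from_profile(cp1, 0.98)
  expect_true(z1 > 9 && z1 <= 10)
})

test_that("the crossing depth is monotone in the threshold", {
  expect_error(zveec_from_profile(
    cumulative_profile(NA_real_, 1e-7, 0:1), 1.2), "parameter error")
  set.seed(11)
  for (rep in 1:10) {
    other <- runif(60) * 1e-7
    cp <- cumulative_profile(rep(NA_real_, 60), other, 0:60)
    th <- sort(runif(5, 0.5, 0.999))
    z <- vapply(th, function(t) zveec_from_profile(cp, t), 0)
    expect_true(all(diff(z) >= 0))
  }
})

test_that("the series recovers a flat oxycline and the 5 m ping spacing", {
  sc <- generate_scene(small_spec(z_range = c(50, 50), undulations = list(),
                                  zveec_noise_sd_m = 0, n_schools = 0))
  b <- preprocess_scene(sc)
  z <- zveec_series(b)
  expect_true(all(z$valid))
  expect_lte(mean(abs(z$z_veec_m - 50)), attr(z, "cell_height"))
  # 1 ping per second at 10 knots: 10 x 1852 / 3600 = 5.144 m along track
  step_m <- mean(diff(z$distance_km)) * 1000
  expect_equal(step_m, 10 * 1852 / 3600, tolerance = 1e-3)
})

test_that("the boundary can be estimated from the 120 kHz channel alone", {
  sc <- generate_scene(small_spec(n_schools = 0))
  b <- preprocess_scene(sc)
  m <- fish_mask(b)
  z_comb <- zveec_series(b, m)
  # single-frequency estimate: every valid cell treated as "other" at 120
  m120 <- m; m120$other <- m$fish | m$other; m120$fish[] <- FALSE
  z_single <- zveec_series(b, m120, other_channel = "120")
  d <- abs(z_comb$z_veec_m - z_single$z_veec_m)
  expect_lt(stats::quantile(d, 0.95, na.rm = TRUE), attr(z_comb, "cell_height"))
})

test_that("the estimate is robust to the fish weight on moderate scenes", {
  # schools cover < 5% of pings: not a dense-aggregation survey
  sc <- generate_scene(small_spec(n_schools = 2, school_half_pings = 3))
  b <- preprocess_scene(sc)
  m <- fish_mask(b)
  z3 <- zveec_series(b, m, fish_weight = 1e-3)
  z1 <- zveec_series(b, m, fish_weight = 1)
  frac <- mean(abs(z3$z_veec_m - z1$z_veec_m) < 1, na.rm = TRUE)
  expect_gte(frac, 0.95)
})

test_that("an empty survey yields an empty series", {
  sc <- generate_scene(small_spec(n_pings = 20))
  b <- preprocess_scene(sc)
  b$e38$pings$diel <- b$e120$pings$diel <- "twilight"
  suppressWarnings(b0 <- drop_twilight(b))
  z <- zveec_series(b0)
  expect_s3_class(z, "zveec_series")
  expect_equal(nrow(z), 0)
})

test_that("threshold scanning returns one series per threshold and the
           delta-Sv diagnostic peaks near the layer base", {
  sc <- generate_scene(small_spec(z_range = c(40, 40), undulations = list(),
                                  zveec_noise_sd_m = 0, n_schools = 0))
  b <- preprocess_scene(sc)
  scan <- threshold_scan(b)
  expect_named(scan$series, c("0.95", "0.96", "0.97", "0.98", "0.99"))
  # all thresholds agree near a sharp 40 m layer base
  for (s in scan$series)
    expect_lt(mean(abs(s$z_veec_m - 40), na.rm = TRUE), 1.5)
  # the vertical gradient of cumulated echo peaks just above the base
  pk <- scan$delta_sv$depth[which.max(scan$delta_sv$mean_delta)]
  expect_lt(abs(pk - 40), 3)
})

test_that("series CSV export is readable and complete", {
  sc <- generate_scene(small_spec(n_pings = 30))
  z <- zveec_series(preprocess_scene(sc))
  path <- withr::local_tempfile(fileext = ".csv")
  write_zveec_series(z, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), nrow(z))
  expect_named(tab, c("ping_index", "time_iso", "lat", "lon", "diel",
                      "z_veec_m", "valid"))
  expect_equal(tab$z_veec_m, z$z_veec_m)
})
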