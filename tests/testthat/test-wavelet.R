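test_that("the transform is zero on a zero series and linear in its input", {
  n <- 128; dx <- 0.1
  expect_true(all(abs(morlet_cwt(rep(0, n), dx)$coef) == 0))
  set.seed(12)
  d1 <- rnorm(n); d2 <- rnorm(n)
  w1 <- morlet_cwt(d1, dx, demean = FALSE)
  w2 <- morlet_cwt(d2, dx, demean = FALSE)
  w12 <- morlet_cwt(2 * d1 - 3 * d2, dx, demean = FALSE)
  expect_equal(w12$coef, 2 * w1$coef - 3 * w2$coef, tolerance = 1e-10)
})

test_that("a pure cosine peaks at the scale of its wavelength", {
  dx <- 0.1; n <- 1024
  x <- (seq_len(n) - 1) * dx
  d <- cos(2 * pi * x / 10)                 # wavelength 10 km
  ws <- wavelet_spectrum(d, dx)
  sa <- scale_average(ws)
  peak <- sa$wavelength[which.max(sa$mean_power)]
  # within one dyadic scale step (factor 2^0.125) of 10 km
  expect_lt(abs(log2(peak / 10)), 0.125 + 1e-9)
})

test_that("an impulse decays with the Morlet envelope (e-fold at sqrt(2) s)", {
  dx <- 0.1; n <- 512
  d <- rep(0, n); d[n / 2] <- 1
  cw <- morlet_cwt(d, dx, scales = c(2, 4), demean = FALSE)
  for (si in 1:2) {
    s <- cw$scales[si]
    prof <- abs(cw$coef[si, ])
    x0 <- (n / 2 - 1) * dx
    at0 <- prof[n / 2]
    # |psi| ~ exp(-eta^2/2): at distance sqrt(2) s the modulus is at0/e
    k <- round(sqrt(2) * s / dx)
    expect_equal(prof[n / 2 + k] / at0, exp(-1), tolerance = 0.05)
  }
})

test_that("the Fourier implementation matches direct convolution", {
  set.seed(33)
  dx <- 0.1; n <- 256
  d <- rnorm(n)
  scales <- c(0.4, 1, 3)
  cw <- morlet_cwt(d, dx, scales = scales, demean = FALSE)
  x <- (seq_len(n) - 1) * dx
  interior <- 60:(n - 60)
  for (si in seq_along(scales)) {
    s <- scales[si]
    direct <- vapply(interior, function(i) {
      eta <- (x - x[i]) / s
      psi <- pi^(-1 / 4) * exp(1i * 6 * eta) * exp(-eta^2 / 2)
      sum(d * Conj(psi)) * sqrt(dx / s)   # sampled-wavelet normalisation
    }, 0i)
    got <- cw$coef[si, interior]
    expect_lt(max(abs(got - direct)) / max(abs(direct)), 1e-6)
  }
})

test_that("coefficients are translation covariant inside the cone", {
  set.seed(44)
  dx <- 0.1; n <- 256; k <- 10
  d <- rnorm(n)
  dshift <- c(rep(0, k), d[1:(n - k)])
  w <- morlet_cwt(d, dx, scales = c(0.5, 1), demean = FALSE)
  ws <- morlet_cwt(dshift, dx, scales = c(0.5, 1), demean = FALSE)
  mid <- 80:150
  expect_equal(ws$coef[, mid + k], w$coef[, mid], tolerance = 1e-3)
})

test_that("adjusted power divides by scale and is flat for white noise", {
  dx <- 0.1
  set.seed(55)
  cw <- morlet_cwt(rnorm(256), dx, scales = c(5, 10), demean = FALSE)
  # equal |W|^2 at scales 5 and 10 km -> adjusted ratio exactly 2:1
  cw$coef[1, ] <- 1 + 0i; cw$coef[2, ] <- 1 + 0i
  pa <- adjusted_power(cw)
  expect_equal(pa[1, 1] / pa[2, 1], 2)
  # expectation over replicates: mean raw power ~ sigma^2 at every scale
  nrep <- 60; n <- 256
  scales <- 0.4 * 2^(seq(0, 3, by = 0.5))
  acc <- numeric(length(scales))
  for (r in seq_len(nrep)) {
    w <- morlet_cwt(rnorm(n), dx, scales = scales)
    coi <- cone_of_influence(w)
    pw <- abs(w$coef)^2
    pw[!outer(scales, coi, `<=`)] <- NA
    acc <- acc + rowMeans(pw, na.rm = TRUE)
  }
  acc <- acc / nrep
  # near-flat across a 16-fold scale range
  expect_lt(diff(range(acc)) / mean(acc), 0.3)
})

test_that("the cone of influence is the edge-distance over sqrt(2)", {
  n <- 101; dx <- 0.2
  coi <- cone_of_influence(n, dx)
  expect_equal(coi[1], 0); expect_equal(coi[n], 0)
  expect_equal(which.max(coi), 51)               # midpoint
  expect_equal(coi[51], 50 * dx / sqrt(2))
  expect_equal(diff(coi[1:40]), rep(dx / sqrt(2), 39))
})

test_that("the AR(1) significance test is calibrated near its level", {
  set.seed(66)
  nrep <- 80; n <- 300; dx <- 0.1; a <- 0.5
  fracs <- vapply(seq_len(nrep), function(r) {
    d <- as.numeric(arima.sim(list(ar = a), n))
    ws <- wavelet_spectrum(d, dx, significance = TRUE)
    mean(ws$signif[ws$in_cone])
  }, 0)
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
  # a zero series flags nothing
  ws0 <- wavelet_spectrum(c(rep(0, 50), 1e-12, rep(0, 49)), dx)
  sg <- red_noise_significance(ws0, sigma2 = 1, ar1 = 0)
  expect_false(any(sg))
  expect_error(morlet_cwt(rnorm(5), dx) |> red_noise_significance(),
               "too short")
})

test_that("injected 10 km sinusoid yields a contiguous significant band", {
  set.seed(77)
  dx <- 0.1; n <- 600
  x <- (seq_len(n) - 1) * dx
  d <- 4 * sin(2 * pi * x / 10) + rnorm(n, 0, 0.5)
  ws <- wavelet_spectrum(d, dx, significance = TRUE)
  near_idx <- which(abs(log2(ws$scales * ws$cwt$fourier_factor / 10)) < 0.2)
  band <- ws$signif[near_idx, ws$in_cone[near_idx[1], ], drop = FALSE]
  expect_gt(mean(band), 0.9)
})

test_that("spectrum NetCDF export round-trips the power grid", {
  set.seed(88)
  ws <- wavelet_spectrum(rnorm(64), 0.1, significance = TRUE)
  path <- withr::local_tempfile(fileext = ".nc")
  write_wavelet_spectrum(ws, path)
  nc <- ncdf4::nc_open(path); on.exit(ncdf4::nc_close(nc))
  expect_equal(t(ncdf4::ncvar_get(nc, "power_adj")), ws$power_adj,
               tolerance = 1e-12)
  expect_equal(as.vector(ncdf4::ncvar_get(nc, "coi")), ws$coi)
})
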