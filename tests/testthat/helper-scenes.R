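# shared fixture builders -- everything is generated in code at test time

default_noise_models <- function(spec) {
  list(`38` = suppressWarnings(noise_model(spec$alpha38, spec$offset38)),
       `120` = suppressWarnings(noise_model(spec$alpha120, spec$offset120)))
}

# a quick coastal scene small enough for unit tests
small_spec <- function(...) {
  base <- list(n_pings = 300, max_depth_m = 80, z_range = c(30, 55),
               undulations = list(list(wavelength_km = 1, amplitude_m = 2)),
               n_stations = 10, n_schools = 3, seed = 101)
  ov <- list(...)
  base[names(ov)] <- ov          # replace outright (no recursive merging)
  do.call(scene_spec, base)
}

# noise subtraction (when rendered), elementary cells, twilight removal
preprocess_scene <- function(sc, cell_height = 0.75) {
  b <- sc$echograms
  if (sc$spec$noise_on) b <- subtract_noise(b, default_noise_models(sc$spec))
  drop_twilight(resample_echogram(b, cell_height))
}

# rebuild a scene spec with field overrides
modifyList_spec <- function(spec, ...) {
  args <- unclass(spec)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(scene_spec, args)
}

# minimal hand-built ping metadata
mk_pings <- function(n, t0 = "2008-02-10 17:00:00", lat = -8, lon = -79) {
  data.frame(time = as.POSIXct(t0, tz = "UTC") + seq_len(n) - 1,
             lat = rep(lat, n), lon = rep(lon, n))
}

# one-ping bi-frequency pair from two Sv vectors on 1 m cells
mk_bifreq <- function(sv38, sv120, h = 1, t0 = "2008-02-10 17:00:00") {
  edges <- (0:length(sv38)) * h
  p <- mk_pings(1, t0)
  bifrequency(
    echogram(matrix(sv38, 1), edges, 38, p, transducer_depth = 0),
    echogram(matrix(sv120, 1), edges, 120, p, transducer_depth = 0))
}
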