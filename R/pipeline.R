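.config_defaults <- function() {
  list(
    scene = list(),                       # overrides for scene_spec()
    noise = list(alpha_db_per_m = list(`38` = 0.0098, `120` = 0.0267),
                 offset_db = list(`38` = -145, `120` = -140)),
    grid = list(cell_height_m = 0.75, pings_per_cell = 1),
    diel = list(day_min_elev_deg = 0, night_max_elev_deg = -12),
    discriminate = list(sum_threshold_db = -135, diff_threshold_db = 2),
    zveec = list(threshold = 0.98, fish_weight = 1e-3,
                 fish_channel = "38", other_channel = "120"),
    match = list(min_pings = 300, max_radius_km = 5),
    oxygen = list(iso_ml_l = 0.8, omz_conc_ml_l = 0.5,
                  grad_crit_ml_l_m = -0.02, transducer_depth_m = 3.4),
    habitat = list(resolution_deg = 0.05, mask_file = NULL),
    wavelet = list(dx_km = 0.1, omega0 = 6),
    output = list(dir = NULL),
    logging = list(level = "info")
  )
}

.check_known_keys <- function(user, ref, path = "") {
  extra <- setdiff(names(user), names(ref))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(ref[[k]]) && length(names(ref[[k]])) && !is.null(user[[k]])) {
      if (!is.list(user[[k]]))
        stop("config key ", path, k, " must be a table", call. = FALSE)
      kref <- if (k == "scene") formals_as_list(scene_spec) else ref[[k]]
      .check_known_keys(user[[k]], kref, paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

formals_as_list <- function(f) as.list(formals(f))

#' Build a validated run configuration
#'
#' One TOML document (or an R list) carrying every stage's parameters; the
#' defaults are the survey-standard values (-135 dB fish-extraction
#' threshold, +2 dB frequency difference, 98% cumulative fraction, 1e-3
#' fish weight, 0.75 m cells, 300 pings within 5 km for station matching,
#' 0.8 mL L^-1 isovalue, 3.4 m transducer).  Unknown keys are rejected
#' before any computation; supplied values override the defaults.
#'
#' @param config path to a TOML file, or a named list of overrides.
#' @return the merged configuration list, class `"run_config"`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- RcppTOML::parseTOML(config)
    class(config) <- "list"
  }
  defaults <- .config_defaults()
  .check_known_keys(config, defaults)
  merged <- utils::modifyList(defaults, config)
  structure(merged, class = c("run_config", "list"))
}

.log <- function(cfg, level, ...) {
  lv <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (lv[[level]] >= lv[[cfg$logging$level %||% "info"]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

.stage <- function(name, cfg, expr) {
  .log(cfg, "info", "stage ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full synthetic-survey workflow
#'
#' Wires the stages end to end on a generated scene: simulate, noise
#' subtraction, resampling to elementary cells, twilight removal, fish
#' discrimination, the per-ping boundary series, oxycline features and
#' station matching with the validation regression, optional habitat
#' gridding/volume (when a mask file is configured), and the wavelet
#' spectrum of the boundary space series.  A failed stage aborts with the
#' stage name and cause.
#'
#' @param config a [run_config()] (or anything accepted by it).
#' @param seed optional override of the scene seed.
#' @param skip_validation skip the station-matching/regression stage.
#' @param skip_wavelet skip the wavelet stage.
#' @return a run report (list): `n_pings`, `n_valid`, `regression`
#'   (slope/intercept/n/F/p/r_squared), `anova_diel`, `mean_diff_m`,
#'   `do_at_zveec_mean`, `volume_km3` (or `NA`), `wavelet_peaks_km`, and
#'   file paths of any outputs written to `config$output$dir`.  Written as
#'   `report.json` when an output directory is set.
#' @export
run_pipeline <- function(config = run_config(), seed = NULL,
                         skip_validation = FALSE, skip_wavelet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  scene_args <- cfg$scene
  if (!is.null(seed)) scene_args$seed <- seed
  spec <- do.call(scene_spec, scene_args)

  sc <- .stage("simulate", cfg, generate_scene(spec))
  b <- sc$echograms
  b <- .stage("preprocess", cfg, {
    nm <- list(`38` = suppressWarnings(noise_model(
                 cfg$noise$alpha_db_per_m$`38`, cfg$noise$offset_db$`38`)),
               `120` = suppressWarnings(noise_model(
                 cfg$noise$alpha_db_per_m$`120`, cfg$noise$offset_db$`120`)))
    x <- if (spec$noise_on) subtract_noise(b, nm) else b
    x <- resample_echogram(x, cfg$grid$cell_height_m, cfg$grid$pings_per_cell)
    drop_twilight(x)
  })
  masks <- .stage("discriminate", cfg,
                  fish_mask(b, cfg$discriminate$sum_threshold_db,
                            cfg$discriminate$diff_threshold_db))
  z <- .stage("zveec", cfg,
              zveec_series(b, masks, threshold = cfg$zveec$threshold,
                           fish_weight = cfg$zveec$fish_weight,
                           fish_channel = cfg$zveec$fish_channel,
                           other_channel = cfg$zveec$other_channel))
  report <- list(n_pings = nrow(z), n_valid = sum(z$valid),
                 regression = NULL, anova_diel = NULL, mean_diff_m = NA_real_,
                 do_at_zveec_mean = NA_real_, volume_km3 = NA_real_,
                 wavelet_peaks_km = numeric(), outputs = character())

  if (!skip_validation) {
    val <- .stage("validate", cfg, {
      mt <- match_stations(z, sc$stations,
                           min_pings = cfg$match$min_pings,
                           max_radius_km = cfg$match$max_radius_km)
      inc <- mt[mt$included & is.finite(mt$z_iso), ]
      reg <- if (nrow(inc) >= 3) ols_regression(inc$z_iso, inc$z_veec_mean)
      an <- if (length(unique(inc$diel[!is.na(inc$diel)])) >= 2)
        oneway_anova(inc$do_at_zveec, inc$diel)
      list(matches = mt, reg = reg, anova = an,
           mean_diff = mean(inc$z_iso - inc$z_veec_mean),
           do_mean = mean(inc$do_at_zveec, na.rm = TRUE))
    })
    report$regression <- if (!is.null(val$reg)) unclass(val$reg)
    report$anova_diel <- val$anova
    report$mean_diff_m <- val$mean_diff
    report$do_at_zveec_mean <- val$do_mean
  }

  if (!is.null(cfg$habitat$mask_file)) {
    report$volume_km3 <- .stage("habitat", cfg, {
      g <- grid_zveec(z, cfg$habitat$resolution_deg)
      habitat_volume(g, read_habitat_mask(cfg$habitat$mask_file))$volume_km3
    })
  }

  if (!skip_wavelet) {
    report$wavelet_peaks_km <- .stage("wavelet", cfg, {
      ss <- zveec_space_series(z, cfg$wavelet$dx_km)
      ws <- wavelet_spectrum(ss$z_veec_m, cfg$wavelet$dx_km,
                             omega0 = cfg$wavelet$omega0)
      sa <- scale_average(ws)
      sa$wavelength[sa$is_peak]
    })
  }

  out <- cfg$output$dir
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(out, "zveec_series.csv"); write_zveec_series(z, p1)
    p2 <- file.path(out, "report.json")
    jsonlite::write_json(report, p2, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    report$outputs <- c(p1, p2)
  }
  invisible(report)
}
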