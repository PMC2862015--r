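#' Echogram container
#'
#' A calibrated single-frequency echogram: a ping x depth-bin grid of volume
#' backscattering strength Sv (dB re 1 m^-1) with per-ping time/position
#' metadata.  Depths are metres below the sea surface, positive downward;
#' when the on-disk or instrument grid is referenced to the transducer face,
#' pass `reference = "transducer"` and the transducer immersion depth
#' (3.4 m for the survey vessel this workflow was designed around) is added
#' once, here, at construction time.
#'
#' Missing cells ("no data") are `NA` internally and never enter
#' linear-domain sums.
#'
#' @param sv_db numeric matrix, pings in rows, depth bins in columns;
#'   finite values must be <= 0 dB.
#' @param depth_edges strictly increasing bin edges of uniform height,
#'   length `ncol(sv_db) + 1`, metres.
#' @param frequency acoustic frequency, kHz (38 or 120 in this workflow).
#' @param pings data frame with columns `time` (POSIXct, UTC, strictly
#'   increasing), `lat`, `lon`, and optionally `index` (integer >= 0) and
#'   `diel`.
#' @param transducer_depth transducer immersion, metres below surface.
#' @param reference `"surface"` if `depth_edges` are already below-surface
#'   depths, `"transducer"` if they are ranges below the transducer face.
#' @return an object of class `"echogram"`.
#' @export
echogram <- function(sv_db, depth_edges, frequency, pings,
                     transducer_depth = 3.4,
                     reference = c("surface", "transducer")) {
  reference <- match.arg(reference)
  sv_db <- as.matrix(sv_db)
  storage.mode(sv_db) <- "double"
  dimnames(sv_db) <- NULL
  sv_db <- .nodata_to_na(sv_db)
  depth_edges <- as.numeric(depth_edges)
  if (reference == "transducer") depth_edges <- depth_edges + transducer_depth
  if (length(depth_edges) != ncol(sv_db) + 1)
    stop("depth_edges must have length depth_bins + 1 (format error)")
  dz <- diff(depth_edges)
  if (any(dz <= 0))
    stop("depth_edges must be strictly increasing (format error)")
  if (diff(range(dz)) > 1e-6 * mean(dz))
    stop("depth bins must have uniform height (format error)")
  if (any(sv_db > 0, na.rm = TRUE))
    stop("finite Sv must be <= 0 dB re 1 m^-1 (format error)")
  pings <- as.data.frame(pings)
  if (!all(c("time", "lat", "lon") %in% names(pings)))
    stop("pings must have time, lat, lon columns (metadata error)")
  if (nrow(pings) != nrow(sv_db))
    stop("one metadata row per ping is required (metadata error)")
  if (!inherits(pings$time, "POSIXct"))
    stop("ping time must be POSIXct (metadata error)")
  attr(pings$time, "tzone") <- "UTC"
  if (anyNA(pings$lat) || anyNA(pings$lon))
    stop("NaN ping positions (metadata error)")
  if (any(abs(pings$lat) > 90) || any(abs(pings$lon) > 180))
    stop("ping positions outside valid ranges (metadata error)")
  if (nrow(pings) > 1 && any(diff(as.numeric(pings$time)) <= 0))
    stop("ping times must be strictly increasing (metadata error)")
  if (is.null(pings$index)) pings$index <- seq_len(nrow(pings)) - 1L
  if (is.null(pings$diel)) pings$diel <- NA_character_
  structure(list(sv_db = sv_db, depth_edges = depth_edges,
                 frequency = frequency, pings = pings,
                 transducer_depth = transducer_depth),
            class = "echogram")
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf("<echogram> %g kHz, %d pings x %d bins, %.2f-%.2f m (h = %.3g m)\n",
              x$frequency, nrow(x$sv_db), ncol(x$sv_db),
              min(x$depth_edges), max(x$depth_edges), bin_height(x)))
  cat(sprintf("  %.1f%% no-data; transducer at %.1f m\n",
              100 * mean(is.na(x$sv_db)), x$transducer_depth))
  invisible(x)
}

#' @export
dim.echogram <- function(x) dim(x$sv_db)

#' Bin geometry helpers
#'
#' @param e an [echogram].
#' @return `bin_height`: the uniform bin height (m); `bin_centres`: depth of
#'   each bin centre (m below surface); `bin_ranges`: range of each bin
#'   centre below the transducer face (m), as used by the noise model.
#' @export
bin_height <- function(e) diff(e$depth_edges[1:2])

#' @rdname bin_height
#' @export
bin_centres <- function(e) {
  (utils::head(e$depth_edges, -1) + utils::tail(e$depth_edges, -1)) / 2
}

#' @rdname bin_height
#' @export
bin_ranges <- function(e) bin_centres(e) - e$transducer_depth

#' Bi-frequency echogram pair
#'
#' Bundles the 38 and 120 kHz echograms of a survey on one common
#' ping x cell grid (same ping metadata, same depth edges; the per-cell
#' no-data masks may differ between frequencies).
#'
#' @param e38,e120 [echogram] objects at 38 and 120 kHz.
#' @return an object of class `"bifrequency"`.
#' @export
bifrequency <- function(e38, e120) {
  stopifnot(inherits(e38, "echogram"), inherits(e120, "echogram"))
  if (!isTRUE(all.equal(e38$depth_edges, e120$depth_edges)))
    stop("frequencies must share identical depth edges (alignment error)")
  if (nrow(e38$sv_db) != nrow(e120$sv_db) ||
      !isTRUE(all.equal(as.numeric(e38$pings$time),
                        as.numeric(e120$pings$time))))
    stop("frequencies must share identical ping grids (alignment error)")
  structure(list(e38 = e38, e120 = e120), class = "bifrequency")
}

#' @export
print.bifrequency <- function(x, ...) {
  cat("<bifrequency> pair:\n")
  print(x$e38); print(x$e120)
  invisible(x)
}

#' @export
dim.bifrequency <- function(x) dim(x$e38)

#' Subset pings of an echogram or bi-frequency pair
#'
#' @param e [echogram] or [bifrequency].
#' @param i ping selector (logical or integer, rows of the ping grid).
#' @return the subset object.
#' @export
subset_pings <- function(e, i) {
  if (inherits(e, "bifrequency"))
    return(bifrequency(subset_pings(e$e38, i), subset_pings(e$e120, i)))
  stopifnot(inherits(e, "echogram"))
  e$sv_db <- e$sv_db[i, , drop = FALSE]
  e$pings <- e$pings[i, , drop = FALSE]
  rownames(e$pings) <- NULL
  e
}

.time_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")

#' Write an echogram to disk
#'
#' Two dialects are supported.  `"csv"`: comment header lines
#' `# frequency_khz=` and `# transducer_depth_m=`, then one row per ping
#' with ISO-8601 time, lat, lon and one column per depth bin, the column
#' names being the bin-centre depths in metres; no-data cells are written as
#' `NaN`.  `"netcdf"`: dimensions `ping` and `depth_bin`; variables
#' `sv_db(ping, depth_bin)`, `time(ping)` (seconds since epoch),
#' `lat(ping)`, `lon(ping)`, `depth_edges(depth_edge)`; global attributes
#' `frequency_khz` and `transducer_depth_m`.
#'
#' @param e an [echogram].
#' @param path output file path.
#' @param dialect `"csv"` or `"netcdf"`.
#' @return invisibly, `path`.
#' @export
write_echogram <- function(e, path, dialect = c("csv", "netcdf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(e, "echogram"))
  if (!dir.exists(dirname(path)))
    stop("unwritable path: ", dirname(path), " (I/O error)")
  if (dialect == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# frequency_khz=%.17g", e$frequency),
                 sprintf("# transducer_depth_m=%.17g", e$transducer_depth)),
               con)
    centres <- bin_centres(e)
    writeLines(paste(c("time", "lat", "lon", sprintf("%.17g", centres)),
                     collapse = ","), con)
    sv_chr <- matrix(sprintf("%.17g", e$sv_db), nrow = nrow(e$sv_db))
    sv_chr[is.na(e$sv_db)] <- "NaN"
    rows <- paste(.time_iso(e$pings$time),
                  sprintf("%.17g", e$pings$lat),
                  sprintf("%.17g", e$pings$lon),
                  apply(sv_chr, 1, paste, collapse = ","), sep = ",")
    writeLines(rows, con)
  } else {
    np <- nrow(e$sv_db); nb <- ncol(e$sv_db)
    dp <- ncdf4::ncdim_def("ping", "", seq_len(np), create_dimvar = FALSE)
    db <- ncdf4::ncdim_def("depth_bin", "", seq_len(nb), create_dimvar = FALSE)
    de <- ncdf4::ncdim_def("depth_edge", "", seq_len(nb + 1),
                           create_dimvar = FALSE)
    fill <- 9.969209968386869e36
    vars <- list(
      ncdf4::ncvar_def("sv_db", "dB re 1 m-1", list(dp, db), fill,
                       prec = "double"),
      ncdf4::ncvar_def("time", "seconds since 1970-01-01T00:00:00Z",
                       list(dp), prec = "double"),
      ncdf4::ncvar_def("lat", "degrees_north", list(dp), prec = "double"),
      ncdf4::ncvar_def("lon", "degrees_east", list(dp), prec = "double"),
      ncdf4::ncvar_def("depth_edges", "m", list(de), prec = "double"))
    nc <- ncdf4::nc_create(path, vars)
    on.exit(ncdf4::nc_close(nc))
    sv_out <- e$sv_db                   # own copy: ncvar_put substitutes
    sv_out[is.na(sv_out)] <- fill       # the fill value in place
    ncdf4::ncvar_put(nc, "sv_db", sv_out)
    ncdf4::ncvar_put(nc, "time", as.numeric(e$pings$time))
    ncdf4::ncvar_put(nc, "lat", e$pings$lat)
    ncdf4::ncvar_put(nc, "lon", e$pings$lon)
    ncdf4::ncvar_put(nc, "depth_edges", e$depth_edges)
    ncdf4::ncatt_put(nc, 0, "frequency_khz", e$frequency, prec = "double")
    ncdf4::ncatt_put(nc, 0, "transducer_depth_m", e$transducer_depth,
                     prec = "double")
  }
  invisible(path)
}

#' Read an echogram from disk
#'
#' Reads either on-disk dialect written by [write_echogram()].  Depths in
#' files are below-surface; validation (monotone uniform edges, Sv <= 0,
#' finite positions) happens in the [echogram()] constructor.  Diel labels
#' are not stored on disk; they are recomputed from time and position when
#' `classify = TRUE` (the default), so that a written-then-read survey is
#' ready for analysis.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"netcdf"`.
#' @param classify assign diel labels after reading.
#' @return an [echogram].
#' @export
read_echogram <- function(path, dialect = c("csv", "netcdf"),
                          classify = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    hdr <- readLines(path, n = 2)
    if (!all(grepl("^# ", hdr)))
      stop("malformed header: expected two '# key=value' lines (format error)")
    kv <- sub("^# ", "", hdr)
    keys <- sub("=.*", "", kv); vals <- as.numeric(sub(".*=", "", kv))
    names(vals) <- keys
    if (!all(c("frequency_khz", "transducer_depth_m") %in% keys))
      stop("malformed header: missing frequency_khz/transducer_depth_m (format error)")
    tab <- utils::read.csv(path, skip = 2, check.names = FALSE,
                           colClasses = c(time = "character"))
    if (ncol(tab) < 4) stop("malformed table: no depth bins (format error)")
    centres <- as.numeric(names(tab)[-(1:3)])
    if (anyNA(centres))
      stop("malformed header: depth columns must be numeric (format error)")
    if (any(diff(centres) <= 0))
      stop("depth bin centres must be strictly increasing (format error)")
    h <- mean(diff(centres))
    edges <- c(centres - h / 2, centres[length(centres)] + h / 2)
    time <- as.POSIXct(tab$time, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    if (anyNA(time)) stop("unparseable ISO-8601 time (format error)")
    e <- echogram(as.matrix(tab[, -(1:3), drop = FALSE]), edges,
                  frequency = vals[["frequency_khz"]],
                  pings = data.frame(time = time, lat = tab$lat, lon = tab$lon),
                  transducer_depth = vals[["transducer_depth_m"]])
  } else {
    nc <- ncdf4::nc_open(path)
    on.exit(ncdf4::nc_close(nc))
    sv <- ncdf4::ncvar_get(nc, "sv_db", collapse_degen = FALSE)
    sv[abs(sv) > 1e35] <- NA_real_       # fill value -> no-data
    time <- as.POSIXct(as.vector(ncdf4::ncvar_get(nc, "time")),
                       origin = "1970-01-01", tz = "UTC")
    e <- echogram(sv, as.vector(ncdf4::ncvar_get(nc, "depth_edges")),
                  frequency = ncdf4::ncatt_get(nc, 0, "frequency_khz")$value,
                  pings = data.frame(time = time,
                                     lat = as.vector(ncdf4::ncvar_get(nc, "lat")),
                                     lon = as.vector(ncdf4::ncvar_get(nc, "lon"))),
                  transducer_depth =
                    ncdf4::ncatt_get(nc, 0, "transducer_depth_m")$value)
  }
  if (classify) e <- assign_diel(e)
  e
}

#' Display an echogram as an image
#'
#' @param x an [echogram].
#' @param ... passed to [graphics::image()].
#' @export
plot.echogram <- function(x, ...) {
  z <- x$sv_db
  graphics::image(seq_len(nrow(z)), bin_centres(x), z,
                  ylim = rev(range(x$depth_edges)),
                  xlab = "ping", ylab = "depth (m)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::box()
  invisible(x)
}
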