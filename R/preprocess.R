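#' Range-dependent background-noise model
#'
#' Background noise received by an echosounder, expressed at the Sv grid,
#' grows with range R as the two-way spreading and absorption losses applied
#' by time-varied gain: N(R) = 20 log10(R) + 2 alpha R + offset, where
#' `alpha` is the frequency-specific absorption coefficient (dB m^-1) and
#' `offset` the assumed noise at 1 m range (dB).
#'
#' @param alpha absorption coefficient, dB m^-1 (>= 0).
#' @param offset noise at the first metre, dB (negative for physical
#'   instruments; a non-negative value only warns).
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(alpha, offset) {
  if (alpha < 0) stop("absorption coefficient must be >= 0")
  if (offset >= 0)
    warning("noise offset >= 0 dB is not physical for a real instrument")
  structure(list(alpha = alpha, offset = offset), class = "noise_model")
}

#' Evaluate the noise field at given ranges
#'
#' @param ranges ranges below the transducer face, metres (> 0).
#' @param model a [noise_model].
#' @return noise level at each range, dB.
#' @export
noise_field <- function(ranges, model) {
  stopifnot(inherits(model, "noise_model"))
  if (any(ranges <= 0)) stop("ranges must be > 0 (domain error)")
  20 * log10(ranges) + 2 * model$alpha * ranges + model$offset
}

#' Linear-minus noise subtraction
#'
#' Subtracts a noise estimate from Sv in the linear domain:
#' `10 log10(10^(Sv/10) - 10^(N/10))` wherever Sv exceeds the noise, and
#' no-data (`NA`) wherever it does not.  Masking is the contract, not an
#' error: cells at or below the noise floor carry no usable signal.
#'
#' @param sv_db Sv grid (matrix, pings x bins) or vector, dB.
#' @param noise_db noise level, either one value per depth bin (recycled
#'   across pings) or a full grid conformable with `sv_db`.
#' @return the noise-subtracted grid, dB, same shape as `sv_db`.
#' @export
linear_minus <- function(sv_db, noise_db) {
  lin <- 10^(sv_db / 10)
  if (is.matrix(sv_db) && !is.matrix(noise_db)) {
    if (length(noise_db) != ncol(sv_db))
      stop("noise vector must have one value per depth bin (alignment error)")
    nlin <- matrix(10^(noise_db / 10), nrow(sv_db), ncol(sv_db), byrow = TRUE)
  } else {
    if (is.matrix(noise_db) && !identical(dim(noise_db), dim(sv_db)))
      stop("noise grid must match the Sv grid (alignment error)")
    nlin <- 10^(noise_db / 10)
  }
  out <- lin - nlin
  out[!is.na(out) & out <= 0] <- NA_real_
  linear_to_db(out)
}

#' Subtract modelled noise from an echogram
#'
#' Convenience wrapper: evaluates [noise_field()] at the echogram's bin
#' ranges (below the transducer face) and applies [linear_minus()].
#'
#' @param e an [echogram] or [bifrequency] pair.
#' @param model a [noise_model]; for a [bifrequency] input, a named list
#'   `list("38" = ..., "120" = ...)`.
#' @return the denoised object.
#' @export
subtract_noise <- function(e, model) {
  if (inherits(e, "bifrequency")) {
    return(bifrequency(subtract_noise(e$e38, model[["38"]]),
                       subtract_noise(e$e120, model[["120"]])))
  }
  stopifnot(inherits(e, "echogram"))
  e$sv_db <- linear_minus(e$sv_db, noise_field(bin_ranges(e), model))
  e
}

#' Estimate the noise offset from the deepest bins
#'
#' The survey practice fits the noise function to passive or signal-free
#' data with external tools; as a self-contained extension, this helper
#' estimates `offset` by least squares from the deepest fraction of bins
#' (where the signal-to-noise ratio is lowest), holding `alpha` fixed.  It
#' is an estimation aid, not part of the core method.
#'
#' @param e an [echogram].
#' @param alpha absorption coefficient, dB m^-1.
#' @param deep_frac fraction of the deepest bins to use.
#' @return a fitted [noise_model].
#' @export
fit_noise_offset <- function(e, alpha, deep_frac = 0.1) {
  stopifnot(inherits(e, "echogram"), deep_frac > 0, deep_frac <= 1)
  nb <- ncol(e$sv_db)
  sel <- seq.int(max(1L, nb - ceiling(deep_frac * nb) + 1L), nb)
  r <- bin_ranges(e)[sel]
  resid <- sweep(e$sv_db[, sel, drop = FALSE], 2, 20 * log10(r) + 2 * alpha * r)
  offset <- mean(resid, na.rm = TRUE)
  suppressWarnings(noise_model(alpha, offset))
}

#' Resample an echogram to common elementary cells
#'
#' Averages native samples into cells of `cell_height` metres and
#' `pings_per_cell` pings (the survey standard is 0.75 m by 1 ping).
#' Averaging is done on the linear backscattering coefficient, the standard
#' echo-integration practice; no-data members are excluded and an
#' all-no-data cell stays no-data.  Output cell tops are aligned to the sea
#' surface (depth 0); cells not fully covered by native samples (top cell
#' straddling the transducer depth, partial bottom cell) are dropped.
#'
#' @param e an [echogram] or [bifrequency] pair.
#' @param cell_height output cell height, metres (>= native bin height).
#' @param pings_per_cell pings averaged per output cell.
#' @return the resampled object.
#' @export
resample_echogram <- function(e, cell_height = 0.75, pings_per_cell = 1L) {
  if (inherits(e, "bifrequency")) {
    return(bifrequency(resample_echogram(e$e38, cell_height, pings_per_cell),
                       resample_echogram(e$e120, cell_height, pings_per_cell)))
  }
  stopifnot(inherits(e, "echogram"))
  if (!is.numeric(cell_height) || length(cell_height) != 1 || cell_height <= 0)
    stop("cell_height must be a positive number (parameter error)")
  h0 <- bin_height(e)
  if (cell_height < h0 - 1e-9)
    stop("cell_height must be >= the native bin height (parameter error)")
  edges <- e$depth_edges
  k_first <- ceiling(edges[1] / cell_height - 1e-9)
  k_last  <- floor(edges[length(edges)] / cell_height + 1e-9)
  if (k_last <= k_first)
    stop("no complete output cell fits inside the sampled depth range")
  out_edges <- (k_first:k_last) * cell_height
  centres <- bin_centres(e)
  # membership: native bins whose centre falls inside an output cell
  grp <- findInterval(centres, out_edges, left.open = FALSE)
  keep <- grp >= 1 & grp <= length(out_edges) - 1 &
    centres > out_edges[1] & centres < out_edges[length(out_edges)]
  grp[!keep] <- 0L
  ncell <- length(out_edges) - 1L
  M <- matrix(0, ncol(e$sv_db), ncell)
  M[cbind(which(grp > 0), grp[grp > 0])] <- 1
  lin <- 10^(e$sv_db / 10)
  lin0 <- lin; lin0[is.na(lin0)] <- 0
  sums <- lin0 %*% M
  cnts <- (!is.na(lin)) %*% M
  mean_lin <- sums / cnts          # 0/0 -> NaN -> NA
  mean_lin[cnts == 0] <- NA_real_
  sv <- linear_to_db(mean_lin)
  pings <- e$pings
  if (pings_per_cell > 1L) {
    np <- nrow(sv)
    ng <- np %/% pings_per_cell
    if (ng < 1L) stop("fewer pings than pings_per_cell")
    g <- rep(seq_len(ng), each = pings_per_cell)
    idx <- seq_len(ng * pings_per_cell)
    P <- matrix(0, length(idx), ng)
    P[cbind(seq_along(idx), g)] <- 1
    lin2 <- 10^(sv[idx, , drop = FALSE] / 10)
    lin20 <- lin2; lin20[is.na(lin20)] <- 0
    s2 <- t(P) %*% lin20
    c2 <- t(P) %*% (!is.na(lin2))
    m2 <- s2 / c2; m2[c2 == 0] <- NA_real_
    sv <- linear_to_db(m2)
    first <- which(!duplicated(g))          # metadata of the leading ping
    pings <- pings[idx, , drop = FALSE][first, , drop = FALSE]
    rownames(pings) <- NULL
  }
  echogram(sv, out_edges, frequency = e$frequency, pings = pings,
           transducer_depth = e$transducer_depth)
}

#' Remove twilight pings from a survey
#'
#' Drops every ping labelled `twilight` from both frequencies identically.
#' Diel labels must have been assigned (see [assign_diel()]).
#'
#' @param b a [bifrequency] pair (or a single [echogram]).
#' @return the object without twilight pings.
#' @export
drop_twilight <- function(b) {
  pings <- if (inherits(b, "bifrequency")) b$e38$pings else b$pings
  if (anyNA(pings$diel))
    stop("diel labels must be assigned before twilight removal")
  keep <- pings$diel != "twilight"
  if (!any(keep)) warning("all pings are twilight; survey is empty")
  subset_pings(b, keep)
}
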