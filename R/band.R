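#' Detect the aerotactic band by full width at half maximum
#'
#' Intersects the density profile with a horizontal line at half its global
#' maximum and returns the outermost crossings that bracket the maximum,
#' located by linear interpolation between adjacent cell centers. If the
#' half-max region runs into a domain wall on one side, that side is taken
#' at the wall.
#'
#' A candidate is only reported as a band when its peak clears
#' `min_peak_ratio` times the background density, defined as the median of
#' the profile outside the candidate interval. Before a band forms the
#' profile is nearly flat (peak about equal to background) and the half-max
#' line would spuriously span the whole domain; the ratio test rejects that.
#' The detection depends only on the shape of the profile, not its scale.
#'
#' @param B nonnegative density profile at the cell centers.
#' @param grid an [spatial_grid()].
#' @param min_peak_ratio qualification threshold (peak over background).
#' @return Named numeric `c(xL = , xR = )` in um, or `NULL` when no band
#'   qualifies (flat, all-zero, or sub-threshold profiles).
#' @examples
#' g <- spatial_grid(25, 200)
#' tri <- pmax(0, 4 * (1 - abs(g$centers - 100) / 50))
#' detect_band_fwhm(tri, g)   # crossings of level 2 at x = 75 and 125
#' @export
detect_band_fwhm <- function(B, grid, min_peak_ratio = 1.5) {
  stopifnot(inherits(grid, "aeroband_grid"), length(B) == grid$n_cells)
  if (any(B < 0)) stop("density profile must be nonnegative")
  n <- grid$n_cells; dx <- grid$dx
  imax <- which.max(B)
  maxB <- B[imax]
  if (maxB <= 0) return(NULL)
  level <- maxB / 2

  xL <- 0
  if (imax > 1) {
    up <- which(B[seq_len(imax - 1)] < level &
                B[seq_len(imax - 1) + 1] >= level)
    if (length(up)) {
      i <- up[1]
      xL <- ((i - 0.5) + (level - B[i]) / (B[i + 1] - B[i])) * dx
    }
  }
  xR <- grid$S
  if (imax < n) {
    idx <- seq(imax, n - 1)
    dn <- idx[B[idx] >= level & B[idx + 1] < level]
    if (length(dn)) {
      i <- dn[length(dn)]
      xR <- ((i - 0.5) + (level - B[i]) / (B[i + 1] - B[i])) * dx
    }
  }

  outside <- B[grid$centers < xL | grid$centers > xR]
  if (!length(outside)) return(NULL)
  bg <- stats::median(outside)
  if (bg > 0 && maxB / bg < min_peak_ratio) return(NULL)
  c(xL = xL, xR = xR)
}

#' Band trace of a simulation
#'
#' The per-step record of FWHM band detection: sides, midpoint location,
#' width, and the peak density normalized by `B_o`. This is the data behind
#' band-evolution plots.
#'
#' @param sim an `aeroband_sim`.
#' @return A data frame with columns `t_s`, `xL_um`, `xR_um`, `location_um`,
#'   `width_um`, `peak_B_norm`, `present`.
#' @export
band_trace <- function(sim) {
  stopifnot(inherits(sim, "aeroband_sim"))
  sim$trace
}

#' Band readout at a given time
#'
#' @param sim an `aeroband_sim`.
#' @param t time, s (matched to the nearest recorded step; steps are ~0.014 s
#'   apart so this is effectively exact at snapshot times).
#' @return One-row data frame from the band trace.
#' @export
band_at <- function(sim, t) {
  stopifnot(inherits(sim, "aeroband_sim"))
  j <- which.min(abs(sim$trace$t_s - t))
  sim$trace[j, , drop = FALSE]
}

#' Oxygen concentration at the band sides and midpoint
#'
#' Linearly interpolates the oxygen profile (converted to percent of air
#' oxygen) at the left side, midpoint and right side of the band. In the
#' validated base case these readouts bracket the oxygen range the organism
#' prefers.
#'
#' @param state an `aeroband_state` (oxygen stored in uM).
#' @param band numeric `c(xL, xR)` in um.
#' @param params an [band_params()] object (for the Henry factor).
#' @return Named numeric `c(C_left, C_mid, C_right)`, percent of air oxygen.
#' @export
oxygen_at_band <- function(state, band, params) {
  if (is.null(band) || length(band) < 2 || any(!is.finite(band[1:2])))
    stop("band is absent: oxygen readouts at the band are undefined")
  xs <- c(band[[1]], (band[[1]] + band[[2]]) / 2, band[[2]])
  n <- length(state$C)
  centers <- attr(state, "centers")
  if (is.null(centers)) {
    # cell centers implied by the profile length and the capillary span
    dx <- params$S / n
    centers <- (seq_len(n) - 0.5) * dx
  }
  Cpct <- state$C / params$henry_factor * 100
  v <- stats::approx(centers, Cpct, xout = xs, rule = 2)$y
  stats::setNames(v, c("C_left", "C_mid", "C_right"))
}

#' Dissolved-oxygen range spanned by the band
#'
#' Converts the oxygen percentages at the band's right (oxygen-poor) and
#' left (oxygen-rich) sides to dissolved micromolar oxygen. The base case
#' yields about 1.2 to 37 uM: the micromolar window the cells accumulate in.
#'
#' @param readouts numeric `c(C_left, C_right)` in percent (the `C_left` and
#'   `C_right` entries of [oxygen_at_band()] are accepted directly).
#' @param henry_factor uM per unit fraction of air oxygen.
#' @return Named numeric `c(low, high)`, uM.
#' @export
band_oxygen_range_uM <- function(readouts, henry_factor = 1300) {
  cl <- if (!is.null(names(readouts)) && "C_left" %in% names(readouts))
    readouts[["C_left"]] else readouts[[1]]
  cr <- if (!is.null(names(readouts)) && "C_right" %in% names(readouts))
    readouts[["C_right"]] else readouts[[2]]
  c(low = percent_to_micromolar(cr, henry_factor),
    high = percent_to_micromolar(cl, henry_factor))
}

#' Step-like jump diagnostic for the band sides
#'
#' Counts, separately for the left and right band sides, the number of
#' consecutive-sample movements larger than `jump_threshold`. A perfectly
#' smooth trace gives zero on both sides; step-like side movements (the band
#' side hopping by a cell or more between steps) are counted once per hop.
#' Only stretches where the band is present are considered.
#'
#' @param trace a band trace data frame ([band_trace()]).
#' @param jump_threshold jump size, um; defaults to one cell width inferred
#'   from the caller via `dx`.
#' @param dx cell width used for the default threshold.
#' @param after_s ignore the trace before this time (band sides move
#'   erratically while the band is first assembling).
#' @return Named integer `c(left = , right = )`.
#' @export
smoothness_diagnostic <- function(trace, jump_threshold = dx, dx = NULL,
                                  after_s = 0) {
  stopifnot(is.data.frame(trace))
  if (is.null(jump_threshold))
    stop("provide jump_threshold (um) or dx (cell width)")
  tr <- trace[trace$present & trace$t_s >= after_s, , drop = FALSE]
  if (nrow(tr) < 2) stop("need at least two present band samples")
  # restrict to consecutive present samples (no differencing across gaps)
  consec <- c(FALSE, diff(which(trace$present & trace$t_s >= after_s)) == 1)
  jl <- abs(diff(tr$xL_um)) > jump_threshold
  jr <- abs(diff(tr$xR_um)) > jump_threshold
  keep <- consec[-1]
  c(left = sum(jl & keep), right = sum(jr & keep))
}
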