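#' Convert percent air oxygen to dissolved oxygen
#'
#' Henry's-law linear conversion from oxygen expressed as percent of air
#' oxygen to dissolved oxygen in water: `(p / 100) * henry_factor` uM. With
#' the default factor 1300, 1% air oxygen corresponds to 13 uM dissolved
#' oxygen.
#'
#' @param p oxygen, percent of air oxygen (vectorized, must be >= 0).
#' @param henry_factor uM per unit fraction of air oxygen.
#' @return Dissolved oxygen, uM.
#' @examples
#' percent_to_micromolar(1)    # 13 uM
#' percent_to_micromolar(21)   # air-saturated water, 273 uM
#' @export
percent_to_micromolar <- function(p, henry_factor = 1300) {
  if (any(p < 0)) stop("oxygen percentage must be nonnegative")
  if (henry_factor <= 0) stop("henry_factor must be positive")
  p / 100 * henry_factor
}

#' Reversal-frequency switching laws
#'
#' The piecewise-constant reversal frequencies that drive band formation.
#' A right-moving cell reverses (R -> L) at the high frequency while the
#' local oxygen lies strictly inside the window `(C_hat_min, C_max)` and at
#' `F_min` otherwise; a left-moving cell reverses (L -> R) at the high
#' frequency inside `(C_min, C_hat_max)` and at `F_min` otherwise. Both
#' windows overlap on the favorable range `(C_min, C_max)`, where frequent
#' reversals of both populations trap cells: that overlap is what forms the
#' band. Outside the detectable range (below `C_hat_min` or above
#' `C_hat_max`) both directions run at `F_min`, so long runs carry cells
#' away.
#'
#' The high frequency is `F_max_band` for cells inside the currently detected
#' band and `F_max` outside it; the `F_min` branches are never overridden.
#' Oxygen exactly equal to a threshold falls to the `F_min` branch
#' (strict inequalities; measure-zero in the continuum, but it fixes
#' tie-breaking deterministically).
#'
#' @param C oxygen, percent of air oxygen (vectorized).
#' @param params an [band_params()] object.
#' @param inside_band logical: does the cell lie inside the detected band?
#'   Recycled against `C`.
#' @return Reversal frequency, 1/s; one of `F_min`, `F_max`, `F_max_band`.
#' @examples
#' p <- band_params()
#' reversal_frequency_rl(1, p)                      # favorable window: 0.65/s
#' reversal_frequency_rl(1, p, inside_band = TRUE)  # in the band: 0.96/s
#' reversal_frequency_rl(5, p)                      # above C_max: 0.35/s
#' @export
reversal_frequency_rl <- function(C, params, inside_band = FALSE) {
  hi <- ifelse(inside_band, params$F_max_band, params$F_max)
  ifelse(C > params$C_hat_min & C < params$C_max, hi, params$F_min)
}

#' @rdname reversal_frequency_rl
#' @export
reversal_frequency_lr <- function(C, params, inside_band = FALSE) {
  hi <- ifelse(inside_band, params$F_max_band, params$F_max)
  ifelse(C > params$C_min & C < params$C_hat_max, hi, params$F_min)
}

#' Oxygen-depletion gate for the consumption term
#'
#' Indicator that switches bacterial oxygen consumption off once the local
#' oxygen is depleted: 1 where `C > 0`, 0 where `C <= 0` (including tiny
#' negative round-off undershoots).
#'
#' @param C dissolved oxygen, uM (vectorized).
#' @return 0/1 numeric vector.
#' @export
consumption_gate <- function(C) {
  as.numeric(C > 0)
}
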