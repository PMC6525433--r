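#' Initial simulation state
#'
#' The capillary starts oxygen-free (the cell suspension is equilibrated
#' under nitrogen before air is applied at the meniscus) with the bacteria
#' uniformly distributed. The uniform density is split 50/50 between right-
#' and left-movers: only the total is physically constrained, any split with
#' `R + L = B_o` relaxes within a few reversal times, and the symmetric split
#' makes the initial state reaction-neutral.
#'
#' @param params an [band_params()] object.
#' @param grid an [spatial_grid()] object.
#' @return An `aeroband_state`: list with `t` (s), `R`, `L` (cells/ml per
#'   cell) and `C` (dissolved oxygen, uM, per cell).
#' @export
initialize_state <- function(params, grid) {
  stopifnot(inherits(params, "aeroband_params"), inherits(grid, "aeroband_grid"))
  n <- grid$n_cells
  st <- list(t = 0, R = rep(params$B_o / 2, n), L = rep(params$B_o / 2, n),
             C = rep(0, n))
  class(st) <- "aeroband_state"
  st
}

#' Stable explicit time step
#'
#' Forward-Euler bound for the coupled scheme: the advective (CFL) limit
#' `dx / v` and the diffusive limit `dx^2 / (2 D)`, scaled by a safety
#' factor. On the reference grid the diffusive limit binds (about 0.014 s at
#' 128 cells/mm with D = 2000 um^2/s). During integration the step is halved
#' and retried if diffusion would drive oxygen negative, so this bound is a
#' cap, not a promise.
#'
#' @param params an [band_params()] object.
#' @param grid an [spatial_grid()] object.
#' @param safety factor in (0, 1].
#' @return Time step, s.
#' @export
stable_dt <- function(params, grid, safety = 0.9) {
  stopifnot(safety > 0, safety <= 1)
  safety * min(grid$dx / params$v, grid$dx^2 / (2 * params$D))
}

#' One transport + reversal step (pure R reference)
#'
#' Advances the right- and left-mover densities by one forward-Euler step:
#' first-order upwind advection at speed `v` in conservative flux form, with
#' reflecting walls (the outgoing right-mover flux at `x = S` is injected
#' into the left-movers, and vice versa at `x = 0`), plus the reversal
#' exchange `-f_RL R + f_LR L` with frequencies evaluated from each cell's
#' oxygen and whether its center lies in the band interval. Total bacteria
#' `sum(R + L)` is conserved to round-off.
#'
#' This is the reference single-step implementation; [run_simulation()] runs
#' the same update in compiled code, and a test holds the two to agreement.
#'
#' @param state an `aeroband_state`.
#' @param band numeric `c(xL, xR)` (um), or `NULL` when no band is present.
#' @param params,grid model parameters and grid.
#' @param dt time step, s (must respect [stable_dt()]).
#' @return The state with updated `R` and `L` (time is advanced by the
#'   caller).
#' @export
advect_react_step <- function(state, band, params, grid, dt) {
  n <- grid$n_cells; dx <- grid$dx; v <- params$v
  R <- state$R; L <- state$L
  Cpct <- state$C / params$henry_factor * 100
  inside <- if (is.null(band)) rep(FALSE, n)
            else grid$centers >= band[1] & grid$centers <= band[2]
  fRL <- reversal_frequency_rl(Cpct, params, inside)
  fLR <- reversal_frequency_lr(Cpct, params, inside)

  FR_in <- v * c(L[1], R[-n])        # rightward flux through each left face
  FR_out <- v * R
  FL_in <- v * c(L[-1], R[n])        # leftward flux through each right face
  FL_out <- v * L
  ex <- dt * (-fRL * R + fLR * L)
  Rn <- R + dt / dx * (FR_in - FR_out) + ex
  Ln <- L + dt / dx * (FL_in - FL_out) - ex
  # negatives beyond round-off scale signal a CFL/reaction-bound violation;
  # round-off-scale undershoots (e.g. at Courant number exactly 1) are zeroed
  tol <- 1e-10 * max(R, L, 1e-300)
  if (any(Rn < -tol) || any(Ln < -tol))
    stop("negative cell density: time step violates the CFL/reaction bound")
  state$R <- pmax(Rn, 0)
  state$L <- pmax(Ln, 0)
  state
}

#' One oxygen diffusion + consumption step (pure R reference)
#'
#' Explicit finite-volume diffusion of dissolved oxygen with the meniscus
#' held at `C_o` (Dirichlet value applied at the `x = 0` face through a
#' half-cell gradient) and a sealed, zero-flux far end, followed by bacterial
#' consumption `K * B * dt` per cell, gated off where oxygen is depleted and
#' clamped to the oxygen actually available so the concentration can never
#' undershoot zero.
#'
#' @inheritParams advect_react_step
#' @return The state with updated `C`.
#' @export
diffuse_consume_step <- function(state, params, grid, dt) {
  n <- grid$n_cells; dx <- grid$dx
  C <- state$C
  Co <- percent_to_micromolar(params$C_o, params$henry_factor)
  lap <- c(C[2] - 3 * C[1] + 2 * Co,
           C[-c(1, 2)] - 2 * C[-c(1, n)] + C[-c(n - 1, n)],
           C[n - 1] - C[n])
  Cd <- C + dt * params$D / dx^2 * lap
  B <- state$R + state$L
  cons <- pmin(params$K * B * dt, Cd) * consumption_gate(Cd)
  state$C <- Cd - cons
  state
}

#' Run the coupled band-formation simulation
#'
#' Integrates the full model from `t = 0` (or from a supplied initial state)
#' to `t_end`. Every step the band is re-detected from the current total
#' density by FWHM ([detect_band_fwhm()]); cells whose centers lie in the
#' detected interval use the elevated in-band maximum reversal frequency for
#' that step's transport update. The update order per step is: detect band,
#' transport + reversals, oxygen diffusion + consumption. Until a band first
#' qualifies, the outside-band `F_max` applies everywhere.
#'
#' The inner loop runs in compiled code. The step size is
#' `stable_dt(params, grid, safety)`, shortened to land exactly on each
#' requested output time, and halved-and-retried should diffusion ever drive
#' oxygen negative.
#'
#' @param params an [band_params()] object.
#' @param grid an [spatial_grid()]; defaults to 128 cells/mm over `params$S`.
#' @param t_end end time, s.
#' @param output_times times (s) at which to store full state snapshots;
#'   defaults to every 50 s plus `t_end`. The band trace is recorded at every
#'   time step regardless.
#' @param safety time-step safety factor, see [stable_dt()].
#' @param min_peak_ratio band-qualification threshold: the peak must exceed
#'   this multiple of the background density (median outside the candidate
#'   band), see [detect_band_fwhm()].
#' @param state0 optional `aeroband_state` to start from instead of
#'   [initialize_state()] (used e.g. for pure-diffusion verification runs).
#' @param quiet suppress the one-line run log.
#' @return An object of class `aeroband_sim` with elements
#'   \describe{
#'     \item{params, grid}{the inputs,}
#'     \item{times}{snapshot times,}
#'     \item{states}{list of `aeroband_state` snapshots,}
#'     \item{trace}{per-step band trace data frame (`t_s`, `xL_um`, `xR_um`,
#'       `location_um`, `width_um`, `peak_B_norm`, `present`),}
#'     \item{mass_history}{total bacteria (integral of `R + L`, cells/ml um)
#'       at each snapshot time,}
#'     \item{diagnostics}{step counts, dt bound, halvings, relative
#'       conservation error.}
#'   }
#' @examples
#' \donttest{
#' sim <- run_simulation(band_params(), t_end = 300)
#' band_at(sim, 300)
#' }
#' @export
run_simulation <- function(params, grid = default_grid(params), t_end,
                           output_times = NULL, safety = 0.9,
                           min_peak_ratio = 1.5, state0 = NULL,
                           quiet = TRUE) {
  stopifnot(inherits(params, "aeroband_params"), inherits(grid, "aeroband_grid"))
  if (abs(grid$S - params$S) > 1e-9 * params$S)
    stop("grid spans [0, ", grid$S, "] um but params$S = ", params$S, " um")
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("t_end must be a positive time in seconds")
  if (is.null(output_times))
    output_times <- unique(c(seq(0, t_end, by = 50), t_end))
  output_times <- sort(unique(output_times))
  if (any(output_times < 0) || any(output_times > t_end + 1e-9))
    stop("output_times must lie in [0, t_end]")

  st <- if (is.null(state0)) initialize_state(params, grid) else state0
  stopifnot(length(st$R) == grid$n_cells)
  dt_base <- stable_dt(params, grid, safety)
  Co_uM <- percent_to_micromolar(params$C_o, params$henry_factor)

  res <- .cpp_simulate(st$R, st$L, st$C, st$t, t_end, output_times,
                       grid$dx, params$v, params$D, params$K,
                       Co_uM, params$henry_factor, params$B_o,
                       params$F_max_band, params$F_max, params$F_min,
                       params$C_hat_max, params$C_max, params$C_min,
                       params$C_hat_min, dt_base, min_peak_ratio)

  trace <- data.frame(t_s = res$trace_t, xL_um = res$trace_xL,
                      xR_um = res$trace_xR,
                      location_um = (res$trace_xL + res$trace_xR) / 2,
                      width_um = res$trace_xR - res$trace_xL,
                      peak_B_norm = res$trace_peak,
                      present = res$trace_present == 1L)
  states <- lapply(seq_along(output_times), function(j) {
    s <- list(t = output_times[j], R = res$snap_R[, j], L = res$snap_L[, j],
              C = res$snap_C[, j])
    class(s) <- "aeroband_state"
    s
  })
  mass0 <- sum(st$R + st$L) * grid$dx
  cons_err <- if (mass0 > 0) max(abs(res$mass - mass0)) / mass0 else 0

  sim <- list(params = params, grid = grid, t_end = t_end,
              times = output_times, states = states, trace = trace,
              mass_history = res$mass,
              min_peak_ratio = min_peak_ratio,
              diagnostics = list(dt_base = res$dt_base,
                                 dt_min_used = res$dt_min_used,
                                 n_steps = res$n_steps,
                                 n_halvings = res$n_halvings,
                                 conservation_rel_error = cons_err))
  class(sim) <- "aeroband_sim"
  if (!quiet)
    message(sprintf(
      "INFO run t_end=%gs n_cells=%d dt=%.4gs steps=%d conservation=%.2e",
      t_end, grid$n_cells, res$dt_base, as.integer(res$n_steps), cons_err))
  no_band_warning(trace, quiet)
  sim
}

# warn when the band fails to qualify for a long stretch of simulated time
no_band_warning <- function(trace, quiet, grace_s = 30) {
  if (nrow(trace) < 2 || !any(trace$present)) {
    if (!quiet && max(trace$t_s) >= grace_s)
      warning("no band qualified during the whole run", call. = FALSE)
    return(invisible(NULL))
  }
  t_first <- trace$t_s[which(trace$present)[1]]
  after <- trace[trace$t_s >= t_first, ]
  gaps <- rle(after$present)
  if (any(!gaps$values)) {
    idx <- cumsum(gaps$lengths)
    for (k in which(!gaps$values)) {
      t0 <- after$t_s[idx[k] - gaps$lengths[k] + 1]
      t1 <- after$t_s[idx[k]]
      if (t1 - t0 >= grace_s) {
        warning(sprintf("band failed to qualify for %.0f s (t = %.0f..%.0f s)",
                        t1 - t0, t0, t1), call. = FALSE)
        break
      }
    }
  }
  invisible(NULL)
}

#' Extract the state snapshot nearest a requested time
#' @param sim an `aeroband_sim`.
#' @param t time, s; must be within half an output interval of a stored
#'   snapshot.
#' @return An `aeroband_state`.
#' @export
state_at <- function(sim, t) {
  stopifnot(inherits(sim, "aeroband_sim"))
  j <- which.min(abs(sim$times - t))
  if (abs(sim$times[j] - t) > 1e-6)
    stop("no snapshot stored at t = ", t,
         " s (nearest: ", sim$times[j], " s); add it to output_times")
  sim$states[[j]]
}

#' @export
print.aeroband_sim <- function(x, ...) {
  cat(sprintf("Aerotaxis band simulation: %g s on %d cells (dx = %g um)\n",
              x$t_end, x$grid$n_cells, x$grid$dx))
  b <- band_at(x, x$t_end)
  if (b$present)
    cat(sprintf("  final band: location %.1f um, width %.1f um, peak %.2f x B_o\n",
                b$location_um, b$width_um, b$peak_B_norm))
  else
    cat("  no band present at end of run\n")
  cat(sprintf("  steps: %d (dt <= %.4g s), mass conservation error %.2e\n",
              as.integer(x$diagnostics$n_steps), x$diagnostics$dt_base,
              x$diagnostics$conservation_rel_error))
  invisible(x)
}

#' @export
summary.aeroband_sim <- function(object, t = NULL, ...) {
  x <- object
  if (is.null(t)) t <- x$t_end
  b <- band_at(x, t)
  st <- tryCatch(state_at(x, t), error = function(e) NULL)
  out <- list(t = t,
              band = b,
              oxygen = if (b$present && !is.null(st))
                oxygen_at_band(st, c(b$xL_um, b$xR_um), x$params) else NULL,
              conservation_rel_error = x$diagnostics$conservation_rel_error)
  class(out) <- "summary.aeroband_sim"
  out
}

#' @export
print.summary.aeroband_sim <- function(x, ...) {
  cat(sprintf("At t = %g s:\n", x$t))
  if (x$band$present) {
    cat(sprintf("  band [%.1f, %.1f] um: location %.1f, width %.1f um, peak %.2f x B_o\n",
                x$band$xL_um, x$band$xR_um, x$band$location_um,
                x$band$width_um, x$band$peak_B_norm))
    if (!is.null(x$oxygen))
      cat(sprintf("  oxygen: %.2f%% (left) / %.2f%% (mid) / %.2f%% (right)\n",
                  x$oxygen[["C_left"]], x$oxygen[["C_mid"]],
                  x$oxygen[["C_right"]]))
  } else cat("  no band present\n")
  cat(sprintf("  mass conservation error: %.2e (relative)\n",
              x$conservation_rel_error))
  invisible(x)
}

#' Plot a simulation: band evolution and profiles
#'
#' Two panels: the left and right band sides versus time, and the normalized
#' bacterial density `B / B_o` plus oxygen `C / C_o` profiles at chosen
#' snapshot times.
#'
#' @param x an `aeroband_sim`.
#' @param profile_times snapshot times (s) for the profile panel.
#' @param ... ignored.
#' @export
plot.aeroband_sim <- function(x, profile_times = c(50, min(300, x$t_end)), ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tr <- x$trace[x$trace$present, ]
  graphics::plot(NA, xlim = c(0, x$t_end),
                 ylim = range(c(tr$xL_um, tr$xR_um), na.rm = TRUE),
                 xlab = "time (s)", ylab = "x (um)", main = "band sides")
  graphics::lines(tr$t_s, tr$xL_um, col = "blue")
  graphics::lines(tr$t_s, tr$xR_um, col = "red")
  graphics::legend("topright", c("left side", "right side"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  cols <- grDevices::hcl.colors(length(profile_times) + 1, "Dark 2")
  profs <- lapply(profile_times, function(tt) {
    st <- state_at(x, tt)
    (st$R + st$L) / x$params$B_o
  })
  stc <- state_at(x, profile_times[length(profile_times)])
  Cn <- stc$C / percent_to_micromolar(x$params$C_o, x$params$henry_factor)
  graphics::plot(NA, xlim = c(0, x$grid$S),
                 ylim = c(0, max(1, unlist(profs))),
                 xlab = "x (um)", ylab = "B/B_o, C/C_o", main = "profiles")
  for (k in seq_along(profs))
    graphics::lines(x$grid$centers, profs[[k]], col = cols[k])
  graphics::lines(x$grid$centers, Cn, col = cols[length(cols)], lty = 2)
  graphics::legend("topright",
                   c(sprintf("B, t=%gs", profile_times), "C (final)"),
                   col = cols, lty = c(rep(1, length(profile_times)), 2),
                   bty = "n")
  invisible(x)
}
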