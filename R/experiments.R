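#' Base-case validation run
#'
#' Runs the base parameter set ([band_params()] defaults) on the reference
#' 128 cells/mm grid and reports the quantities used for validation against
#' the capillary assay: band sides, location and width at 300 s, the peak
#' normalized density, the oxygen readouts at the band, the dissolved-oxygen
#' range the band spans, the 300 to 600 s location drift, and the mass
#' conservation error.
#'
#' @param t_end end time, s (>= 300; the steadiness check needs 600).
#' @param grid optional [spatial_grid()].
#' @param ... passed to [run_simulation()].
#' @return A list of class `aeroband_report` with elements `sim` (the
#'   `aeroband_sim`) and `report` (named list of readouts).
#' @examples
#' \donttest{
#' bc <- run_base_case()
#' bc$report$location_um
#' }
#' @export
run_base_case <- function(t_end = 600, grid = NULL, ...) {
  params <- band_params()
  if (is.null(grid)) grid <- default_grid(params)
  t_report <- min(300, t_end)
  sim <- run_simulation(params, grid, t_end = t_end,
                        output_times = unique(c(0, 50, t_report, t_end)), ...)
  rep <- band_report(sim, t_report, params)
  if (t_end >= 2 * t_report) {
    b2 <- band_at(sim, t_end)
    rep$location_drift_um <- abs(b2$location_um - rep$location_um)
    rep$verdict <- if (rep$location_drift_um > 50) "moving" else "steady"
  }
  structure(list(sim = sim, report = rep, label = "base case"),
            class = "aeroband_report")
}

#' Comparison run with the earlier model's parameter values
#'
#' Same machinery as [run_base_case()] but with [mazzag_params()]. Under
#' these values the band does not stabilize: its location keeps advancing
#' between 300 s and 600 s, and the report's verdict is `"moving"` (location
#' drift > 50 um between the two times), versus `"steady"` for the base
#' case.
#'
#' @inheritParams run_base_case
#' @return An `aeroband_report`; the report additionally holds
#'   `location_600_um`.
#' @export
run_mazzag_comparison <- function(t_end = 600, grid = NULL, ...) {
  params <- mazzag_params()
  if (is.null(grid)) grid <- default_grid(params)
  sim <- run_simulation(params, grid, t_end = t_end,
                        output_times = unique(c(0, 50, 300, t_end)), ...)
  rep <- band_report(sim, 300, params)
  b2 <- band_at(sim, t_end)
  rep$location_600_um <- b2$location_um
  rep$width_600_um <- b2$width_um
  rep$location_drift_um <- abs(b2$location_um - rep$location_um)
  rep$verdict <- if (rep$location_drift_um > 50) "moving" else "steady"
  structure(list(sim = sim, report = rep, label = "Mazzag parameter set"),
            class = "aeroband_report")
}

# shared readout block at one time point
band_report <- function(sim, t, params) {
  b <- band_at(sim, t)
  if (!b$present)
    return(list(t_s = t, band_present = FALSE,
                conservation_rel_error = sim$diagnostics$conservation_rel_error))
  ox <- oxygen_at_band(state_at(sim, t), c(b$xL_um, b$xR_um), params)
  rng <- band_oxygen_range_uM(ox[c("C_left", "C_right")], params$henry_factor)
  list(t_s = t, band_present = TRUE,
       xL_um = b$xL_um, xR_um = b$xR_um,
       location_um = b$location_um, width_um = b$width_um,
       peak_B_norm = b$peak_B_norm,
       oxygen_percent = ox, oxygen_range_uM = rng,
       conservation_rel_error = sim$diagnostics$conservation_rel_error)
}

#' @export
print.aeroband_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("Aerotaxis run report (%s)\n", x$label))
  if (!isTRUE(r$band_present)) {
    cat(sprintf("  no band present at t = %g s\n", r$t_s))
    return(invisible(x))
  }
  cat(sprintf("  at t = %g s: sides %.1f / %.1f um, location %.1f um, width %.1f um\n",
              r$t_s, r$xL_um, r$xR_um, r$location_um, r$width_um))
  cat(sprintf("  peak density %.2f x B_o\n", r$peak_B_norm))
  cat(sprintf("  oxygen at band: %.2f%% (left) %.2f%% (mid) %.2f%% (right)\n",
              r$oxygen_percent[["C_left"]], r$oxygen_percent[["C_mid"]],
              r$oxygen_percent[["C_right"]]))
  cat(sprintf("  band spans %.1f - %.1f uM dissolved oxygen\n",
              r$oxygen_range_uM[["low"]], r$oxygen_range_uM[["high"]]))
  if (!is.null(r$location_600_um))
    cat(sprintf("  location at end of run: %.1f um\n", r$location_600_um))
  if (!is.null(r$verdict))
    cat(sprintf("  drift %.1f um -> band is %s\n", r$location_drift_um, r$verdict))
  cat(sprintf("  mass conservation error: %.2e\n", r$conservation_rel_error))
  invisible(x)
}

#' Default one-at-a-time sensitivity sweep specification
#'
#' The +/-50%, +/-25% or +/-30% perturbations of the eleven physical
#' parameters examined in the sensitivity study, in its canonical order.
#'
#' @return A list of `(parameter, values)` pairs.
#' @export
default_sweep_spec <- function() {
  list(B_o = c(1e9, 3e8),
       C_o = c(30, 10),
       D = c(2500, 1500),
       K = c(6e-9, 2e-9),
       v = c(30, 10),
       F_max = c(0.85, 0.45),
       F_min = c(0.45, 0.25),
       C_max = c(3, 1),
       C_min = c(0.45, 0.15),
       C_hat_max = c(15, 5),
       C_hat_min = c(0.015, 0.005))
}

#' One-at-a-time parameter sensitivity sweep
#'
#' Runs one full simulation per perturbed value, with every other parameter
#' at its base value, and tabulates band location, width and peak density at
#' `t_end` together with percent changes against the base run. A row whose
#' simulation fails (e.g. an invalid threshold ordering) is reported with
#' status `"failed"` rather than dropped.
#'
#' @param spec named list mapping parameter names to vectors of perturbed
#'   values; defaults to [default_sweep_spec()].
#' @param t_end evaluation time, s (the tabulated values are read at this
#'   time).
#' @param base_params base parameter set.
#' @param grid optional grid (shared across rows; rebuilt per row if the
#'   capillary length is swept).
#' @param quiet passed through to [run_simulation()].
#' @return A data frame of class `aeroband_sweep` with columns `parameter`,
#'   `value`, `pct_change_param`, `location_um`, `pct_change_location`,
#'   `width_um`, `pct_change_width`, `bpeak`, `jumps`, `status`; the base
#'   row's readouts are stored in `attr(, "base")`.
#' @examples
#' \donttest{
#' sw <- run_sensitivity_sweep(list(B_o = c(1e9, 3e8)))
#' sw
#' }
#' @export
run_sensitivity_sweep <- function(spec = default_sweep_spec(), t_end = 300,
                                  base_params = band_params(), grid = NULL,
                                  quiet = TRUE) {
  stopifnot(length(spec) > 0, !is.null(names(spec)))
  unknown <- setdiff(names(spec), names(base_params))
  if (length(unknown))
    stop("sweep over unknown parameter(s): ", paste(unknown, collapse = ", "))

  eval_row <- function(params) {
    g <- if (is.null(grid)) default_grid(params) else grid
    sim <- run_simulation(params, g, t_end = t_end,
                          output_times = c(0, t_end), quiet = quiet)
    b <- band_at(sim, t_end)
    jumps <- if (any(sim$trace$present))
      sum(smoothness_diagnostic(sim$trace, jump_threshold = g$dx))
    else NA_integer_
    list(location = b$location_um, width = b$width_um,
         bpeak = b$peak_B_norm, present = b$present, jumps = jumps)
  }

  base <- eval_row(base_params)
  rows <- list()
  for (nm in names(spec)) {
    for (val in spec[[nm]]) {
      row <- data.frame(parameter = nm, value = val,
                        pct_change_param =
                          (val - base_params[[nm]]) / base_params[[nm]] * 100,
                        location_um = NA_real_, pct_change_location = NA_real_,
                        width_um = NA_real_, pct_change_width = NA_real_,
                        bpeak = NA_real_, jumps = NA_integer_,
                        status = "ok", stringsAsFactors = FALSE)
      res <- tryCatch(
        eval_row(do.call(update_params, c(list(base_params),
                                          stats::setNames(list(val), nm)))),
        error = function(e) e)
      if (inherits(res, "error")) {
        row$status <- paste("failed:", conditionMessage(res))
      } else if (!res$present) {
        row$status <- "no band"
      } else {
        row$location_um <- res$location
        row$pct_change_location <- (res$location - base$location) / base$location * 100
        row$width_um <- res$width
        row$pct_change_width <- (res$width - base$width) / base$width * 100
        row$bpeak <- res$bpeak
        row$jumps <- res$jumps
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "base") <- base
  attr(out, "t_end") <- t_end
  class(out) <- c("aeroband_sweep", "data.frame")
  out
}

#' @export
print.aeroband_sweep <- function(x, digits = 4, ...) {
  b <- attr(x, "base")
  cat(sprintf("One-at-a-time sensitivity sweep at t = %g s\n",
              attr(x, "t_end")))
  cat(sprintf("  base run: location %.1f um, width %.1f um, peak %.2f\n",
              b$location, b$width, b$bpeak))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Identify the oxygen switch thresholds from a measured band
#'
#' Exhaustive grid search for the four switch concentrations
#' `(C_hat_max, C_max, C_min, C_hat_min)`: every combination of the supplied
#' candidate values that respects the ordering
#' `C_hat_min < C_min < C_max < C_hat_max` is simulated to `t_end`, and the
#' candidate whose band location and width at `t_end` have the smallest
#' Euclidean residual against the target is returned. Identifying the
#' switches is an ill-posed problem; requiring both location and width
#' constrains it enough that, on a physically sensible candidate grid,
#' either a single combination fits or none forms a band near the target.
#' Brute force is used deliberately: the response is piecewise-constant in
#' the thresholds, so gradient methods have nothing to grip.
#'
#' @param target_location,target_width measured band location and width, um.
#' @param search_grid named list with candidate vectors for `C_hat_max`,
#'   `C_max`, `C_min`, `C_hat_min`; defaults to the base values and their
#'   +/-50% perturbations.
#' @param t_end evaluation time, s.
#' @param base_params all non-switch parameters.
#' @param unique_tol fits within this residual (um) of the best are counted
#'   when deciding whether the best fit is unique.
#' @param max_residual candidates further than this (um) from the target are
#'   not acceptable fits; a target no candidate band comes near yields `NULL`.
#' @param quiet passed to [run_simulation()].
#' @return An object of class `aeroband_switchfit` (list with `candidate`,
#'   `achieved`, `target`, `residual`, `unique`, `n_candidates`, `table`),
#'   or `NULL` when no candidate produces a band near the target.
#' @export
fit_switches <- function(target_location, target_width,
                         search_grid = list(C_hat_max = c(5, 10, 15),
                                            C_max = c(1, 2, 3),
                                            C_min = c(0.15, 0.3, 0.45),
                                            C_hat_min = c(0.005, 0.01, 0.015)),
                         t_end = 300, base_params = band_params(),
                         unique_tol = 5, max_residual = 1000, quiet = TRUE) {
  need <- c("C_hat_max", "C_max", "C_min", "C_hat_min")
  if (!all(need %in% names(search_grid)))
    stop("search_grid must supply candidates for ",
         paste(need, collapse = ", "))
  cand <- expand.grid(search_grid[need], KEEP.OUT.ATTRS = FALSE)
  ok <- with(cand, C_hat_min < C_min & C_min < C_max & C_max < C_hat_max)
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand))
    stop("no candidate combination satisfies the switch ordering")

  grid <- default_grid(base_params)
  res <- lapply(seq_len(nrow(cand)), function(i) {
    p <- update_params(base_params,
                       C_hat_max = cand$C_hat_max[i], C_max = cand$C_max[i],
                       C_min = cand$C_min[i], C_hat_min = cand$C_hat_min[i])
    sim <- run_simulation(p, grid, t_end = t_end, output_times = c(0, t_end),
                          quiet = quiet)
    b <- band_at(sim, t_end)
    if (!b$present) return(c(NA_real_, NA_real_, NA_real_))
    c(b$location_um, b$width_um,
      sqrt((b$location_um - target_location)^2 +
           (b$width_um - target_width)^2))
  })
  res <- do.call(rbind, res)
  tab <- cbind(cand, location_um = res[, 1], width_um = res[, 2],
               residual_um = res[, 3])
  if (all(is.na(tab$residual_um))) return(NULL)
  if (min(tab$residual_um, na.rm = TRUE) > max_residual) return(NULL)
  best <- which.min(tab$residual_um)
  n_close <- sum(tab$residual_um <= tab$residual_um[best] + unique_tol,
                 na.rm = TRUE)
  out <- list(candidate = as.numeric(cand[best, need]),
              achieved = c(location = tab$location_um[best],
                           width = tab$width_um[best]),
              target = c(location = target_location, width = target_width),
              residual = tab$residual_um[best],
              unique = n_close == 1L,
              n_candidates = nrow(cand),
              table = tab)
  names(out$candidate) <- need
  class(out) <- "aeroband_switchfit"
  out
}

#' @export
print.aeroband_switchfit <- function(x, ...) {
  cat("Oxygen switch identification (exhaustive grid search)\n")
  cat(sprintf("  best candidate: C_hat_max=%g%% C_max=%g%% C_min=%g%% C_hat_min=%g%%\n",
              x$candidate[["C_hat_max"]], x$candidate[["C_max"]],
              x$candidate[["C_min"]], x$candidate[["C_hat_min"]]))
  cat(sprintf("  achieved (location, width) = (%.1f, %.1f) um vs target (%.1f, %.1f) um\n",
              x$achieved[["location"]], x$achieved[["width"]],
              x$target[["location"]], x$target[["width"]]))
  cat(sprintf("  residual %.2f um; %s within tolerance (%d ordered candidates)\n",
              x$residual, if (x$unique) "unique" else "NOT unique",
              x$n_candidates))
  invisible(x)
}
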