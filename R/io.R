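#' Write state snapshots as CSV
#'
#' Long-format table of every stored snapshot: one row per (time, cell) with
#' the raw right/left-mover densities, the normalized total `B / B_o` and
#' oxygen in percent of air oxygen — the data behind density/oxygen profile
#' figures.
#'
#' @param sim an `aeroband_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshots_csv <- function(sim, path) {
  stopifnot(inherits(sim, "aeroband_sim"))
  rows <- lapply(sim$states, function(st) {
    data.frame(t_s = st$t, x_um = sim$grid$centers, R = st$R, L = st$L,
               B_norm = (st$R + st$L) / sim$params$B_o,
               C_percent = st$C / sim$params$henry_factor * 100)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the band trace as CSV
#'
#' @param sim an `aeroband_sim` (or a band trace data frame).
#' @param path output file.
#' @param every keep every `every`-th step (the full per-step trace at
#'   reference resolution has ~40k rows; 1 keeps all).
#' @return `path`, invisibly.
#' @export
write_band_trace_csv <- function(sim, path, every = 1L) {
  tr <- if (inherits(sim, "aeroband_sim")) sim$trace else sim
  stopifnot(is.data.frame(tr))
  tr <- tr[seq(1, nrow(tr), by = every), , drop = FALSE]
  write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' Write run metadata as a JSON sidecar
#'
#' Parameters, grid, time-step summary and the conservation error of a run,
#' for provenance alongside the CSV outputs.
#'
#' @param sim an `aeroband_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_metadata_json <- function(sim, path) {
  stopifnot(inherits(sim, "aeroband_sim"))
  meta <- list(parameters = unclass(sim$params),
               grid = list(n_cells = sim$grid$n_cells, dx_um = sim$grid$dx,
                           S_um = sim$grid$S),
               t_end_s = sim$t_end,
               min_peak_ratio = sim$min_peak_ratio,
               diagnostics = sim$diagnostics)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a sensitivity sweep as CSV
#'
#' Numeric columns of the sensitivity table: parameter, perturbed value,
#' percent changes of the parameter, band location and width, peak density
#' and the jump diagnostic.
#'
#' @param sweep an `aeroband_sweep` from [run_sensitivity_sweep()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "aeroband_sweep"))
  write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
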