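#' Model parameters for aerotactic band formation
#'
#' Bundles the physical parameters of the two-population transport model and
#' the oxygen diffusion--consumption equation. Defaults are the experimentally
#' grounded base case for wild-type *A. brasilense* in a 5 mm capillary with
#' air (21% oxygen) at the meniscus.
#'
#' Oxygen thresholds are stored and compared in percent-of-air-oxygen units;
#' conversion to dissolved micromolar oxygen (via `henry_factor`) happens only
#' in the oxygen PDE and in reporting, so comparison runs can swap the Henry
#' factor without touching the switch logic.
#'
#' @param B_o total bacteria concentration, cells/ml.
#' @param C_o oxygen fraction at the meniscus, percent of air oxygen.
#' @param D oxygen diffusion coefficient in water, um^2/s.
#' @param K per-cell oxygen consumption rate, uM ml / (s cell).
#' @param v swimming speed, um/s.
#' @param F_max_band maximum reversal frequency inside the band, 1/s.
#' @param F_max maximum reversal frequency outside the band, 1/s.
#' @param F_min minimum reversal frequency, 1/s.
#' @param C_hat_max upper detectable oxygen concentration, percent.
#' @param C_max upper favorable oxygen concentration, percent.
#' @param C_min lower favorable oxygen concentration, percent.
#' @param C_hat_min lower detectable oxygen concentration, percent.
#' @param S capillary length, um.
#' @param henry_factor dissolved-oxygen conversion, uM per unit fraction of
#'   air oxygen (1300 means 1% air oxygen = 13 uM dissolved).
#'
#' @return An object of class `aeroband_params`: a named list of the fourteen
#'   quantities above.
#'
#' @details The switch thresholds must satisfy
#'   `C_hat_min < C_min < C_max < C_hat_max` (the detectable window encloses
#'   the favorable window) and the frequencies
#'   `0 < F_min <= F_max <= F_max_band`; violations are errors.
#'
#' @examples
#' p <- band_params()
#' p$C_max
#' mazzag_params()$v
#' @seealso [mazzag_params()], [update_params()], [read_params()]
#' @export
band_params <- function(B_o = 7e8, C_o = 21, D = 2000, K = 4e-9, v = 20,
                        F_max_band = 0.96, F_max = 0.65, F_min = 0.35,
                        C_hat_max = 10, C_max = 2, C_min = 0.3,
                        C_hat_min = 0.01, S = 5000, henry_factor = 1300) {
  p <- list(B_o = B_o, C_o = C_o, D = D, K = K, v = v,
            F_max_band = F_max_band, F_max = F_max, F_min = F_min,
            C_hat_max = C_hat_max, C_max = C_max, C_min = C_min,
            C_hat_min = C_hat_min, S = S, henry_factor = henry_factor)
  validate_params(p)
  class(p) <- "aeroband_params"
  p
}

validate_params <- function(p) {
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  pos <- c("B_o", "C_o", "D", "v", "S", "henry_factor")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (p$K < 0)
    stop("consumption rate K must be nonnegative", call. = FALSE)
  if (!(p$C_hat_min < p$C_min && p$C_min < p$C_max && p$C_max < p$C_hat_max))
    stop("switch thresholds must satisfy C_hat_min < C_min < C_max < C_hat_max",
         call. = FALSE)
  if (!(0 < p$F_min && p$F_min <= p$F_max && p$F_max <= p$F_max_band))
    stop("reversal frequencies must satisfy 0 < F_min <= F_max <= F_max_band",
         call. = FALSE)
  invisible(p)
}

#' Parameter set of the earlier aerotaxis model of Mazzag and co-workers
#'
#' The base-case parameters with the substitutions used for the comparison
#' against the earlier model: lower cell density and consumption rate, faster
#' swimming, different frequency extremes, a wider favorable window, and a
#' Henry factor of 1200 instead of 1300. Under these values the simulated
#' band keeps moving instead of stabilizing.
#'
#' @return An `aeroband_params` object.
#' @export
mazzag_params <- function() {
  band_params(B_o = 1e8, K = 1e-9, v = 40, F_max = 0.5, F_min = 0.1,
              C_hat_max = 5, C_max = 0.5, henry_factor = 1200)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#' Convenience for one-at-a-time sensitivity runs.
#'
#' @param params an `aeroband_params` object.
#' @param ... named replacements, e.g. `K = 2e-9`.
#' @return An `aeroband_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "aeroband_params"))
  repl <- list(...)
  if (length(repl)) {
    unknown <- setdiff(names(repl), names(params))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p <- modifyList(unclass(params), repl)
  validate_params(p)
  class(p) <- "aeroband_params"
  p
}

#' Read / write a parameter configuration
#'
#' `write_params()` serializes a parameter set either as a flat `key = value`
#' text file (one parameter per line, `#` comments allowed) or as JSON;
#' `read_params()` reads either format back (auto-detected from content).
#' Keys are the field names of [band_params()]. Missing keys take their
#' base-case defaults, so a config file listing only the perturbed values is
#' valid.
#'
#' @param params an `aeroband_params` object.
#' @param path file path.
#' @param format `"conf"` (flat key = value) or `"json"`.
#' @return `read_params()` returns an `aeroband_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path, format = c("conf", "json")) {
  stopifnot(inherits(params, "aeroband_params"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- sprintf("%s = %s", names(params),
                     vapply(params, format_num, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 17, format = "g")

#' @rdname write_params
#' @export
read_params <- function(path) {
  txt <- readLines(path, warn = FALSE)
  first <- trimws(txt[nzchar(trimws(txt))][1])
  if (startsWith(first, "{")) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    txt <- sub("#.*$", "", txt)
    txt <- trimws(txt)
    txt <- txt[nzchar(txt)]
    kv <- strsplit(txt, "=", fixed = TRUE)
    if (any(lengths(kv) != 2L))
      stop("malformed config line: ", txt[lengths(kv) != 2L][1])
    vals <- lapply(kv, function(x) as.numeric(trimws(x[2])))
    names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  }
  do.call(band_params, vals)
}

#' @export
print.aeroband_params <- function(x, ...) {
  cat("Aerotaxis model parameters\n")
  lab <- c(B_o = "cells/ml", C_o = "% air oxygen", D = "um^2/s",
           K = "uM ml/(s cell)", v = "um/s", F_max_band = "1/s",
           F_max = "1/s", F_min = "1/s", C_hat_max = "%", C_max = "%",
           C_min = "%", C_hat_min = "%", S = "um", henry_factor = "uM/fraction")
  for (nm in names(lab))
    cat(sprintf("  %-12s %-12g %s\n", nm, x[[nm]], lab[[nm]]))
  invisible(x)
}
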