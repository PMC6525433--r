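test_that("FWHM crossings of a triangular profile follow hand geometry", {
  # peak 4 at x = 100 with half-width 50: the level-2 line crosses at 75 / 125
  g <- spatial_grid(25, 200)
  tri <- pmax(0, 4 * (1 - abs(g$centers - 100) / 50))
  band <- detect_band_fwhm(tri, g)
  expect_equal(band[["xL"]], 75)
  expect_equal(band[["xR"]], 125)
})

test_that("flat, empty and sub-threshold profiles yield no band", {
  g <- spatial_grid(64, 500)
  expect_null(detect_band_fwhm(rep(7e8, 64), g))
  expect_null(detect_band_fwhm(rep(0, 64), g))
  # a 20% bump over a flat background leaves everything above half max
  bump <- 1 + 0.2 * exp(-(g$centers - 250)^2 / (2 * 30^2))
  expect_null(detect_band_fwhm(bump, g))
  expect_error(detect_band_fwhm(rep(-1, 64), g), "nonnegative")
})

test_that("peak-to-background ratio gates mid-formation profiles", {
  # a weak peak flanked by depletion dips, with high plateaus beyond: the
  # half-max line crosses, but the background median disqualifies the peak
  g <- spatial_grid(100, 1000)
  x <- g$centers
  prof <- rep(0.8, 100)
  prof[x > 300 & x < 400] <- 0.2
  prof[x > 600 & x < 700] <- 0.2
  prof[x >= 400 & x <= 600] <- 1.0
  expect_null(detect_band_fwhm(prof, g))                        # 1.0 / 0.8 < 1.5
  band <- detect_band_fwhm(prof, g, min_peak_ratio = 1.2)       # 1.25 qualifies
  expect_false(is.null(band))
  expect_true(band[["xL"]] > 300 && band[["xR"]] < 700)
})

test_that("FWHM of a Gaussian equals 2 sqrt(2 ln 2) sigma to a cell width", {
  g <- spatial_grid(640, 5000)
  for (sigma in c(100, 150, 250)) {
    prof <- exp(-(g$centers - 2000)^2 / (2 * sigma^2))
    band <- detect_band_fwhm(prof, g)
    expect_lt(abs((band[["xR"]] - band[["xL"]]) - 2 * sqrt(2 * log(2)) * sigma),
              g$dx)
  }
})

test_that("detection depends only on profile shape, not scale or position", {
  g <- spatial_grid(640, 5000)
  prof <- exp(-(g$centers - 2000)^2 / (2 * 150^2))
  band <- detect_band_fwhm(prof, g)
  for (scale in c(1e-6, 3.7, 1e9))
    expect_equal(detect_band_fwhm(scale * prof, g), band)
  # translating the profile by whole cells translates the crossings exactly
  for (k in c(-40, 13, 128)) {
    shifted <- exp(-(g$centers - 2000 - k * g$dx)^2 / (2 * 150^2))
    expect_equal(detect_band_fwhm(shifted, g), band + k * g$dx)
  }
})

test_that("multi-peak profiles resolve to the outermost crossings", {
  g <- spatial_grid(400, 4000)
  x <- g$centers
  prof <- exp(-(x - 2000)^2 / (2 * 80^2)) + 0.8 * exp(-(x - 2350)^2 / (2 * 60^2))
  band <- detect_band_fwhm(prof, g)
  # the secondary lobe exceeds half max, so the right crossing lies beyond it
  expect_gt(band[["xR"]], 2350)
  expect_lt(band[["xL"]], 2000)
})

test_that("oxygen readouts interpolate the profile at the band anchors", {
  p <- band_params()
  g <- default_grid(p)
  # linear oxygen profile: interpolation must be exact at interior points
  st <- list(t = 0, R = rep(0, 640), L = rep(0, 640),
             C = percent_to_micromolar(21) * (1 - g$centers / 5000))
  ox <- oxygen_at_band(st, c(1000, 3000), p)
  expect_equal(ox[["C_left"]], 21 * (1 - 1000 / 5000))
  expect_equal(ox[["C_mid"]], 21 * (1 - 2000 / 5000))
  expect_equal(ox[["C_right"]], 21 * (1 - 3000 / 5000))
  expect_error(oxygen_at_band(st, NULL, p), "absent")
})

test_that("band oxygen range converts side readouts to micromolar", {
  rng <- band_oxygen_range_uM(c(C_left = 2.85, C_right = 0.09), 1300)
  expect_equal(rng[["low"]], 1.17)
  expect_equal(rng[["high"]], 37.05)
  expect_equal(band_oxygen_range_uM(c(0, 0)), c(low = 0, high = 0))
  # linear in the Henry factor
  expect_equal(band_oxygen_range_uM(c(2.85, 0.09), 650), rng / 2)
})

test_that("jump diagnostic counts step-like side movements", {
  mk <- function(xL, xR) data.frame(
    t_s = seq_along(xL), xL_um = xL, xR_um = xR,
    location_um = (xL + xR) / 2, width_um = xR - xL,
    peak_B_norm = 2, present = TRUE)
  dx <- 7.8125
  # perfectly constant sides
  expect_equal(smoothness_diagnostic(mk(rep(340, 50), rep(472, 50)), dx),
               c(left = 0, right = 0))
  # one side stepping by 2 dx once
  xR <- c(rep(472, 25), rep(472 + 2 * dx, 25))
  expect_equal(smoothness_diagnostic(mk(rep(340, 50), xR), dx),
               c(left = 0, right = 1))
  # movements below the threshold do not count
  set.seed(7)
  xL <- 340 + cumsum(runif(50, 0, 0.1))
  expect_equal(smoothness_diagnostic(mk(xL, rep(472, 50)), dx),
               c(left = 0, right = 0))
  absent <- mk(rep(340, 3), rep(472, 3))
  absent$present <- FALSE
  expect_error(smoothness_diagnostic(absent, dx), "at least two present")
})

test_that("the settled base-case band moves smoothly", {
  sim <- base_case_600()$sim
  jumps <- smoothness_diagnostic(sim$trace, jump_threshold = sim$grid$dx,
                                 after_s = 120)
  expect_equal(unname(jumps), c(0, 0))
})
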