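p_base <- band_params()
g_base <- default_grid(p_base)

test_that("initial state is uniform, symmetric and oxygen-free", {
  st <- initialize_state(p_base, g_base)
  expect_equal(st$t, 0)
  expect_equal(st$R + st$L, rep(7e8, 640))
  expect_equal(st$R - st$L, rep(0, 640))
  expect_equal(st$C, rep(0, 640))
  # total bacteria per unit cross-section = B_o * S
  expect_equal(sum(st$R + st$L) * g_base$dx, 7e8 * 5000)
})

test_that("stable time step combines the advective and diffusive bounds", {
  expect_equal(stable_dt(p_base, g_base, safety = 1),
               min(7.8125 / 20, 7.8125^2 / (2 * 2000)))
  # the diffusive bound binds at base values
  expect_equal(stable_dt(p_base, g_base, safety = 1), 7.8125^2 / 4000)
  expect_equal(7.8125 / 20, 0.390625)   # advective bound for reference
  # doubling D halves the step while diffusion-limited
  expect_equal(stable_dt(update_params(p_base, D = 4000), g_base, 1),
               stable_dt(p_base, g_base, 1) / 2)
  expect_equal(stable_dt(p_base, g_base, 0.5),
               0.5 * stable_dt(p_base, g_base, 1))
  expect_error(stable_dt(p_base, g_base, 0), "safety")
})

test_that("uniform populations with balanced frequencies are a fixed point", {
  st <- initialize_state(p_base, g_base)
  # uniform C = 1% sits in both high windows: f_RL = f_LR everywhere
  st$C <- rep(percent_to_micromolar(1), 640)
  dt <- stable_dt(p_base, g_base)
  out <- st
  for (i in 1:25) out <- advect_react_step(out, NULL, p_base, g_base, dt)
  expect_equal(out$R, st$R, tolerance = 1e-13)
  expect_equal(out$L, st$L, tolerance = 1e-13)
  # likewise with uniform C above the detectable range (both at F_min)
  st$C <- rep(percent_to_micromolar(21), 640)
  out <- advect_react_step(st, NULL, p_base, g_base, dt)
  expect_equal(out$R, st$R, tolerance = 1e-13)
})

test_that("a unit-Courant pulse advects exactly one cell per step", {
  # vanishing reversal frequencies isolate pure transport
  p <- band_params(F_min = 1e-300, F_max = 1e-300, F_max_band = 1e-300)
  g <- spatial_grid(50, 500)
  st <- initialize_state(p, g)
  st$R <- rep(0, 50); st$L <- rep(0, 50); st$C <- rep(0, 50)
  st$R[10] <- 1
  dt <- g$dx / p$v   # Courant number exactly 1
  out <- advect_react_step(st, NULL, p, g, dt)
  expect_equal(out$R[11], 1)
  expect_equal(sum(out$R), 1)
  expect_equal(out$L, rep(0, 50))
  # and a left-mover pulse moves one cell left
  st$R[10] <- 0; st$L[40] <- 1
  out <- advect_react_step(st, NULL, p, g, dt)
  expect_equal(out$L[39], 1)
})

test_that("transport conserves total bacteria for arbitrary states", {
  set.seed(42)
  g <- spatial_grid(80, 625)
  p <- p_base
  dt <- stable_dt(p, g)
  for (rep in 1:5) {
    st <- initialize_state(p, g)
    st$R <- runif(80) * 1e9
    st$L <- runif(80) * 1e9
    st$C <- runif(80) * percent_to_micromolar(21)
    band <- if (rep %% 2) c(200, 400) else NULL
    m0 <- sum(st$R + st$L)
    out <- st
    for (i in 1:20) out <- advect_react_step(out, band, p, g, dt)
    expect_equal(sum(out$R + out$L), m0, tolerance = 1e-12)
    expect_true(all(out$R >= 0) && all(out$L >= 0))
  }
})

test_that("oxygen stepping respects equilibria and the depletion gate", {
  g <- spatial_grid(64, 500)
  st <- initialize_state(p_base, g)
  dt <- stable_dt(p_base, g)
  # saturated capillary with no consumption is steady
  p0 <- update_params(p_base, K = 0)
  st$C <- rep(percent_to_micromolar(21), 64)
  out <- diffuse_consume_step(st, p0, g, dt)
  expect_equal(out$C, st$C)
  # a depleted cell is not consumed from, however many bacteria sit in it
  st2 <- st
  st2$C[30] <- 0
  st2$R[30] <- 1e12
  out2 <- diffuse_consume_step(st2, p_base, g, dt)
  # diffusion refills from neighbours; consumption cannot push below zero
  expect_true(out2$C[30] >= 0)
  # consumption is clamped to the oxygen available
  st3 <- st
  st3$C <- rep(1e-6, 64)
  st3$R <- rep(1e12, 64)
  out3 <- diffuse_consume_step(st3, p_base, g, dt)
  expect_true(all(out3$C >= 0))
})

test_that("with no bacteria the oxygen front matches the erfc solution", {
  sim <- diffusion_only_50s()
  p <- sim$params; g <- sim$grid
  st <- state_at(sim, 50)
  Co <- percent_to_micromolar(p$C_o, p$henry_factor)
  analytic <- Co * 2 * pnorm(g$centers / (2 * sqrt(p$D * 50)) * sqrt(2),
                             lower.tail = FALSE)
  near <- g$centers < g$S / 2   # before the sealed far wall is felt
  expect_lt(max(abs(st$C[near] - analytic[near])) / Co, 0.01)
})

test_that("compiled driver reproduces the pure-R step loop", {
  p <- update_params(p_base, S = 1250)
  g <- spatial_grid(160, 1250)
  t_end <- 30
  sim <- run_simulation(p, g, t_end = t_end, output_times = c(0, t_end))
  # replicate the drivers loop in R: detect band, transport, oxygen
  st <- initialize_state(p, g)
  dt_base <- stable_dt(p, g)
  t <- 0
  while (t < t_end - 1e-12) {
    band <- detect_band_fwhm(st$R + st$L, g)
    dt <- dt_base
    landing <- FALSE
    if (t + dt >= t_end - 1e-12) { dt <- t_end - t; landing <- TRUE }
    st <- advect_react_step(st, band, p, g, dt)
    st <- diffuse_consume_step(st, p, g, dt)
    t <- if (landing) t_end else t + dt
  }
  end <- state_at(sim, t_end)
  expect_equal(end$R, st$R, tolerance = 1e-10)
  expect_equal(end$L, st$L, tolerance = 1e-10)
  expect_equal(end$C, st$C, tolerance = 1e-10)
})

test_that("densities stay nonnegative and oxygen bounded by the meniscus value", {
  sim <- base_case_600()$sim
  Co <- percent_to_micromolar(21)
  for (st in sim$states) {
    expect_true(all(st$R >= 0) && all(st$L >= 0))
    expect_true(all(st$C >= 0))
    expect_true(all(st$C <= Co * (1 + 1e-12)))
  }
})

test_that("bacterial mass is conserved over long runs", {
  for (sim in list(base_case_600()$sim, mazzag_600()$sim)) {
    expect_lt(sim$diagnostics$conservation_rel_error, 1e-9)
  }
})

test_that("band location is grid-converged at the reference resolution", {
  b640 <- band_at(base_case_600()$sim, 300)
  b1280 <- band_at(base_case_1280(), 300)
  expect_lt(abs(b1280$location_um - b640$location_um) / b640$location_um, 0.03)
})

test_that("the base-case band is steady from 300 s to 600 s", {
  sim <- base_case_600()$sim
  expect_lt(abs(band_at(sim, 600)$location_um - band_at(sim, 300)$location_um),
            5)
})

test_that("simulated oxygen agrees with the quasi-steady two-point oracle", {
  # independent check of the C solver: given the simulated B profile at 300 s,
  # solve D C'' = K B theta(C), C(0) = Co, C and C' vanishing at the depletion
  # front, by direct quadrature, and compare with the simulated C profile.
  sim <- base_case_600()$sim
  p <- sim$params; g <- sim$grid
  st <- state_at(sim, 300)
  B <- st$R + st$L
  x <- g$centers; dx <- g$dx
  Co <- percent_to_micromolar(p$C_o, p$henry_factor)
  KD <- p$K / p$D
  C_of <- function(xf) {
    # C(x) = (K/D) int_x^xf (s - x) B(s) ds, cells weighted by overlap with [0, xf]
    w <- pmax(pmin(xf, x + dx / 2) - (x - dx / 2), 0) / dx
    function(xx) {
      keep <- x <= xf & x >= xx
      sum((x[keep] - xx) * B[keep] * w[keep]) * dx * KD
    }
  }
  xf <- uniroot(function(z) C_of(z)(0) - Co, c(g$dx, g$S))$root
  Cq <- vapply(x[x < xf], C_of(xf), numeric(1))
  expect_lt(max(abs(st$C[x < xf] - Cq)) / Co, 0.01)
})

test_that("unstable settings abort with a diagnostic rather than garbage", {
  g <- spatial_grid(50, 500)
  st <- initialize_state(p_base, g)
  # a step far beyond the CFL bound must be refused once profiles vary
  st$R <- rep(1e6, 50)
  st$R[20] <- 1e8
  expect_error(advect_react_step(st, NULL, p_base, g, dt = 2 * g$dx / p_base$v),
               "negative cell density")
  expect_error(run_simulation(p_base, t_end = -5), "t_end")
  expect_error(run_simulation(p_base, t_end = 10, output_times = c(0, 20)),
               "output_times")
  expect_error(run_simulation(p_base, spatial_grid(10, 100), t_end = 1),
               "grid spans")
})
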