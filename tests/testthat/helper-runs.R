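# Simulation runs shared across test files; each is computed once per test
# session and cached.  All runs are deterministic, so caching cannot hide
# order dependence between tests.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

base_case_600 <- function()
  cached_run("base600", run_base_case(t_end = 600))

mazzag_600 <- function()
  cached_run("mazzag600", run_mazzag_comparison(t_end = 600))

# the sensitivity rows exercised by the validation suite
validation_sweep <- function()
  cached_run("sweep", run_sensitivity_sweep(
    list(B_o = c(1e9, 3e8), K = c(2e-9, 6e-9), C_o = c(30, 10),
         C_hat_min = c(0.015, 0.005))))

base_case_1280 <- function()
  cached_run("g1280", run_simulation(band_params(), spatial_grid(1280, 5000),
                                     t_end = 300, output_times = c(0, 300)))

switch_fit_default <- function()
  cached_run("switchfit", fit_switches(407, 132))

# pure-diffusion run (no bacteria) for the closed-form oxygen check
diffusion_only_50s <- function() {
  cached_run("diff50", {
    p <- band_params()
    g <- default_grid(p)
    st0 <- initialize_state(p, g)
    st0$R[] <- 0
    st0$L[] <- 0
    run_simulation(p, g, t_end = 50, output_times = c(0, 50), state0 = st0)
  })
}
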