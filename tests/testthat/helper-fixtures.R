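# Shared fixtures: small, fast synthetic cohorts built in code.

# Wild-type-like spec at reduced sampling density (2 um window spacing)
# so cohort-level tests stay fast; all biological parameters are the
# package defaults.
test_spec <- function(n_embryos = 8, seed = 1L, ...) {
  cohort_spec(n_embryos = n_embryos, window_spacing = 2, seed = seed, ...)
}

# Fully deterministic spec: no shape variability, no noise.
noiseless_spec <- function(n_embryos = 1, seed = 1L, ...) {
  cohort_spec(n_embryos = n_embryos, window_spacing = 2, seed = seed,
              shape_sd = c(length = 0, lateral_diameter = 0,
                           dorsal_height = 0, ventral_height = 0),
              amplitude_cv = 0, window_cv_D = 0, window_cv_V = 0,
              hb_noise_sd = 0, ...)
}

# Tiny simulation setup (coarse grid, short schedule) for stepping tests.
small_sim_params <- function(grid_h = 10, dt = 2, ...) {
  sim_params(shape = shape_params(280, 110, 46, 64), grid_h = grid_h,
             dt = dt, source_center = c(40, 0, 0), source_radius = 25, ...)
}
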