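# shared fixtures, built in code once per test run

co_default <- optical_constants()
cal_default <- default_calibration()

# one small zero-noise micrograph with three E. huxleyi-scale coccoliths
make_three_coccolith_image <- function(noise_sd = 0, seed = 11) {
  set.seed(seed)
  specs <- list(
    coccolith_spec(2.4, aspect_ratio = 1.2, thickness_peak = 0.10,
                   orientation = 0.3),
    coccolith_spec(2.8, aspect_ratio = 1.3, thickness_peak = 0.12,
                   orientation = 1.1),
    coccolith_spec(3.2, aspect_ratio = 1.25, thickness_peak = 0.14,
                   orientation = 2.0)
  )
  maps <- lapply(specs, make_thickness_map, constants = co_default)
  render_image(maps, cal_default, co_default, noise_sd = noise_sd)
}

img3 <- make_three_coccolith_image()

quantize_grey_for_test <- function(g, bits = 16) {
  round(g * (2^bits - 1)) / (2^bits - 1)
}

# small factorial design used by pipeline/statistics tests
make_mini_design <- function(coupling = "decoupled", beta = 0.037,
                             n = 30L) {
  pops <- list(
    A = population_spec(n = n, mean_length = 2.9, sd_length = 0.45,
                        beta_salinity = beta, coupling = coupling,
                        coupling_c = 0.026, thickness_mean = 0.066,
                        sd_thickness = 0.005),
    B = population_spec(n = n, mean_length = 2.7, sd_length = 0.4,
                        beta_salinity = beta, coupling = coupling,
                        coupling_c = 0.026, thickness_mean = 0.08,
                        sd_thickness = 0.006)
  )
  study_design(pops, salinities = c(25, 34, 44))
}
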