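# Shared fast fixtures for the test suite.

# Single-layer analytic test models.
slab_model <- function(mua = 1, mus = 0, g = 0, d = 1, n = 1, n_above = 1) {
  skin_model(optical_layer("slab", d, 0, mua, mus, g, n), n_above = n_above)
}

semi_infinite_model <- function(mua, mus, g = 0, n = 1) {
  skin_model(optical_layer("semi", Inf, 0, mua, mus, g, n), n_above = 1)
}

# Short low-rate occlusion scenario: 20 ms windows hold integer cycles of
# both carriers at 10 kHz too, keeping property tests fast.
fast_scenario <- function(...) {
  occlusion_scenario(baseline_duration = 20, occlusion_duration = 80,
                     release_duration = 10, sample_rate = 10000, ...)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
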