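test_that("pure absorber follows the Beer-Lambert law", {
  cfg <- transport_config(n_packets = 4e4, seed = 5)
  for (tau in c(0.5, 1, 2)) {
    r <- run_transport(slab_model(mua = tau, d = 1), cfg)
    expect_equal(r$rd, 0)
    se <- sqrt(exp(-tau) * (1 - exp(-tau)) / cfg$n_packets)
    expect_close(r$tt, exp(-tau), 3 * se)
  }
})

test_that("tallied weight is conserved exactly and statistically", {
  cfg <- transport_config(n_packets = 1e4, seed = 2)
  m <- skin_model(rbind(optical_layer("a", 0.3, 0, 0.5, 20, 0.8, 1.4),
                        optical_layer("b", 2.0, 0, 0.2, 10, 0.9, 1.37)),
                  n_above = 1)
  r <- run_transport(m, cfg)
  total <- r$rsp + r$rd + r$tt + r$aa + r$roulette_net
  expect_equal(total, 1, tolerance = 1e-12)
  # roulette is unbiased: the imbalance is small at moderate N0
  expect_lt(abs(r$rsp + r$rd + r$tt + r$aa - 1), 0.005)
  # mismatched entry: normal-incidence specular reflection
  expect_equal(r$rsp, ((1 - 1.4) / (1 + 1.4))^2)
})

test_that("semi-infinite isotropic medium matches the radiative-transfer benchmark", {
  # plane albedo for single-scattering albedo 0.9, matched boundary;
  # 0.41495 from the Chandrasekhar H-function solution
  r <- run_transport(semi_infinite_model(0.1, 0.9),
                     transport_config(n_packets = 2e5, seed = 11))
  expect_close(r$rd, 0.41495, 0.004)
})

test_that("transport is bit-reproducible for a fixed seed", {
  cfg <- transport_config(n_packets = 5e3, seed = 77)
  m <- semi_infinite_model(0.5, 5, g = 0.9)
  a <- run_transport(m, cfg)
  b <- run_transport(m, cfg)
  expect_identical(a$exit_r, b$exit_r)
  expect_identical(a$exit_w, b$exit_w)
  expect_identical(a$aa, b$aa)
  cfg2 <- cfg; cfg2$seed <- 78
  expect_false(identical(run_transport(m, cfg2)$aa, a$aa))
})

test_that("radial binning uses 0.1 mm bins centered on multiples of 0.1", {
  p <- radial_profile(c(0.04, 0.06, 0.14, 0.16, 10), rep(0.2, 5),
                      n_packets = 10, bin_width = 0.1, max_radius = 5)
  expect_equal(p$bin_center[1:3], c(0, 0.1, 0.2))
  expect_equal(p$value[1], 0.02)        # r = 0.04 -> bin centered 0
  expect_equal(p$value[2], 0.04)        # 0.06 and 0.14 share bin 0.1
  expect_equal(p$value[3], 0.02)        # 0.16 -> bin centered 0.2
  expect_equal(attr(p, "overflow"), 0.02)
  expect_true(all(p$value >= 0))
  expect_lte(sum(p$value) + attr(p, "overflow"), 1)
})

test_that("averaging runs equals pooling and is seed-stable", {
  m <- semi_infinite_model(0.2, 1.8)
  cfg <- transport_config(n_packets = 5e3, seed = 30)
  one <- average_runs(m, cfg, n_runs = 1)
  expect_equal(one$profile$value, run_transport(m, cfg)$profile$value)

  nr <- 4
  avg <- average_runs(m, cfg, n_runs = nr)
  pooled_r <- unlist(lapply(avg$runs, `[[`, "exit_r"))
  pooled_w <- unlist(lapply(avg$runs, `[[`, "exit_w"))
  pooled <- radial_profile(pooled_r, pooled_w, nr * cfg$n_packets,
                           cfg$bin_width, cfg$max_radius)
  expect_equal(avg$profile$value, pooled$value, tolerance = 1e-12)

  cfg2 <- cfg; cfg2$seed <- 4000
  avg2 <- average_runs(m, cfg2, n_runs = nr)
  tot1 <- sum(avg$profile$value); tot2 <- sum(avg2$profile$value)
  se <- sqrt(sum(avg$profile$stderr^2) + sum(avg2$profile$stderr^2))
  expect_close(tot1, tot2, 3 * se)
})

test_that("annulus intensity sums raw exits inside the window", {
  m <- semi_infinite_model(0.2, 1.8)
  r <- run_transport(m, transport_config(n_packets = 5e3, seed = 8))
  expect_equal(annulus_intensity(r, 0, Inf), r$rd)
  hand <- sum(r$exit_w[r$exit_r >= 0.5 & r$exit_r <= 1.2]) / r$n_packets
  expect_equal(annulus_intensity(r, 0.5, 1.2), hand)
  expect_error(annulus_intensity(r, 1.2, 0.5), "r_min")
  # empty tally
  ra <- run_transport(slab_model(mua = 1, d = 1),
                      transport_config(n_packets = 100, seed = 1))
  expect_equal(annulus_intensity(ra, 0.5, 1.2), 0)
})

test_that("configuration is validated", {
  expect_error(transport_config(n_packets = 0), "n_packets")
  expect_error(transport_config(roulette_threshold = 2), "roulette")
  expect_error(transport_config(roulette_m = 1), "roulette_m")
})
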