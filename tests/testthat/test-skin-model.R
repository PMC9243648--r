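test_that("canonical model reproduces the printed seven-layer table", {
  m <- canonical_skin_model(1.0, 590)
  expect_equal(nrow(m$layers), 7L)
  expect_equal(m$layers$name,
               c("stratum corneum", "vital epidermis",
                 "upper vascular plexus", "reticular dermis",
                 "deep vascular plexus", "subcutaneous fat", "muscle"))
  uvp <- m$layers[m$layers$name == "upper vascular plexus", ]
  expect_equal(uvp$d, 0.1)
  expect_equal(uvp$cb, 0.20)
  expect_equal(uvp$mua, 0.233)
  expect_equal(uvp$mus, 35)
  expect_equal(uvp$g, 0.95)
  expect_equal(uvp$n, 1.39)

  hypo <- canonical_skin_model(0.1, 780)$layers
  expect_equal(hypo$cb[3], 0.020)
  expect_equal(hypo$mua[3], 0.026)

  # muscle properties identical at every blood scale
  for (wl in c(590, 780)) {
    mus_rows <- vapply(c(0.1, 1, 3), function(s) {
      canonical_skin_model(s, wl)$layers$mua[7]
    }, numeric(1))
    expect_equal(mus_rows, rep(mus_rows[1], 3))
  }
  expect_equal(canonical_skin_model(1, 590)$layers$mua[7], 0.442)

  # epidermis 780 nm column quirk is reproduced verbatim, not smoothed
  expect_equal(canonical_skin_model(0.1, 780)$layers$mua[2], 0.338)
  expect_equal(canonical_skin_model(1, 780)$layers$mua[2], 0.339)
  expect_equal(canonical_skin_model(3, 780)$layers$mua[2], 0.338)
})

test_that("full printed absorption columns match at the three scales", {
  ref <- read.csv(system.file("extdata", "seven_layer_skin_model.csv",
                              package = "lrbc"), check.names = FALSE)
  for (wl in c("590", "780")) {
    for (sc in c("0.1" = 0.1, "1" = 1, "3" = 3)) {
      m <- canonical_skin_model(sc, as.numeric(wl))
      col <- paste0("mua", wl, "_s", format(sc))
      expect_equal(m$layers$mua, ref[[col]])
      expect_equal(m$layers$cb, ref[[paste0("cb_s", format(sc))]])
    }
  }
})

test_that("linear mixing rule and fitted coefficients behave", {
  expect_equal(mix_absorption(0, 0.5, 0.03), 0.03)
  expect_equal(mix_absorption(1, 0.5, 0.03), 0.5)
  expect_error(mix_absorption(1.2, 0.5, 0.03), "0, 1")

  # 2x2 solve from the upper-plexus 590 nm rows
  co <- blood_tissue_coefficients(590)
  up <- co[co$layer == "upper vascular plexus", ]
  expect_equal(up$mua_blood, 1.046333, tolerance = 1e-6)
  expect_equal(up$mua_tissue, 0.0296667, tolerance = 1e-5)
  expect_equal(mix_absorption(0.02, up$mua_blood, up$mua_tissue), 0.050)
  expect_equal(mix_absorption(0.20, up$mua_blood, up$mua_tissue), 0.233)

  # monotone nondecreasing in cb when blood absorbs more than tissue
  cb <- seq(0, 1, by = 0.05)
  expect_true(all(diff(mix_absorption(cb, 1.0, 0.03)) >= 0))
})

test_that("intermediate scales interpolate and warn about extrapolation", {
  expect_message(m2 <- canonical_skin_model(2, 590), "interpolated")
  co <- blood_tissue_coefficients(590)
  i <- which(m2$layers$name == "deep vascular plexus")
  expect_equal(m2$layers$cb[i], 0.20)
  expect_equal(m2$layers$mua[i],
               mix_absorption(0.20, co$mua_blood[i], co$mua_tissue[i]))
  # bloodless and muscle layers untouched
  expect_equal(m2$layers$mua[c(1, 2, 7)],
               canonical_skin_model(1, 590)$layers$mua[c(1, 2, 7)])
  expect_error(canonical_skin_model(5, 590), "0.1, 3")
  expect_error(canonical_skin_model(1, 632), "590 or 780")
})

test_that("config round trip is bit-exact", {
  m <- suppressMessages(canonical_skin_model(1.7, 780))
  m$layers$mua[3] <- m$layers$mua[3] * (1 + 1e-15)  # perturb last bits
  path <- tempfile(fileext = ".cfg")
  write_skin_model(m, path)
  m2 <- read_skin_model(path)
  expect_identical(m2$layers$d, m$layers$d)
  expect_identical(m2$layers$cb, m$layers$cb)
  expect_identical(m2$layers$mua, m$layers$mua)
  expect_identical(m2$layers$mus, m$layers$mus)
  expect_identical(m2$layers$g, m$layers$g)
  expect_identical(m2$layers$n, m$layers$n)
  expect_identical(m2$n_above, m$n_above)
  expect_identical(m2$wavelength, m$wavelength)
  expect_identical(m2$layers$name, m$layers$name)
})

test_that("layer validation rejects unphysical inputs", {
  expect_error(optical_layer("x", -1, 0, 1, 1, 0, 1), "thickness")
  expect_error(optical_layer("x", 1, 1.5, 1, 1, 0, 1), "blood fraction")
  expect_error(optical_layer("x", 1, 0, -1, 1, 0, 1), "coefficients")
  expect_error(optical_layer("x", 1, 0, 1, 1, 2, 1), "anisotropy")
  expect_error(optical_layer("x", 1, 0, 1, 1, 0, 0.5), "refractive")
  # semi-infinite layer only allowed last
  lay <- rbind(optical_layer("a", Inf, 0, 1, 1, 0, 1),
               optical_layer("b", 1, 0, 1, 1, 0, 1))
  expect_error(skin_model(lay), "last layer")
})
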