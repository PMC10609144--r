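test_that("xyY -> XYZ lifts chromaticity correctly", {
  # equal-energy point maps to equal tristimulus values
  ee <- xyY_to_XYZ(1 / 3, 1 / 3, 100)
  expect_equal(unlist(ee), c(X = 100, Y = 100, Z = 100))

  # deep-red laser primary at its experimental luminance
  red <- xyY_to_XYZ(0.7077, 0.2834, 40.49)
  expect_equal(red$X, 101.11, tolerance = 1e-4)
  expect_equal(red$Y, 40.49)

  # zero luminance gives the zero vector regardless of chromaticity
  z <- xyY_to_XYZ(0.2, 0.4, 0)
  expect_equal(unlist(z), c(X = 0, Y = 0, Z = 0))

  expect_error(xyY_to_XYZ(0.3, 0, 10), "degenerate")
  expect_error(xyY_to_XYZ(0.3, 0.3, -1), ">= 0")
})

test_that("xy <-> u'v' conversions match the standard projective forms", {
  ee <- xy_to_uv(1 / 3, 1 / 3)
  expect_equal(ee$up, 4 / 19, tolerance = 1e-12)
  expect_equal(ee$vp, 9 / 19, tolerance = 1e-12)

  red <- xy_to_uv(0.7077, 0.2834)
  expect_equal(red$up, 0.5678, tolerance = 1e-3)

  # round trip over a grid of valid chromaticities
  g <- expand.grid(x = seq(0.05, 0.7, by = 0.05), y = seq(0.05, 0.8, by = 0.05))
  g <- g[g$x + g$y <= 0.99, ]
  uv <- xy_to_uv(g$x, g$y)
  back <- uv_to_xy(uv$up, uv$vp)
  expect_equal(back$x, g$x, tolerance = 1e-12)
  expect_equal(back$y, g$y, tolerance = 1e-12)

  expect_error(xy_to_uv(0.9, -0.4), "degenerate")
})

test_that("spectral luminance integral behaves photometrically", {
  wl <- seq(380, 780, by = 1)
  zero <- data.frame(wavelength_nm = wl, radiance = 0)
  expect_equal(luminance_from_spectrum(zero), 0)

  # narrow line at the V(lambda) peak with unit integrated radiance
  line <- data.frame(wavelength_nm = c(554, 555, 556), radiance = c(0, 1, 0))
  expect_equal(luminance_from_spectrum(line), 683, tolerance = 0.005)

  # linearity and additivity of the integral
  s1 <- data.frame(wavelength_nm = wl, radiance = exp(-((wl - 550) / 40)^2))
  s2 <- data.frame(wavelength_nm = wl, radiance = 0.3 + 1e-3 * (wl - 380))
  L1 <- luminance_from_spectrum(s1)
  L2 <- luminance_from_spectrum(s2)
  both <- data.frame(wavelength_nm = wl, radiance = s1$radiance + s2$radiance)
  expect_equal(luminance_from_spectrum(both), L1 + L2, tolerance = 1e-9)
  scaled <- data.frame(wavelength_nm = wl, radiance = 2.5 * s1$radiance)
  expect_equal(luminance_from_spectrum(scaled), 2.5 * L1, tolerance = 1e-9)

  expect_error(luminance_from_spectrum(data.frame(wavelength_nm = numeric(0),
                                                  radiance = numeric(0))),
               "empty")
  expect_error(luminance_from_spectrum(
    data.frame(wavelength_nm = c(500, 400), radiance = c(1, 1))), "increasing")
})

test_that("V(lambda) comes from the embedded observer table", {
  expect_equal(cie_vlambda(555), 1, tolerance = 1e-4)
  expect_equal(cie_vlambda(c(300, 800)), c(0, 0))
  # ybar of the CMF at 5 nm equals V(lambda) at the knots
  cmf <- cie_cmf(5)
  expect_equal(cie_vlambda(cmf$wavelength_nm), cmf$ybar, tolerance = 1e-12)
})
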