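test_that("hue-quadrature factor q(theta) evaluates the Fourier series", {
  # at theta = 0 only the cosine constants survive
  expect_equal(nayatani_q(0),
               -0.01585 - 0.03017 - 0.04556 - 0.02667 - 0.00295)

  th <- seq(-5, 5, by = 0.37)
  expect_equal(nayatani_q(th + 2 * pi), nayatani_q(th), tolerance = 1e-12)

  # averaging over a full period leaves only the constant term
  grid <- 2 * pi * (0:359) / 360
  expect_equal(mean(nayatani_q(grid)), -0.01585, tolerance = 1e-12)
})

test_that("adaptation factor K_Br has the right anchors and asymptote", {
  expect_equal(nayatani_kbr(0), 0.2717)
  # unity near La = 63.66 cd/m2 (where La^0.4495 = 6.469)
  expect_equal(nayatani_kbr(63.66), 1, tolerance = 1e-3)

  La <- 10^seq(-2, 6, by = 0.25)
  k <- nayatani_kbr(La)
  expect_true(all(diff(k) > 0))
  expect_true(all(k < 0.2717 * 6.362))
  expect_equal(nayatani_kbr(1e8), 0.2717 * 6.362, tolerance = 1e-2)
  expect_error(nayatani_kbr(-5), ">= 0")
})

test_that("chromatic saturation s_uv is a distance from the white point", {
  ctx <- nayatani_context()
  expect_equal(nayatani_suv(0.3127, 0.3290, ctx), 0)

  # rotation of (u'v') about the white point preserves s_uv
  uvw <- ctx$white_uv
  r <- 0.05
  for (ang in seq(0, 2 * pi, length.out = 9)) {
    pt <- uv_to_xy(uvw[["up"]] + r * cos(ang), uvw[["vp"]] + r * sin(ang))
    expect_equal(nayatani_suv(pt$x, pt$y, ctx), 13 * r, tolerance = 1e-9)
  }

  # hand evaluation on the red laser primary: 13 x Euclidean u'v' distance
  uv <- xy_to_uv(0.7077, 0.2834)
  d <- c(uv$up - uvw[["up"]], uv$vp - uvw[["vp"]])
  expect_equal(nayatani_suv(0.7077, 0.2834, ctx), 13 * sqrt(sum(d^2)),
               tolerance = 1e-12)
})

test_that("equivalent-luminance ratio has the achromatic identity", {
  ctx <- nayatani_context()
  for (m in c("VAC", "VCC")) {
    r <- nayatani_ratio(0.3127, 0.3290, ctx, method = m)
    expect_lt(abs(r - 1), 2e-4)
  }
})

test_that("VCC does not exceed VAC where q(theta) is positive", {
  ctx <- nayatani_context()
  g <- expand.grid(x = seq(0.1, 0.6, by = 0.05), y = seq(0.1, 0.7, by = 0.05))
  g <- g[g$x + g$y <= 0.9, ]
  uvw <- ctx$white_uv
  uv <- xy_to_uv(g$x, g$y)
  theta <- atan2(uv$vp - uvw[["vp"]], uv$up - uvw[["up"]])
  keep <- nayatani_q(theta) > 0
  vac <- nayatani_ratio(g$x[keep], g$y[keep], ctx, "VAC")
  vcc <- nayatani_ratio(g$x[keep], g$y[keep], ctx, "VCC")
  expect_true(all(vcc <= vac))
})

test_that("the ratio grows with saturation when the hue term is favorable", {
  ctx <- nayatani_context()
  # walk from the white point toward the red primary
  t <- seq(0, 1, by = 0.1)
  xs <- 0.3127 + t * (0.7077 - 0.3127)
  ys <- 0.3290 + t * (0.2834 - 0.3290)
  r <- nayatani_ratio(xs, ys, ctx, "VAC")
  expect_true(all(diff(r) > 0))
})
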