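test_that("viewing-condition derivation matches the closed forms", {
  vc <- default_vc()
  expect_equal(vc$n, 0.2)
  expect_equal(vc$z, 1.48 + sqrt(0.2))
  expect_equal(vc$N_bb, 0.725 * 5^0.2)
  expect_gt(vc$A_w, 0)
  expect_true(vc$D >= 0 && vc$D <= 1)

  # zero adapting luminance annihilates both F_L terms
  vc0 <- cam16_conditions(La = 0)
  expect_equal(vc0$F_L, 0)

  # at high adapting luminance D tends to the surround's F from below
  vc_hi <- cam16_conditions(La = 500, surround = "dark")
  expect_lt(vc_hi$D, 0.8)
  expect_equal(vc_hi$D, 0.8, tolerance = 1e-3)
  expect_equal(cam16_conditions(La = 5000)$D, 0.8, tolerance = 1e-10)

  expect_error(cam16_conditions(white_L = 0), "positive")
  expect_error(cam16_conditions(Yb = 0), "Yb")
})

test_that("the adopted white maps to J = 100 and the white brightness", {
  for (sur in c("dark", "dim", "average")) {
    vc <- cam16_conditions(surround = sur)
    w <- cam16_appearance(
      data.frame(x = vc$white_x, y = vc$white_y, L = vc$white_L), vc)
    expect_equal(w$J, 100)
    expect_equal(w$Q, (4 / vc$c) * (vc$A_w + 4) * vc$F_L^0.25)
    expect_equal(w$Q, cam16_brightness(100, vc))
  }
})

test_that("full adaptation maps stimuli proportional to the white to C ~ 0", {
  # force D = 1 via a very high adapting luminance, average surround
  vc <- cam16_conditions(La = 1e5, surround = "average")
  expect_equal(vc$D, 1)
  app <- cam16_appearance(
    data.frame(x = vc$white_x, y = vc$white_y, L = c(20, 80, 160)), vc)
  expect_lt(max(abs(app$a)), 1e-10)
  expect_lt(max(abs(app$b)), 1e-10)
  expect_lt(max(app$C), 1e-8)
})

test_that("brightness follows the square-root law in lightness", {
  vc <- default_vc()
  J <- c(3, 10, 25, 60, 90)
  expect_equal(cam16_brightness(4 * J, vc) / cam16_brightness(J, vc),
               rep(2, length(J)))
  expect_equal(cam16_brightness(0, vc), 0)
  expect_error(cam16_brightness(-1, vc), ">= 0")
})

test_that("achromatic brightness is strictly increasing and invertible", {
  vc <- default_vc()
  L <- c(0.5, 2, 10, 40, 100, 180, 250, 400)
  q <- cam16_appearance(
    data.frame(x = vc$white_x, y = vc$white_y, L = L), vc)$Q
  expect_true(all(diff(q) > 0))

  back <- achromatic_luminance(q, vc)
  expect_equal(back, L, tolerance = 1e-6)
  expect_equal(achromatic_luminance(0, vc), 0)
  # larger target brightness gives strictly larger luminance
  expect_true(all(diff(achromatic_luminance(sort(q), vc)) > 0))
  expect_error(achromatic_luminance(1e6, vc), "range")
})

test_that("hue angle is consistent with the opponent signals", {
  vc <- default_vc()
  app <- cam16_appearance(table2(), vc)
  expect_true(all(app$h >= 0 & app$h < 360))
  h_re <- (atan2(app$b, app$a) * 180 / pi) %% 360
  expect_equal(app$h, h_re)
  # negating both opponent signals rotates the hue by 180 degrees
  h_neg <- (atan2(-app$b, -app$a) * 180 / pi) %% 360
  expect_equal((h_neg - app$h) %% 360, rep(180, nrow(app)))
})

test_that("forward model agrees with the independent reference values", {
  d <- read.csv(test_path("fixtures", "cam16_reference.csv"))
  expect_equal(nrow(d), 100)
  for (g in split(d, list(d$white_x, d$white_L), drop = TRUE)) {
    vc <- cam16_conditions(g$white_x[1], g$white_y[1], g$white_L[1],
                           g$La[1], g$Yb[1], g$surround[1])
    app <- cam16_appearance(g[, c("x", "y", "L")], vc)
    # 4 significant figures = relative agreement well below 5e-4
    expect_lt(max(rel_diff(app$J, g$J)), 1e-6)
    expect_lt(max(rel_diff(app$C, g$C)), 1e-6)
    expect_lt(max(rel_diff(app$Q, g$Q)), 1e-6)
    dh <- pmin(abs(app$h - g$h), 360 - abs(app$h - g$h))
    expect_lt(max(dh), 1e-6)
  }
})

test_that("negative tristimulus input is rejected", {
  vc <- default_vc()
  expect_error(cam16_appearance(data.frame(X = -1, Y = 5, Z = 2), vc),
               "negative")
})
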