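test_that("scale factor is the least-squares projection coefficient", {
  expect_equal(scale_factor(c(1, 2), c(1, 2)), 1)
  expect_equal(scale_factor(c(1, 2), c(2, 4)), 0.5)
  # recovers an arbitrary global rescaling
  ref <- c(80, 120, 160, 210)
  expect_equal(scale_factor(ref, ref / 3.7), 3.7)
  expect_error(scale_factor(c(1, 2), c(0, 0)), "zero")
  expect_error(scale_factor(1:3, 1:2), "equal length")
})

test_that("agreement CV is zero for proportional series and scales right", {
  ref <- c(100, 120, 150, 90)
  expect_equal(agreement_cv(ref, ref / 2)$cv, 0, tolerance = 1e-10)

  # first-order behavior: symmetric +-e perturbation around f = 1
  e <- 1e-3
  r <- agreement_cv(c(1, 1), c(1 + e, 1 - e))
  expect_equal(r$cv, 100 * e, tolerance = 0.01 * 100 * e)

  # joint rescaling of both series leaves the CV unchanged
  pred <- c(90, 140, 130, 100)
  expect_equal(agreement_cv(3 * ref, 3 * pred)$cv,
               agreement_cv(ref, pred)$cv, tolerance = 1e-12)
  # rescaling pred alone is absorbed by f
  expect_equal(agreement_cv(ref, 10 * pred)$cv,
               agreement_cv(ref, pred)$cv, tolerance = 1e-12)
})

test_that("published per-observer CVs average to the reported mean", {
  t3 <- hk_dataset("table3")
  expect_equal(nrow(t3), 16)
  expect_equal(round(mean(t3$cv), 1), 15.9)
})

test_that("per-observer CV is zero for consistent panels", {
  base <- c(100, 130, 90, 160, 120)
  m <- rbind(base, base, base)
  d <- list(records = NULL, per_observer = m)
  io <- interobserver_cv(d)
  expect_equal(io$cv, rep(0, 3), tolerance = 1e-10)

  # an observer uniformly scaled by 2 is still in perfect agreement
  m2 <- rbind(base, base, 2 * base)
  io2 <- interobserver_cv(list(per_observer = m2))
  expect_equal(io2$cv[3], 0, tolerance = 1e-10)
  expect_error(interobserver_cv(list(per_observer = NULL)), "per-observer")
})

test_that("model evaluation wires predictions and references correctly", {
  vc <- default_vc()
  ev <- evaluate_brightness_model(table2(), vc)
  expect_s3_class(ev, "hk_eval")
  expect_equal(ev$n, 30)
  expect_equal(ev$stimuli$ref, table2()$matched_L)
  expect_equal(ev$stimuli$pred, ev$stimuli$L_pred)

  # appearance mode compares brightness against brightness
  ev_app <- evaluate_brightness_model(table2(), vc, mode = "appearance")
  wq <- cam16_appearance(
    data.frame(x = vc$white_x, y = vc$white_y, L = table2()$matched_L), vc)$Q
  expect_equal(ev_app$stimuli$ref, wq)

  # the compensated model outperforms plain CAM16 on the matching data
  cv_cam16 <- evaluate_brightness_model(table2(), vc, model = "cam16")$cv
  expect_lt(ev$cv, cv_cam16)

  expect_error(evaluate_brightness_model(table2()[0, ], vc), "empty|positive")
})

test_that("tidiers return one-row summaries and per-stimulus tables", {
  vc <- default_vc()
  ev <- evaluate_brightness_model(table2(), vc)
  g <- glance(ev)
  expect_equal(nrow(g), 1)
  expect_named(g, c("model", "mode", "cv", "f", "n"))
  td <- tidy(ev)
  expect_equal(nrow(td), 30)
  expect_true(all(c("ref", "pred") %in% names(td)))
})
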