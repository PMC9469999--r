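circle_contour <- function(r, center = c(64.5, 64.5), n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] - r * sin(th), center[2] + r * cos(th)))
}

test_that("ESL equals the subtended arc fraction on symmetric geometries", {
  endo <- circle_contour(20)
  e <- esl(endo, wiper_pair(0, pi / 2), lv_center = c(64.5, 64.5))
  expect_equal(e$esl_percent, 25, tolerance = 1e-6)
  expect_equal(esl(endo, wiper_pair(0, 2 * pi))$esl_percent, 100)
  # empty lesion mask: zero, not an error
  e0 <- esl(endo, lesion_mask = matrix(FALSE, 128, 128),
            lv_center = c(64.5, 64.5))
  expect_equal(e0$esl_percent, 0)
})

test_that("ESL on an ellipse matches dense arc-length integration", {
  a <- 30; b <- 15  # 2:1 axes
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  ell <- contour(cbind(64.5 - b * sin(th), 64.5 + a * cos(th)))
  e <- esl(ell, wiper_pair(0, pi / 2), lv_center = c(64.5, 64.5))

  # independent Riemann-sum oracle on a fine parameterization
  tt <- seq(0, 2 * pi, length.out = 200001)
  x <- a * cos(tt); y <- b * sin(tt)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  midang <- atan2((y[-1] + y[-length(y)]) / 2, (x[-1] + x[-length(x)]) / 2) %% (2 * pi)
  frac_oracle <- sum(seg[midang <= pi / 2]) / sum(seg) * 100
  expect_lt(abs(e$esl_percent - frac_oracle), 0.5)
})

test_that("ESA closes the analytic cylinder and the summation identity", {
  r <- 20; k <- 5; spacing <- 8
  per <- rep(2 * pi * r, k)
  out <- esa(rep(25, k), per, spacing)
  expect_equal(out$esa_mm2, 0.25 * 2 * pi * r * k * spacing)
  expect_equal(out$esa_percent, 25)

  one <- esa(40, 100, 8)
  expect_equal(one$esa_mm2, 0.4 * 100 * 8)

  set.seed(3)
  esls <- runif(7, 0, 100); pers <- runif(7, 50, 150)
  out2 <- esa(esls, pers, 8)
  expect_equal(out2$esa_mm2, sum(esls / 100 * pers) * 8, tolerance = 1e-9)
  # percent ESA is the perimeter-weighted mean of slice ESLs
  expect_equal(out2$esa_percent, sum(esls / 100 * pers) / sum(pers) * 100,
               tolerance = 1e-12)
})

test_that("mask-mode ESL recovers the wedge extent on a phantom", {
  ph <- generate_phantom(bench_spec())
  tr <- ph$truth[[1]]
  endo <- circle_contour(20)
  e <- esl(endo, lesion_mask = class_mask(tr, "lesion"),
           lv_center = c(64.5, 64.5))
  expect_equal(e$esl_percent, 70 / 360 * 100, tolerance = 1.5)
})

test_that("transmural extent reads full, half and sinusoidal wedges", {
  full <- generate_phantom(phantom_spec(lesion_extent_deg = 90))
  tm <- transmurality(class_mask(full$truth[[1]], "myocardium"),
                      class_mask(full$truth[[1]], "infarct"), c(64.5, 64.5))
  expect_equal(attr(tm, "mean_transmurality"), 1.0, tolerance = 0.05)
  # wedge sectors 1.0, remote sectors 0
  expect_true(all(stats::na.omit(tm$fraction[tm$fraction > 0.5]) > 0.9))

  half <- generate_phantom(phantom_spec(lesion_extent_deg = 90,
                                        transmural_mean = 0.5))
  tm2 <- transmurality(class_mask(half$truth[[1]], "myocardium"),
                       class_mask(half$truth[[1]], "infarct"), c(64.5, 64.5))
  expect_equal(attr(tm2, "mean_transmurality"), 0.5, tolerance = 0.05)

  sine <- generate_phantom(phantom_spec(lesion_extent_deg = 120,
                                        transmural_mean = 0.6,
                                        transmural_amplitude = 0.2))
  tm3 <- transmurality(class_mask(sine$truth[[1]], "myocardium"),
                       class_mask(sine$truth[[1]], "infarct"), c(64.5, 64.5), 36)
  expect_equal(attr(tm3, "mean_transmurality"), 0.6, tolerance = 0.05)

  # sector with no myocardium is missing, not zero
  myo_half <- class_mask(full$truth[[1]], "myocardium")
  myo_half[, 1:64] <- FALSE
  tmm <- transmurality(myo_half, class_mask(full$truth[[1]], "infarct") & myo_half,
                       c(64.5, 64.5), 8)
  expect_true(any(is.na(tmm$fraction)))
})

test_that("wiper clipping reclassifies outside pixels and only those", {
  ph <- generate_phantom(phantom_spec(lesion_extent_deg = 90))
  tr <- ph$truth[[1]]
  n_lesion <- sum(class_mask(tr, "lesion"))

  covering <- clip_to_wipers(tr, wiper_pair(-pi / 2, pi / 2), c(64.5, 64.5))
  expect_identical(covering$labels, tr$labels)

  disjoint <- clip_to_wipers(tr, wiper_pair(pi / 2, pi), c(64.5, 64.5))
  expect_equal(sum(class_mask(disjoint, "lesion")), 0)
  expect_equal(sum(class_mask(disjoint, "myocardium")),
               sum(class_mask(tr, "myocardium")))

  half <- clip_to_wipers(tr, wiper_pair(0, pi / 4), c(64.5, 64.5))
  expect_equal(sum(class_mask(half, "lesion")) / n_lesion, 0.5,
               tolerance = 0.03)
  # never creates lesion pixels
  expect_true(all(class_mask(half, "lesion") <= class_mask(tr, "lesion")))
})
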