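test_that("two-click template builds concentric circles at the 0.6 ratio", {
  seg <- init_lv_template(c(64, 64), c(64, 94), shape = c(128, 128))
  th <- seq(0, 2 * pi, length.out = 64)
  expect_equal(radius_at(seg$polar$epi, th), rep(30, 64), tolerance = 1e-6)
  expect_equal(radius_at(seg$polar$endo, th), rep(18, 64), tolerance = 1e-6)
  expect_error(init_lv_template(c(64, 64), c(64, 64)), "distinct")
  expect_error(init_lv_template(c(64, 64), c(64, 200), shape = c(128, 128)),
               "outside")
  # endo strictly inside epi by construction
  for (epi_pt in list(c(10, 64), c(100, 100), c(64, 70)))
    expect_true(all(radius_at(init_lv_template(c(64, 64), epi_pt)$polar$endo, th) <
                      radius_at(init_lv_template(c(64, 64), epi_pt)$polar$epi, th)))
})

test_that("active contour locks onto a noiseless ring to subpixel accuracy", {
  ring <- make_ring_image()
  init <- init_lv_template(c(64.5, 64.5), c(64.5, 97.5), c(128, 128))
  init$polar$endo <- polar_contour(c(64.5, 64.5), rep(17, 12))
  seg <- evolve_beas(ring, init)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  expect_lt(mean(abs(radius_at(seg$polar$epi, th) - 30)), 0.5)
  expect_lt(mean(abs(radius_at(seg$polar$endo, th) - 20)), 0.5)
  expect_true(attr(seg, "converged"))
  # energy non-increasing across accepted iterations
  expect_true(all(diff(attr(seg, "energy")) <= 1e-6))
  # endo strictly inside epi
  expect_true(all(radius_at(seg$polar$endo, th) < radius_at(seg$polar$epi, th)))
})

test_that("the true boundary is a fixed point of the evolution", {
  ring <- make_ring_image()
  init <- init_lv_template(c(64.5, 64.5), c(64.5, 94.5), c(128, 128))
  init$polar$endo <- polar_contour(c(64.5, 64.5), rep(20, 12))
  seg <- evolve_beas(ring, init)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  expect_lt(mean(abs(radius_at(seg$polar$epi, th) - 30)), 0.25)
  expect_lt(mean(abs(radius_at(seg$polar$endo, th) - 20)), 0.25)
  expect_lt(attr(seg, "iterations"), 10)
})

test_that("evolution tolerates a heterogeneous wall with a lesion", {
  ph <- generate_phantom(bench_spec(target_cnr = 6, seed = 2))
  init <- init_lv_template(c(64.5, 64.5), c(64.5, 96.5), c(128, 128))
  init$polar$endo <- polar_contour(c(64.5, 64.5), rep(19, 12))
  expect_no_error(seg <- evolve_beas(ph$stack$slices[[1]], init))
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  expect_true(all(radius_at(seg$polar$endo, th) < radius_at(seg$polar$epi, th)))
})

test_that("myocardium mask honours mm offsets and is antitone in them", {
  seg0 <- init_lv_template(c(64.5, 64.5), c(64.5, 94.5))
  seg0$polar$endo <- polar_contour(c(64.5, 64.5), rep(20, 12))
  seg0$endo <- as_contour(seg0$polar$endo)
  m0 <- myocardium_mask(seg0, c(128, 128))
  rad <- radius_grid()
  expect_true(all(rad[m0] > 19 & rad[m0] < 31))

  seg2 <- seg0; seg2$endo_offset_mm <- 2; seg2$epi_offset_mm <- 2
  m2 <- myocardium_mask(seg2, c(128, 128))
  expect_true(all(rad[m2] > 21 & rad[m2] < 29))       # 22-28 band +- 1 px
  expect_true(!any(m2 & !m0))                          # antitone: no new pixels

  seg6 <- seg0; seg6$endo_offset_mm <- 6; seg6$epi_offset_mm <- 6
  expect_error(myocardium_mask(seg6, c(128, 128)), "empty myocardium")
})

test_that("contour propagation interpolates centers and radii linearly", {
  mk <- function(center, r_epi) {
    s <- init_lv_template(center, center + c(0, r_epi))
    s$polar$endo <- polar_contour(center, rep(0.6 * r_epi, 12))
    s
  }
  # identical keys: intermediates identical
  keys <- list("1" = mk(c(64, 64), 30), "5" = mk(c(64, 64), 30))
  out <- propagate_contours(5, keys)
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  for (i in 2:4)
    expect_equal(radius_at(out[[i]]$polar$epi, th), rep(30, 36), tolerance = 1e-9)

  # linear midpoint in radius and center
  keys2 <- list("1" = mk(c(60, 60), 30), "5" = mk(c(64, 64), 20))
  out2 <- propagate_contours(5, keys2)
  expect_equal(radius_at(out2[[3]]$polar$epi, th), rep(25, 36), tolerance = 1e-9)
  expect_equal(out2[[3]]$polar$epi$center, c(62, 62))

  # single keyed slice: copied to all
  out3 <- propagate_contours(4, list("2" = mk(c(64, 64), 28)))
  for (i in 1:4)
    expect_equal(radius_at(out3[[i]]$polar$epi, th), rep(28, 36), tolerance = 1e-9)
})
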