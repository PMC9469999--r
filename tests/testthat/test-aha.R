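test_that("the AHA model has 17 segments with level spans summing to 360", {
  m <- aha_model()
  expect_equal(nrow(m), 17)
  expect_equal(sort(unique(m$id)), 1:17)
  for (lv in c("basal", "mid", "apical"))
    expect_equal(sum(m$span_deg[m$level == lv]), 360)
  expect_equal(m$level[17], "apex")
})

test_that("slices split into three contiguous near-equal groups, base first", {
  expect_equal(table(classify_slice_levels(9)$level)[c("basal", "mid", "apical")],
               table(rep(c("basal", "mid", "apical"), each = 3))[c("basal", "mid", "apical")])
  l8 <- classify_slice_levels(8)
  expect_equal(unname(c(table(l8$level)[c("basal", "mid", "apical")])), c(3, 3, 2))
  expect_equal(l8$level[1:3], rep("basal", 3))
  l3 <- classify_slice_levels(3)
  expect_equal(l3$level, c("basal", "mid", "apical"))
  expect_error(classify_slice_levels(2), "at least 3")
})

test_that("segment assignment anchors on the RV-insertion ray", {
  ph <- generate_phantom(phantom_spec())
  myo <- class_mask(ph$truth[[1]], "myocardium")
  ctr <- c(64.5, 64.5)
  rv <- c(20, 64.5)  # straight up: reference angle pi/2

  asg <- assign_segments(myo, ctr, rv, "basal")
  # pixel 1 degree counterclockwise of the insertion ray -> anterior (id 1)
  a <- pi / 2 + pi / 180
  p <- round(c(ctr[1] - 25 * sin(a), ctr[2] + 25 * cos(a)))
  expect_equal(asg$ids[p[1], p[2]], 1L)
  # pixel 1 degree clockwise of the ray -> anterolateral (id 6)
  a2 <- pi / 2 - pi / 180
  p2 <- round(c(ctr[1] - 25 * sin(a2), ctr[2] + 25 * cos(a2)))
  expect_equal(asg$ids[p2[1], p2[2]], 6L)

  # rotating the landmark by 60 degrees permutes ids cyclically
  rv2 <- c(ctr[1] - 25 * sin(pi / 2 + pi / 3), ctr[2] + 25 * cos(pi / 2 + pi / 3))
  asg2 <- assign_segments(myo, ctr, rv2, "basal")
  expect_identical(asg2$ids[myo], ((asg$ids[myo] - 2L) %% 6L) + 1L)

  # uniform ring: six equal sectors within 1%
  cnt <- table(asg$ids[myo])
  expect_equal(length(cnt), 6)
  expect_lt(diff(range(cnt)) / mean(cnt), 3 * 0.01 + 0.02)

  # apical level: four sectors
  asg4 <- assign_segments(myo, ctr, rv, "apical")
  expect_equal(sort(unique(asg4$ids[myo])), 13:16)
  expect_error(assign_segments(myo, ctr, ctr, "basal"), "degenerate")
})

test_that("segments partition the myocardium with additive counts", {
  ph <- generate_phantom(bench_spec(target_cnr = 6, seed = 8))
  tr <- ph$truth[[1]]
  myo <- class_mask(tr, "myocardium")
  asg <- assign_segments(myo, c(64.5, 64.5), c(20, 64.5), "mid")
  # partition: every myocardial pixel exactly one id, none outside
  expect_true(all(asg$ids[myo] %in% 7:12))
  expect_true(all(asg$ids[!myo] == 0))

  tab <- segment_stats_table(ph$stack$slices[[1]], tr, asg)
  for (cl in c("remote", "lesion")) {
    tot <- tab$n_pixels[tab$segment == 0 & tab$class == cl]
    expect_equal(tot, sum(tab$n_pixels[tab$segment > 0 & tab$class == cl]))
  }
  # global lesion fraction recovers the geometric truth
  frac <- tab$n_pixels[tab$segment == 0 & tab$class == "lesion"] / sum(myo)
  expect_equal(frac, 70 / 360 * 1, tolerance = 0.05)
})

test_that("a lesion confined to one sector appears in exactly one segment", {
  ph <- generate_phantom(phantom_spec(lesion_extent_deg = 40,
                                      lesion_center_deg = 60))
  tr <- ph$truth[[1]]
  myo <- class_mask(tr, "myocardium")
  # anchor the grid so the wedge [40, 80] sits inside one 60-degree sector
  rv <- c(64.5 - 25 * sin(30 * pi / 180), 64.5 + 25 * cos(30 * pi / 180))
  asg <- assign_segments(myo, c(64.5, 64.5), rv, "basal")
  tab <- segment_stats_table(ph$stack$slices[[1]], tr, asg)
  les_rows <- tab[tab$segment > 0 & tab$class == "lesion", ]
  expect_equal(nrow(les_rows), 1)
})

test_that("whole-stack report stacks slices and closes the totals", {
  sp <- bench_spec(target_cnr = 8, seed = 10)
  sp$n_slices <- 4L
  ph <- generate_phantom(sp)
  lms <- lapply(seq_len(4), function(i)
    run_method(ph, "5sd", slice = i, use_true_remote = TRUE))
  tab <- aha_report(ph$stack, lms, c(64.5, 64.5), c(20, 64.5))
  per_slice <- tab[tab$slice > 0 & tab$segment == 0 & tab$class == "lesion", ]
  global <- tab[tab$slice == 0 & tab$class == "lesion", ]
  expect_equal(global$n_pixels, sum(per_slice$n_pixels))
  bv <- bullseye_values(tab)
  expect_equal(names(bv), as.character(1:17))
  # short-axis-only stack: apex cap (17) never receives pixels
  expect_true(is.na(bv[["17"]]))
})
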