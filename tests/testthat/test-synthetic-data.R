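test_that("iris phantom is deterministic and honours its geometry", {
  cfg <- small_iris_config(seed = 11L)
  a <- generate_iris_phantom(cfg)
  b <- generate_iris_phantom(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  expect_identical(dim(a$image$pixels),
                   c(cfg$image_height, cfg$image_width))
  c2 <- generate_iris_phantom(small_iris_config(seed = 12L))
  expect_false(identical(a$image$pixels, c2$image$pixels))

  lm <- a$landmarks
  expect_equal(lm$pupil_margin,
               c(cfg$pupil_center[1], cfg$pupil_center[2] - cfg$pupil_radius))
  expect_equal(lm$limbus, c(cfg$pupil_center[1], cfg$limbus_offset))
})

test_that("phantom with no vessels has an empty ground-truth mask", {
  ph <- generate_iris_phantom(small_iris_config(n_vessels = 0L))
  expect_equal(sum(ph$mask), 0L)
  roi <- small_rois(ph$landmarks, dim(ph$mask))$full
  expect_equal(compute_vad(ph$mask, roi), 0)
})

test_that("ground-truth VAD equals the direct pixel count ratio", {
  ph <- generate_iris_phantom(small_iris_config(seed = 4L))
  rois <- small_rois(ph$landmarks, dim(ph$mask))
  for (roi in rois) {
    sub <- ph$mask[(roi$row_min + 1):roi$row_max,
                   (roi$col_min + 1):roi$col_max]
    expect_identical(compute_vad(ph$mask, roi), sum(sub) / length(sub))
  }
})

test_that("vessel count can be calibrated to a target inner-segment density", {
  cal <- calibrate_n_vessels(small_iris_config(seed = 2L),
                             target_vad = 0.30, tol = 0.01,
                             half_height = small_roi_args$half_height,
                             span = small_roi_args$span)
  ph <- generate_iris_phantom(cal)
  roi <- small_rois(ph$landmarks, dim(ph$mask))$one_third
  expect_lt(abs(compute_vad(ph$mask, roi) - 0.30), 0.03)
})

test_that("positive density gradient concentrates vessels at the pupil margin", {
  for (s in 1:5) {
    ph <- generate_iris_phantom(small_iris_config(seed = s))
    rois <- small_rois(ph$landmarks, dim(ph$mask))
    expect_gte(compute_vad(ph$mask, rois$one_third),
               compute_vad(ph$mask, rois$full))
    bands <- small_rois(ph$landmarks, dim(ph$mask), mode = "disjoint")
    expect_gte(compute_vad(ph$mask, bands$one_third),
               compute_vad(ph$mask, bands$two_thirds))
  }
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_config(pupil_center = c(10, 360)),
               "outside the image frame")
  expect_error(phantom_config(limbus_offset = 300), "limbus")
  expect_error(phantom_config(vessel_width_range = c(0, 3)),
               "vessel_width_range")
  expect_error(phantom_config(vessel_intensity = 50,
                              background_intensity = 80),
               "exceed")
  expect_error(phantom_config(image_height = 0), "dimensions")
})

test_that("macula phantom covers the frame and is reproducible", {
  cfg <- phantom_config(modality = "macula", image_height = 200L,
                        image_width = 200L, n_vessels = 25L, seed = 9L)
  a <- generate_macula_phantom(cfg)
  b <- generate_macula_phantom(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_equal(a$image$modality, "macula")
  roi <- build_macula_roi(a$image)
  expect_equal(roi_area(roi), 200L * 200L)
  expect_identical(compute_vad(a$mask, roi), mean(a$mask))
})

test_that("cohort simulation conserves counts and labels", {
  d <- cohort_design(list(list(
    label = "RVO", n = 5L,
    mean = c(iris_vad_one_third = 0.34),
    sd = c(iris_vad_one_third = 0.07))), seed = 3L)
  co <- generate_cohort(d)
  expect_equal(nrow(co), 5L)
  expect_true(all(co$group == "RVO"))
  expect_identical(generate_cohort(d), co)  # seeded determinism
})

test_that("cohort draws follow the requested mean at large n", {
  d <- cohort_design(list(list(
    label = "g", n = 10000L,
    mean = c(iris_vad_one_third = 0.34),
    sd = c(iris_vad_one_third = 0.07))), seed = 1L)
  co <- generate_cohort(d)
  # three standard errors of the mean at n = 10,000
  expect_lt(abs(mean(co$iris_vad_one_third) - 0.34), 3 * 0.07 / 100)
})

test_that("near-degenerate SD collapses draws onto the mean", {
  d <- cohort_design(list(list(
    label = "g", n = 100L,
    mean = c(retina_vad = 0.5), sd = c(retina_vad = 1e-4))), seed = 2L)
  co <- generate_cohort(d)
  expect_true(all(abs(co$retina_vad - 0.5) < 1e-3))
})

test_that("truncation keeps metrics inside the unit interval", {
  d <- cohort_design(list(list(
    label = "g", n = 500L,
    mean = c(retina_vad = 0.95), sd = c(retina_vad = 0.2))), seed = 7L)
  co <- generate_cohort(d)
  expect_true(all(co$retina_vad > 0 & co$retina_vad < 1))
})

test_that("cohort design validation rejects malformed groups", {
  expect_error(cohort_design(list()), "non-empty")
  expect_error(cohort_design(list(list(label = "a", n = 0L,
                                       mean = c(x = .5), sd = c(x = .1)))),
               ">= 1")
  expect_error(cohort_design(list(list(label = "a", n = 2L,
                                       mean = c(x = 1.5), sd = c(x = .1)))),
               "in \\(0, 1\\)")
  expect_error(cohort_design(list(list(label = "a", n = 2L,
                                       mean = c(x = .5), sd = c(y = .1)))),
               "same metrics")
})
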