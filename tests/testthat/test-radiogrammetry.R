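test_that("proportional ROI placement uses the 44% / 25% rule", {
  roi <- place_roi_bx(std_contour)
  expect_identical(roi$mode, "bx")
  expect_equal(roi$centre_u, 0.44)
  expect_equal(roi$u_range, c(0.315, 0.565))
  # scaled to a 60 mm bone: 18.9 mm to 33.9 mm from the proximal end
  expect_equal(roi$u_range * 60, c(18.9, 33.9))
  expect_error(place_roi_bx(std_contour, centre_u = 0.95, length_u = 0.25),
               class = "dxr_roi_error")
})

test_that("narrowest-point ROI finds the waist and tie-breaks flat shafts", {
  roi <- place_roi_xp(std_phantom, std_contour)
  expect_identical(roi$mode, "xp")
  expect_equal(roi$centre_u, 0.5, tolerance = 0.01)
  expect_equal(diff(roi$u_range), 0.30, tolerance = 1e-9)

  sp4 <- phantom_bone_spec(60, 4.5, 4.0, 1.8, waist_u = 0.4,
                           proximal_origin_mm = c(10, 6))
  ph4 <- render_phantom(sp4, pixel_spacing_mm = 0.0846)
  roi4 <- place_roi_xp(ph4, detect_bone_contours(ph4, 1)[[1]])
  expect_equal(roi4$centre_u, 0.4, tolerance = 0.01)

  spc <- phantom_bone_spec(60, 4.2, 4.2, 1.8, proximal_origin_mm = c(10, 6))
  phc <- render_phantom(spc, pixel_spacing_mm = 0.0846)
  expect_warning(
    roic <- place_roi_xp(phc, detect_bone_contours(phc, 1)[[1]]),
    "tied")
  expect_equal(roic$centre_u, 0.2)
})

test_that("profile measurement recovers W and T on the analytic projection", {
  s <- 0.0846
  xg <- seq(-8, 8, by = s)
  prof <- 10 + cortical_path_length(5, 3.5, xg)
  m <- measure_profile(prof, s, 8)
  expect_true(m$valid)
  expect_equal(m$W, 10, tolerance = 2 * s / 10)
  expect_equal(m$T, 1.5, tolerance = 2 * s / 1.5)
  expect_true(m$outer_left < m$inner_left)
  expect_true(m$inner_right < m$outer_right)

  # mirroring swaps the cortices but leaves T and W unchanged
  mm <- measure_profile(rev(prof), s, 8)
  expect_equal(mm$T_left, m$T_right, tolerance = 1e-9)
  expect_equal(mm$T_right, m$T_left, tolerance = 1e-9)
  expect_equal(mm$W, m$W, tolerance = 1e-9)
  expect_equal(mm$T, m$T, tolerance = 1e-9)
})

test_that("degenerate profiles are rejected with the right condition", {
  s <- 0.1
  expect_error(measure_profile(rep(5, 100), s),
               class = "dxr_no_bone_error")
  expect_error(measure_profile(seq(0, 10, length.out = 100), s),
               class = "dxr_no_bone_error")
  expect_error(measure_profile(c(1, 2, 3), s), class = "dxr_profile_error")
  expect_error(measure_profile(c(rep(1, 50), NA, rep(1, 49)), s),
               class = "dxr_profile_error")
  # merged cortices (no medulla left): a single central opacity peak is
  # invalid, not an error
  xg <- seq(-8, 8, by = s)
  single <- 10 + cortical_path_length(5, 0, xg)
  res <- measure_profile(single, s, 8)
  expect_false(res$valid)
  expect_match(res$reason, "merged")
})

test_that("ROI measurement recovers the ground truth", {
  bm <- measure_roi(std_phantom, place_roi_bx(std_contour), std_contour)
  expect_equal(bm$T_mean, std_truth$T_mm, tolerance = 0.05 / std_truth$T_mm)
  expect_equal(bm$W_mean, std_truth$W_mm, tolerance = 0.01)
  expect_lte(bm$n_valid, bm$n_profiles)
  expect_gte(bm$n_valid, 10)

  # with 2% noise (relative to the cortical peak) T stays within 0.1 mm
  phn <- render_phantom(std_spec, pixel_spacing_mm = 0.0846,
                        noise_sd = 0.14, seed = 5)
  ctn <- detect_bone_contours(phn, 1)[[1]]
  bmn <- measure_roi(phn, place_roi_bx(ctn), ctn)
  expect_equal(bmn$T_mean, std_truth$T_mm, tolerance = 0.1 / std_truth$T_mm)

  # an ROI outside the bone yields no valid profiles
  fake <- std_contour
  fake$marks <- std_contour$marks + 40
  expect_error(measure_roi(std_phantom, place_roi_bx(fake), fake),
               class = "dxr_insufficient_profiles_error")
})

test_that("erosions at the bone ends leave shaft measurements unchanged", {
  er <- apply_erosion(std_spec, "distal", depth_fraction = 0.8,
                      extent_fraction = 0.15)
  phe <- render_phantom(er, pixel_spacing_mm = 0.0846)
  cte <- detect_bone_contours(phe, 1)[[1]]
  bme <- measure_roi(phe, place_roi_bx(cte), cte)
  bm <- measure_roi(std_phantom, place_roi_bx(std_contour), std_contour)
  expect_equal(2 * bme$T_mean / bme$W_mean, 2 * bm$T_mean / bm$W_mean,
               tolerance = 5e-3)
})
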