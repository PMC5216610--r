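test_that("contours recover bone length to sub-pixel accuracy", {
  s <- std_phantom$pixel_spacing_mm
  expect_length(std_contour$marks[, 1], 32)
  expect_equal(std_contour$length_mm, 60, tolerance = s / 60)
  # proximal end is at the lower row index (top of the image)
  expect_lt(std_contour$marks[std_contour$proximal_idx, 2],
            std_contour$marks[std_contour$distal_idx, 2])
  expect_equal(sqrt(sum(std_contour$axis_unit^2)), 1, tolerance = 1e-12)
})

test_that("detection is rotation invariant and errors on empty images", {
  s <- 0.0846
  rot <- phantom_bone_spec(60, 4.5, 4.0, 1.8, axis_angle_deg = 30,
                           proximal_origin_mm = c(8, 6))
  ct <- detect_bone_contours(render_phantom(rot, pixel_spacing_mm = s), 1)[[1]]
  expect_equal(ct$length_mm, 60, tolerance = 1.5 * s / 60)
  expect_equal(ct$axis_unit, c(sin(pi / 6), cos(pi / 6)), tolerance = 5e-3)

  flat <- structure(list(pixels = matrix(10, 120, 120),
                         pixel_spacing_mm = s), class = "phantom_image")
  expect_error(detect_bone_contours(flat, 1),
               class = "dxr_detection_count_error")
  expect_identical(detect_bone_contours(flat, 0), list())
  expect_error(detect_bone_contours(std_phantom, 2),
               class = "dxr_detection_count_error")
})

test_that("length and area hold across random noise-free geometries", {
  set.seed(21)
  for (k in 1:6) {
    sp <- random_bone()
    ph <- render_phantom(sp, pixel_spacing_mm = 0.0846)
    ct <- detect_bone_contours(ph, 1)[[1]]
    expect_equal(ct$length_mm, sp$length_mm,
                 tolerance = 1.5 * 0.0846 / sp$length_mm)
    # shoelace area of the 32 marks vs true projected area
    u <- seq(0, 1, length.out = 2001)
    true_area <- mean(2 * dxr:::.bone_radii(sp, u)$R) * sp$length_mm
    expect_equal(contour_area(ct), true_area, tolerance = 0.03)
  }
})

test_that("axis and length recomputation is exact and idempotent", {
  ends <- function(p, d) {
    m <- matrix(runif(64), 32, 2)
    m[1, ] <- d; m[17, ] <- p
    structure(list(marks = m, proximal_idx = 17L, distal_idx = 1L,
                   axis_unit = c(0, 1), length_mm = NA_real_,
                   fit_residual_mm = 0), class = "bone_contour")
  }
  a <- bone_axis_and_length(ends(c(0, 0), c(0, 60)))
  expect_equal(a$axis_unit, c(0, 1))
  expect_equal(a$length_mm, 60)
  b <- bone_axis_and_length(ends(c(0, 0), c(36, 48)))
  expect_equal(b$length_mm, 60)  # 3-4-5 triangle
  # idempotence
  c1 <- bone_axis_and_length(std_contour)
  c2 <- bone_axis_and_length(std_contour)
  expect_identical(c1, c2)
  expect_equal(c1$length_mm, std_contour$length_mm, tolerance = 1e-12)
  expect_error(bone_axis_and_length(ends(c(1, 1), c(1, 1))),
               class = "dxr_degenerate_contour_error")
})

test_that("contours serialise to JSON and back exactly", {
  txt <- contour_to_json(std_contour)
  rt <- contour_from_json(txt)
  expect_equal(rt$marks, std_contour$marks, tolerance = 1e-12)
  expect_identical(rt$proximal_idx, std_contour$proximal_idx)
  expect_equal(rt$length_mm, std_contour$length_mm, tolerance = 1e-12)
})
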