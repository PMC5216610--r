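test_that("cortical path length matches the closed form and a brute-force line integral", {
  expect_equal(cortical_path_length(5, 3.5, 0), 3.0)
  expect_equal(cortical_path_length(5, 3.5, 5), 0.0)
  expect_equal(cortical_path_length(5, 3.5, 3.5), 2 * sqrt(25 - 12.25))
  expect_equal(cortical_path_length(5, 3.5, 6), 0.0)

  # independent oracle: find the ray's entry/exit depths on each circle by
  # root bisection on the implicit circle equation, no closed-form sqrt
  chord_half <- function(rad, x) {
    if (abs(x) >= rad) return(0)
    stats::uniroot(function(z) x^2 + z^2 - rad^2, c(0, rad + 1),
                   tol = 1e-12)$root
  }
  brute <- function(R, r, x) 2 * (chord_half(R, x) - chord_half(r, x))
  for (g in list(c(5, 3.5), c(4, 1), c(6, 5.5))) {
    for (x in c(0, 0.7, g[2], (g[1] + g[2]) / 2, g[1] * 0.999)) {
      expect_equal(cortical_path_length(g[1], g[2], x), brute(g[1], g[2], x),
                   tolerance = 1e-6)
    }
  }

  # the maximum is attained at |x| = r
  xs <- seq(-5, 5, by = 0.001)
  p <- cortical_path_length(5, 3.5, xs)
  expect_equal(abs(xs[which.max(p)]), 3.5, tolerance = 2e-3)

  expect_error(cortical_path_length(3, 3, 0), class = "dxr_geometry_error")
  expect_error(cortical_path_length(3, -1, 0), class = "dxr_geometry_error")
})

test_that("total projected mass equals the annulus area", {
  # sum over x of path * dx -> pi * T * (W - T), the cortical area
  for (g in list(c(5, 1.5), c(3.5, 0.5), c(6, 2.9))) {
    R <- g[1]; Tt <- g[2]; W <- 2 * R
    xs <- seq(-R, R, length.out = 4e4)
    mass <- sum(cortical_path_length(R, R - Tt, xs)) * (xs[2] - xs[1])
    expect_equal(mass, pi * Tt * (W - Tt), tolerance = 1e-4)
  }
})

test_that("rendering is deterministic, symmetric, and background-exact", {
  a <- render_phantom(std_spec, pixel_spacing_mm = 0.0846,
                      noise_sd = 0.1, seed = 42)
  b <- render_phantom(std_spec, pixel_spacing_mm = 0.0846,
                      noise_sd = 0.1, seed = 42)
  expect_identical(a$pixels, b$pixels)

  # noise-free scanline through the shaft: symmetric with maxima at
  # +/- (R - T), pixels beyond |x| > R exactly at background
  ph <- std_phantom
  s <- ph$pixel_spacing_mm
  row <- round((6 + 0.5 * 60) / s) + 1  # mid-shaft scanline
  v <- ph$pixels[row, ]
  x <- (seq_along(v) - 1) * s - 10      # offsets from the axis at x = 10
  R <- std_spec$outer_radius_mm(0.5)
  Tt <- std_spec$cortical_thickness_mm(0.5)
  expect_true(all(v[abs(x) > R + s] == ph$background_level))
  left <- which.max(v[x < 0]); right <- which(x > 0)[which.max(v[x > 0])]
  expect_equal(abs(x[left]), R - Tt, tolerance = s)
  expect_equal(abs(x[right]), R - Tt, tolerance = s)

  expect_error(render_phantom(std_spec, pixel_spacing_mm = 0),
               class = "dxr_geometry_error")
  two <- list(phantom_bone_spec(60, 4.5, 4, 1.8, proximal_origin_mm = c(10, 6)),
              phantom_bone_spec(60, 4.5, 4, 1.8, proximal_origin_mm = c(14, 6)))
  expect_error(render_phantom(two), class = "dxr_layout_error")
})

test_that("scanline maxima sit at +/-(R - T) across geometries", {
  set.seed(7)
  for (k in 1:5) {
    R <- runif(1, 3.5, 6); Tt <- runif(1, 1, min(3, R - 0.5))
    sp <- phantom_bone_spec(55, R, R, Tt, proximal_origin_mm = c(10, 6))
    ph <- render_phantom(sp, pixel_spacing_mm = 0.0846)
    s <- ph$pixel_spacing_mm
    row <- round((6 + 0.5 * 55) / s) + 1
    v <- ph$pixels[row, ]
    x <- (seq_along(v) - 1) * s - 10
    left <- which.max(v[x < 0])
    expect_equal(abs(x[left]), R - Tt, tolerance = s / 2)
  }
})

test_that("erosions thin the ends but never the shaft measurement region", {
  expect_error(apply_erosion(std_spec, "distal", 0.5, extent_fraction = 0.3),
               class = "dxr_erosion_extent_error")

  e0 <- apply_erosion(std_spec, "distal", depth_fraction = 0)
  u <- seq(0, 1, length.out = 501)
  expect_equal(dxr:::.bone_radii(e0, u)$T, dxr:::.bone_radii(std_spec, u)$T)

  # full-depth erosion removes the cortex on the affected span only
  e1 <- apply_erosion(std_spec, "distal", depth_fraction = 1,
                      extent_fraction = 0.1)
  rr <- dxr:::.bone_radii(e1, u)
  expect_true(all(rr$T[u >= 0.91] == 0))
  expect_equal(rr$T[u < 0.9], dxr:::.bone_radii(std_spec, u)$T[u < 0.9])

  # the proportional ROI interval of the truth is untouched to 1e-12
  ug <- seq(0.315, 0.565, length.out = 201)
  e <- apply_erosion(std_spec, "proximal", 0.8, extent_fraction = 0.2)
  expect_equal(dxr:::.bone_radii(e, ug)$T,
               dxr:::.bone_radii(std_spec, ug)$T, tolerance = 1e-12)
})

test_that("bone spec validation rejects impossible geometry", {
  expect_error(phantom_bone_spec(60, 4, 4, 4.5), class = "dxr_geometry_error")
  expect_error(phantom_bone_spec(60, 4.5, 4, 1.8, waist_u = 0.1),
               class = "dxr_geometry_error")
})
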