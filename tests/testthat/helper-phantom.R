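# shared fixtures, built in code: a standard single-bone phantom and its
# detected contour, reused across test files to avoid re-rendering
std_spec <- phantom_bone_spec(60, 4.5, 4.0, 1.8, proximal_origin_mm = c(10, 6))
std_phantom <- render_phantom(std_spec, pixel_spacing_mm = 0.0846)
std_contour <- detect_bone_contours(std_phantom, 1)[[1]]
std_truth <- phantom_truth(std_spec)

# random bone geometry within adult metacarpal ranges (valid by construction)
random_bone <- function(origin = c(12, 6), angle = 0) {
  L <- runif(1, 50, 75)
  W <- runif(1, 7, 12)
  Tt <- min(runif(1, 1, 3), W / 2 - 0.6)
  phantom_bone_spec(L, W / 2 + runif(1, 0.2, 0.8), W / 2, Tt,
                    axis_angle_deg = angle, proximal_origin_mm = origin)
}
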