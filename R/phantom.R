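#' Projected path length through a tubular (annular) cross-section
#'
#' An anterior-posterior radiograph of a tubular bone integrates attenuation
#' along rays perpendicular to the image plane. For a cross-section that is an
#' annulus with outer radius `R` and inner (medullary) radius `r`, a ray at
#' transverse offset `x` from the bone axis traverses cortical bone over a
#' chord of length `2 * sqrt(R^2 - x^2) - 2 * sqrt(r^2 - x^2)` inside the
#' medullary span and `2 * sqrt(R^2 - x^2)` between the medullary cavity and
#' the periosteal surface. The projected radio-opacity is maximal exactly at
#' `|x| = r`, which is what makes the "inner border at maximum radio-opacity"
#' edge criterion exact on these phantoms.
#'
#' @param R outer radius (mm), positive.
#' @param r inner radius (mm), `0 <= r < R`.
#' @param x transverse offset(s) from the axis (mm); vectorised.
#' @return numeric vector of cortical path lengths (mm), zero for `|x| > R`.
#' @examples
#' cortical_path_length(5, 3.5, 0)    # 2 * (R - r) = 3
#' cortical_path_length(5, 3.5, 3.5)  # global maximum, 2 * sqrt(R^2 - r^2)
#' @export
cortical_path_length <- function(R, r, x) {
  if (!is.finite(R) || !is.finite(r) || r < 0 || R <= 0 || r >= R)
    .dxr_stop("dxr_geometry_error",
              "invalid annulus geometry: need 0 <= r < R (got R=%g, r=%g)", R, r)
  ax <- abs(x)
  outer <- ifelse(ax <= R, 2 * sqrt(pmax(R^2 - x^2, 0)), 0)
  inner <- ifelse(ax <= r, 2 * sqrt(pmax(r^2 - x^2, 0)), 0)
  outer - inner
}

#' Specify the ground-truth geometry of one phantom metacarpal
#'
#' The bone is a tube of length `length_mm` whose outer radius varies along
#' the axial fraction `u` in `[0, 1]` (proximal end at `u = 0`). The default
#' radius profile is a quadratic waist,
#' `R(u) = r_end - (r_end - r_mid) * (1 - ((u - waist_u)/m)^2)` with
#' `m = max(waist_u, 1 - waist_u)`, so the shaft is narrowest at `waist_u`.
#' Bone ends are rounded by an elliptical cap over the outermost
#' `cap_fraction` of the length: within a cap both the local radius and the
#' local cortical thickness are scaled by
#' `g(u) = sqrt(1 - ((c - u)/c)^2)`, which keeps the cortex inside the bone
#' and makes the projected opacity fall to zero exactly at the anatomical
#' end points, so bone length is recoverable from the image.
#'
#' @param length_mm bone length L (mm).
#' @param r_end_mm outer radius at the bone ends (mm).
#' @param r_mid_mm outer radius at the shaft waist (mm), `<= r_end_mm`.
#' @param cortical_thickness_mm cortical thickness T: a single number or a
#'   function of the axial fraction `u`.
#' @param waist_u axial fraction of the narrowest point, strictly inside
#'   `(0.2, 0.8)`.
#' @param axis_angle_deg in-plane rotation of the bone axis, degrees
#'   clockwise from the image "down" direction (+rows).
#' @param proximal_origin_mm length-2 numeric, image position (x, y) in mm of
#'   the proximal end point.
#' @param cap_fraction fraction of the length rounded off at each end.
#' @param erosion optional erosion descriptor created by [apply_erosion()];
#'   normally `NULL` here.
#' @return an object of class `phantom_bone_spec` with accessor functions
#'   `outer_radius_mm(u)` and `cortical_thickness_mm(u)`.
#' @examples
#' spec <- phantom_bone_spec(60, 4.5, 4.0, 1.8)
#' spec$outer_radius_mm(0.5)       # waist radius
#' spec$cortical_thickness_mm(0.44)
#' @export
phantom_bone_spec <- function(length_mm, r_end_mm, r_mid_mm,
                              cortical_thickness_mm,
                              waist_u = 0.5,
                              axis_angle_deg = 0,
                              proximal_origin_mm = c(10, 5),
                              cap_fraction = 0.05,
                              erosion = NULL) {
  stopifnot(length_mm > 0, r_end_mm > 0, r_mid_mm > 0,
            r_mid_mm <= r_end_mm, cap_fraction > 0, cap_fraction < 0.15,
            length(proximal_origin_mm) == 2)
  if (waist_u <= 0.2 || waist_u >= 0.8)
    .dxr_stop("dxr_geometry_error", "waist_u must lie strictly in (0.2, 0.8)")
  m <- max(waist_u, 1 - waist_u)
  radius_fun <- function(u)
    r_end_mm - (r_end_mm - r_mid_mm) * pmax(0, 1 - ((u - waist_u) / m)^2)
  thick_fun <- if (is.function(cortical_thickness_mm)) cortical_thickness_mm
    else { tv <- cortical_thickness_mm; function(u) rep_len(tv, length(u)) }

  ug <- seq(0, 1, length.out = 401)
  tvals <- thick_fun(ug); rvals <- radius_fun(ug)
  if (any(!is.finite(tvals)) || any(tvals <= 0) || any(tvals > rvals + 1e-12))
    .dxr_stop("dxr_geometry_error",
              "cortical thickness must satisfy 0 < T(u) <= R(u) for all u")

  structure(list(
    length_mm = length_mm,
    r_end_mm = r_end_mm, r_mid_mm = r_mid_mm, waist_u = waist_u,
    outer_radius_mm = radius_fun,
    cortical_thickness_mm = thick_fun,
    axis_angle_deg = axis_angle_deg,
    proximal_origin_mm = as.numeric(proximal_origin_mm),
    cap_fraction = cap_fraction,
    erosion = erosion
  ), class = "phantom_bone_spec")
}

#' @export
print.phantom_bone_spec <- function(x, ...) {
  cat(sprintf(
    "phantom metacarpal: L = %.2f mm, R(ends) = %.2f, R(waist %.2f) = %.2f, T(0.44) = %.3f mm%s\n",
    x$length_mm, x$r_end_mm, x$waist_u, x$r_mid_mm,
    x$cortical_thickness_mm(0.44),
    if (is.null(x$erosion)) "" else sprintf(", eroded (%s)", x$erosion$site)))
  invisible(x)
}

# elliptical end-cap scale factor g(u) in [0, 1]
.cap_scale <- function(u, cap_fraction) {
  c <- cap_fraction
  g <- rep_len(1, length(u))
  lo <- u < c & u >= 0
  hi <- u > 1 - c & u <= 1
  g[lo] <- sqrt(pmax(0, 1 - ((c - u[lo]) / c)^2))
  g[hi] <- sqrt(pmax(0, 1 - ((u[hi] - (1 - c)) / c)^2))
  g[u < 0 | u > 1] <- 0
  g
}

# effective outer/inner radii at axial fraction u, including caps and erosion
.bone_radii <- function(spec, u) {
  g <- .cap_scale(u, spec$cap_fraction)
  uc <- pmin(pmax(u, 0), 1)
  R <- spec$outer_radius_mm(uc) * g
  Tt <- spec$cortical_thickness_mm(uc)
  if (!is.null(spec$erosion)) {
    e <- spec$erosion
    in_site <- if (e$site == "proximal") uc <= e$extent_fraction
               else uc >= 1 - e$extent_fraction
    Tt[in_site] <- Tt[in_site] * (1 - e$depth_fraction)
  }
  Tt <- Tt * g
  list(R = R, r = pmax(R - Tt, 0), T = Tt)
}

#' Erode the cortical shell near one bone end
#'
#' Rheumatoid erosions attack the bone ends (the caputs), not the shaft.
#' This thins the ground-truth cortical profile by `depth_fraction` over the
#' outermost `extent_fraction` of the bone at the chosen end, leaving the
#' shaft — in particular the proportional measurement region
#' `u` in `[0.315, 0.565]` — exactly unchanged, which is the premise that
#' shaft radiogrammetry is robust to end erosions.
#'
#' @param spec a [phantom_bone_spec()].
#' @param site `"proximal"` or `"distal"`.
#' @param depth_fraction fraction of cortical thickness removed, in `[0, 1]`.
#' @param extent_fraction axial extent of the erosion from the end, at most
#'   0.2 so the shaft measurement region is untouched.
#' @return a new `phantom_bone_spec` with the erosion applied.
#' @export
apply_erosion <- function(spec, site = c("distal", "proximal"),
                          depth_fraction, extent_fraction = 0.1) {
  stopifnot(inherits(spec, "phantom_bone_spec"))
  site <- match.arg(site)
  if (depth_fraction < 0 || depth_fraction > 1)
    .dxr_stop("dxr_geometry_error", "depth_fraction must be in [0, 1]")
  if (extent_fraction < 0 || extent_fraction > 0.2)
    .dxr_stop("dxr_erosion_extent_error",
              "erosion extent_fraction %.3f would reach the shaft measurement region; must be <= 0.2",
              extent_fraction)
  out <- spec
  out$erosion <- list(site = site, depth_fraction = depth_fraction,
                      extent_fraction = extent_fraction)
  class(out) <- class(spec)
  out
}

# bone-frame coordinates of image points: axial mm (from proximal end, along
# axis) and signed transverse mm. theta is clockwise from +y (image down).
.bone_frame <- function(spec, px, py) {
  th <- spec$axis_angle_deg * pi / 180
  d <- c(sin(th), cos(th))    # axis unit, proximal -> distal
  nrm <- c(cos(th), -sin(th)) # transverse unit
  rx <- px - spec$proximal_origin_mm[1]
  ry <- py - spec$proximal_origin_mm[2]
  list(axial = rx * d[1] + ry * d[2], trans = rx * nrm[1] + ry * nrm[2],
       axis = d, normal = nrm)
}

#' Render synthetic metacarpal radiographs
#'
#' Produces a mono-energetic projection image: every pixel is
#' `background_level + attenuation_gain * (cortical path length along the
#' ray) + Gaussian(0, noise_sd)`. The attenuation gain is fixed at 1
#' intensity-unit per mm of cortical bone since only relative gradients and
#' opacities matter to the downstream edge criteria. Rendering is
#' deterministic given `seed`.
#'
#' @param specs a [phantom_bone_spec()] or list of them; footprints must not
#'   overlap.
#' @param width_mm,height_mm image extent (mm); defaults fit the bones with a
#'   4 mm margin.
#' @param pixel_spacing_mm pixel pitch (mm); the default 0.0846 mm
#'   corresponds to a 300 dpi film scan.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param background_level constant soft-tissue/film background.
#' @param seed integer seed for the noise generator (Mersenne-Twister).
#' @return object of class `phantom_image`: list with `pixels` (matrix,
#'   rows = image rows), `pixel_spacing_mm`, `truth` (list of specs),
#'   `noise_sd`, `background_level`, `seed`, `rng_kind`.
#' @examples
#' ph <- render_phantom(phantom_bone_spec(30, 4.5, 4, 1.5,
#'                                        proximal_origin_mm = c(8, 4)),
#'                      pixel_spacing_mm = 0.25)
#' dim(ph$pixels)
#' @export
render_phantom <- function(specs, width_mm = NULL, height_mm = NULL,
                           pixel_spacing_mm = 0.0846,
                           noise_sd = 0, background_level = 10, seed = 1L) {
  if (inherits(specs, "phantom_bone_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE,
                                           "phantom_bone_spec")))
  if (pixel_spacing_mm <= 0)
    .dxr_stop("dxr_geometry_error", "pixel_spacing_mm must be positive")
  if (noise_sd < 0) .dxr_stop("dxr_geometry_error", "noise_sd must be >= 0")

  # bounding boxes (generous: max radius around the axis segment)
  boxes <- lapply(specs, function(s) {
    th <- s$axis_angle_deg * pi / 180
    ends <- rbind(s$proximal_origin_mm,
                  s$proximal_origin_mm + s$length_mm * c(sin(th), cos(th)))
    rmax <- s$r_end_mm
    c(xmin = min(ends[, 1]) - rmax, xmax = max(ends[, 1]) + rmax,
      ymin = min(ends[, 2]) - rmax, ymax = max(ends[, 2]) + rmax)
  })
  if (length(boxes) > 1) {
    for (i in seq_along(boxes)) for (j in seq_len(i - 1)) {
      a <- boxes[[i]]; b <- boxes[[j]]
      if (a["xmin"] < b["xmax"] && b["xmin"] < a["xmax"] &&
          a["ymin"] < b["ymax"] && b["ymin"] < a["ymax"])
        .dxr_stop("dxr_layout_error",
                  "bone footprints %d and %d overlap", j, i)
    }
  }
  if (is.null(width_mm))
    width_mm <- max(vapply(boxes, `[`, 0, "xmax")) + 4
  if (is.null(height_mm))
    height_mm <- max(vapply(boxes, `[`, 0, "ymax")) + 4

  nc <- as.integer(ceiling(width_mm / pixel_spacing_mm))
  nr <- as.integer(ceiling(height_mm / pixel_spacing_mm))
  xs <- (seq_len(nc) - 1) * pixel_spacing_mm
  ys <- (seq_len(nr) - 1) * pixel_spacing_mm
  img <- matrix(background_level, nr, nc)

  for (k in seq_along(specs)) {
    s <- specs[[k]]; b <- boxes[[k]]
    ci <- which(xs >= b["xmin"] & xs <= b["xmax"])
    ri <- which(ys >= b["ymin"] & ys <= b["ymax"])
    if (!length(ci) || !length(ri)) next
    px <- rep(xs[ci], each = length(ri))
    py <- rep(ys[ri], times = length(ci))
    bf <- .bone_frame(s, px, py)
    u <- bf$axial / s$length_mm
    inside <- u >= 0 & u <= 1
    if (!any(inside)) next
    rad <- .bone_radii(s, u[inside])
    x <- bf$trans[inside]
    hit <- abs(x) <= rad$R & rad$R > 0
    path <- numeric(sum(inside))
    if (any(hit)) {
      Rh <- rad$R[hit]; rh <- rad$r[hit]; xh <- x[hit]
      path[hit] <- 2 * sqrt(pmax(Rh^2 - xh^2, 0)) -
                   2 * ifelse(abs(xh) <= rh, sqrt(pmax(rh^2 - xh^2, 0)), 0)
    }
    block <- matrix(0, length(ri), length(ci))
    block[inside] <- path
    img[ri, ci] <- img[ri, ci] + block
  }

  if (noise_sd > 0)
    img <- img + with_dxr_seed(seed,
      matrix(rnorm(nr * nc, 0, noise_sd), nr, nc))

  structure(list(pixels = img, pixel_spacing_mm = pixel_spacing_mm,
                 truth = specs, noise_sd = noise_sd,
                 background_level = background_level, seed = as.integer(seed),
                 rng_kind = "Mersenne-Twister"),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("phantom radiograph: %d x %d px @ %.4f mm/px, %d bone(s), noise sd %.3g, seed %d\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_mm,
              length(x$truth), x$noise_sd, x$seed))
  invisible(x)
}

#' Ground-truth shaft measurements of a phantom bone
#'
#' Evaluates the true outer width, cortical thickness and length of a
#' phantom over an axial interval (by default the proportional measurement
#' region `[0.315, 0.565]`), for scoring recovery by the image pipeline.
#'
#' @param spec a [phantom_bone_spec()].
#' @param u_range axial interval over which to average.
#' @param n number of grid points.
#' @return list with `T_mm`, `W_mm`, `L_mm` (interval means / length).
#' @export
phantom_truth <- function(spec, u_range = c(0.315, 0.565), n = 201) {
  u <- seq(u_range[1], u_range[2], length.out = n)
  rad <- .bone_radii(spec, u)
  list(T_mm = mean(rad$T), W_mm = mean(2 * rad$R), L_mm = spec$length_mm)
}
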