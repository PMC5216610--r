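#' Place the proportional (BX-style) measurement region
#'
#' The region of interest is defined relative to the bone ends: its centre
#' sits at 44% of the bone length from the proximal end and its length is
#' 25% of the bone length, i.e. the axial interval `[0.315, 0.565]`. Scaling
#' the ROI with the bone makes the placement independent of image
#' magnification and robust to erosions at the bone ends.
#'
#' @param contour a `bone_contour`.
#' @param centre_u,length_u axial centre and length as fractions of the bone
#'   length.
#' @return an object of class `roi_spec` with `mode = "bx"`, the axial
#'   interval `u_range`, and the generating fractions.
#' @export
place_roi_bx <- function(contour, centre_u = 0.44, length_u = 0.25) {
  stopifnot(inherits(contour, "bone_contour"))
  lo <- centre_u - length_u / 2; hi <- centre_u + length_u / 2
  if (lo <= 0 || hi >= 1)
    .dxr_stop("dxr_roi_error", "ROI interval [%g, %g] must lie inside (0, 1)",
              lo, hi)
  structure(list(mode = "bx", centre_u = centre_u, length_u = length_u,
                 u_range = c(lo, hi)),
            class = "roi_spec")
}

#' Place the narrowest-point (XP-style) measurement region
#'
#' Searches the shaft (axial fractions 0.2 to 0.8) for the scanline with the
#' smallest measured outer width and centres a fixed-length ROI there. The
#' ROI length defaults to 30% of the bone length. Ties in the width profile
#' are broken toward the smallest axial fraction, with a warning.
#'
#' @param image a `phantom_image`.
#' @param contour a `bone_contour`.
#' @param length_fraction ROI length as a fraction of bone length.
#' @param search_range axial interval searched for the narrowest point.
#' @param search_step axial step of the width scan.
#' @return an object of class `roi_spec` with `mode = "xp"`, the centre
#'   `centre_u`, and the axial interval `u_range` (clipped to `(0, 1)`).
#' @export
place_roi_xp <- function(image, contour, length_fraction = 0.30,
                         search_range = c(0.2, 0.8), search_step = 0.005) {
  stopifnot(inherits(contour, "bone_contour"))
  us <- seq(search_range[1], search_range[2], by = search_step)
  # no grid dither here: the scan only needs the location of the width
  # minimum, and a common sub-pixel phase keeps the profile smooth
  b <- .scanline_batch(image, contour, us, dither = FALSE)
  widths <- vapply(seq_along(us), function(i) {
    pm <- tryCatch(measure_profile(b$intensity[, i], b$spacing_mm,
                                   b$axis_offset_mm[i]),
                   dxr_error = function(e) NULL)
    if (is.null(pm) || !pm$valid) NA_real_ else pm$W
  }, 0)
  if (all(is.na(widths)))
    .dxr_stop("dxr_roi_error", "no measurable width profile on the shaft")
  # A flat width profile has no defined narrowest point: tie-break to the
  # smallest axial fraction. Otherwise refine the coarse minimum by a local
  # quadratic fit, which suppresses the sub-pixel discretisation wiggle of
  # the per-scanline width estimates.
  ok <- !is.na(widths)
  centre <- NA_real_
  if (diff(range(widths[ok])) < image$pixel_spacing_mm / 4) {
    warning("width profile is constant within measurement precision; ",
            "narrowest point tied, choosing the smallest axial fraction",
            call. = FALSE)
    centre <- us[which(ok)[1]]
  } else {
    # the shaft width profile is parabolic to good approximation around the
    # waist; a quadratic fit over the whole search interval averages out the
    # sub-pixel wiggle of the per-scanline width estimates
    cf <- unname(stats::coef(stats::lm(widths[ok] ~ us[ok] + I(us[ok]^2))))
    if (is.finite(cf[3]) && cf[3] > 0) {
      vert <- -cf[2] / (2 * cf[3])
      if (vert >= search_range[1] && vert <= search_range[2])
        centre <- vert
    }
    if (!is.finite(centre)) centre <- us[which.min(widths)]
  }
  half <- length_fraction / 2
  structure(list(mode = "xp", centre_u = centre,
                 length_fraction = length_fraction,
                 u_range = c(max(centre - half, 0.01),
                             min(centre + half, 0.99)),
                 width_profile = cbind(u = us, W = widths)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("ROI (%s): centre u = %.3f, axial interval [%.3f, %.3f]\n",
              x$mode, if (x$mode == "bx") x$centre_u else x$centre_u,
              x$u_range[1], x$u_range[2]))
  invisible(x)
}

# Sample intensity profiles perpendicular to the bone axis at the axial
# fractions `us`, in a single batched bilinear interpolation. Returns a
# matrix (rows = transverse samples, cols = scanlines), the sample spacing,
# and the offset (mm from the first sample) at which the axis crosses.
.scanline_batch <- function(image, contour, us, half_extent_mm = NULL,
                            step_mm = NULL, dither = TRUE) {
  p0 <- contour$marks[contour$proximal_idx, ]
  ax <- contour$axis_unit
  nv <- c(ax[2], -ax[1])
  if (is.null(half_extent_mm)) {
    # widest plausible half-width from the contour marks, plus margin
    d <- abs((contour$marks[, 1] - p0[1]) * nv[1] +
             (contour$marks[, 2] - p0[2]) * nv[2])
    half_extent_mm <- max(d) + 2
  }
  if (is.null(step_mm)) step_mm <- image$pixel_spacing_mm
  t <- seq(-half_extent_mm, half_extent_mm, by = step_mm)
  cx <- p0[1] + us * contour$length_mm * ax[1]
  cy <- p0[2] + us * contour$length_mm * ax[2]
  # Deterministic sub-pixel dither of each scanline's sample grid: for a
  # bone aligned with the pixel grid every scanline would otherwise sample
  # at the same sub-pixel phase, so the phase-dependent part of the border
  # localisation error would not average out across the ROI. A golden-ratio
  # offset sequence spreads the phases uniformly.
  dither <- if (dither)
    step_mm * ((seq_along(us) * 0.6180339887498949) %% 1)
  else rep(0, length(us))
  xq <- outer(t * nv[1], cx, `+`) +
    rep(dither * nv[1], each = length(t))
  yq <- outer(t * nv[2], cy, `+`) +
    rep(dither * nv[2], each = length(t))
  v <- .interp_image(image, as.vector(xq), as.vector(yq))
  list(intensity = matrix(v, nrow = length(t)), spacing_mm = step_mm,
       axis_offset_mm = half_extent_mm - dither, us = us)
}

.scanline_profile <- function(image, contour, u, ...) {
  b <- .scanline_batch(image, contour, u, ...)
  list(intensity = b$intensity[, 1], spacing_mm = b$spacing_mm,
       axis_offset_mm = b$axis_offset_mm[1], u = u)
}

#' Measure cortical borders on one transverse intensity profile
#'
#' Implements the radiogrammetric edge criteria on a single scanline taken
#' perpendicular to the bone axis: the outer border of each cortex is
#' located at the maximum intensity gradient (rising on the left flank,
#' falling on the right), and the inner border at the maximum radio-opacity
#' of that cortex. Sub-pixel refinement exploits the projection geometry of
#' a tube: near an outer border `1/gradient^2` is locally linear with root
#' at the border (fitted on the singular flank), and each inner border is
#' refined by a one-parameter least-squares fit of the annulus projection
#' model around the opacity maximum. A three-point parabolic interpolation
#' provides the coarse locations and the fallback when a model fit is
#' degenerate. Offsets are reported relative to the bone axis; the bone
#' width is `W = outer_right - outer_left` and the cortical thickness the
#' mean of the two single-cortex thicknesses.
#'
#' @param intensity numeric vector of sampled intensities (>= 7 samples).
#' @param spacing_mm sample spacing (mm).
#' @param axis_offset_mm position of the bone axis, in mm from the first
#'   sample.
#' @return object of class `profile_measurement`: list with signed offsets
#'   `outer_left`, `inner_left`, `inner_right`, `outer_right` (mm from the
#'   axis), `W`, `T_left`, `T_right`, `T`, `valid`, `reason`.
#' @export
measure_profile <- function(intensity, spacing_mm,
                            axis_offset_mm = (length(intensity) - 1) *
                              spacing_mm / 2) {
  n <- length(intensity)
  if (n < 7) .dxr_stop("dxr_profile_error", "profile needs >= 7 samples")
  if (any(!is.finite(intensity)))
    .dxr_stop("dxr_profile_error", "non-finite intensities")
  if (spacing_mm <= 0) .dxr_stop("dxr_profile_error", "spacing must be > 0")
  rng <- max(intensity) - min(intensity)
  if (rng < 1e-9)
    .dxr_stop("dxr_no_bone_error", "flat profile: no bone on this scanline")

  pos <- (seq_len(n) - 1) * spacing_mm - axis_offset_mm
  ic <- which.min(abs(pos))  # sample nearest the axis
  gm <- which.max(intensity)
  if (gm <= 2L || gm >= n - 1L)
    .dxr_stop("dxr_no_bone_error",
              "intensity maximum on the profile boundary: no bone here")

  # inner borders: maximum radio-opacity on each side of the axis
  il <- .subpixel_peak(intensity, 2L, ic, pos)
  ir <- .subpixel_peak(intensity, ic, n - 1L, pos)
  if (is.null(il) || is.null(ir))
    .dxr_stop("dxr_no_bone_error",
              "no interior intensity maximum: no bone on this scanline")
  merged <- abs(il$pos - ir$pos) < spacing_mm / 2

  # outer borders: extremal signed gradient outside the opacity peaks
  grad <- c(NA, (intensity[-(1:2)] - intensity[1:(n - 2)]) / (2 * spacing_mm),
            NA)
  # gradient-maximum ties are broken toward the outermost location
  ol <- .subpixel_peak(grad, 2L, il$idx, pos)
  or <- .subpixel_peak(-grad, ir$idx, n - 1L, pos, prefer_last = TRUE)

  # Sub-pixel refinement from the projection model: the attenuation profile
  # of a tube has square-root singularities at all four borders, where
  # 1/gradient^2 is locally linear in position with root exactly at the
  # border. Fit that line on the singular flank of each border and use its
  # root; fall back to the parabolic estimate when the fit is inconsistent.
  if (!is.null(ol) && !is.null(or)) {
    ol$pos <- .edge_root(pos, grad, ol$idx, flank = +1L,
                         fallback = ol$pos, spacing = spacing_mm)
    or$pos <- .edge_root(pos, grad, or$idx, flank = -1L,
                         fallback = or$pos, spacing = spacing_mm)
    # the inner borders (radio-opacity maxima) are refined by a local
    # one-parameter least-squares fit of the annulus projection model for
    # the medullary radius, anchored on the outer borders
    c0 <- (ol$pos + or$pos) / 2
    Rhat <- (or$pos - ol$pos) / 2
    bg_hat <- mean(c(intensity[1:min(5, n)],
                     intensity[max(1, n - 4):n]))
    il$pos <- .fit_inner_border(intensity, pos, c0, Rhat, bg_hat,
                                il$pos, side = -1L, spacing_mm)
    ir$pos <- .fit_inner_border(intensity, pos, c0, Rhat, bg_hat,
                                ir$pos, side = +1L, spacing_mm)
  }

  invalid <- function(reason)
    structure(list(outer_left = NA_real_, inner_left = NA_real_,
                   inner_right = NA_real_, outer_right = NA_real_,
                   W = NA_real_, T_left = NA_real_, T_right = NA_real_,
                   T = NA_real_, valid = FALSE, reason = reason),
              class = "profile_measurement")

  if (is.null(ol) || is.null(or)) return(invalid("no outer gradient edge"))
  if (merged) return(invalid("single opacity peak: cortices merged"))
  if (!is.na(grad[ol$idx]) && grad[ol$idx] <= 0)
    return(invalid("left outer border is not a rising edge"))
  if (!is.na(grad[or$idx]) && grad[or$idx] >= 0)
    return(invalid("right outer border is not a falling edge"))
  m <- list(outer_left = ol$pos, inner_left = il$pos,
            inner_right = ir$pos, outer_right = or$pos)
  if (!(m$outer_left < m$inner_left && m$inner_left <= m$inner_right &&
        m$inner_right < m$outer_right))
    return(invalid("border ordering violated"))
  m$W <- m$outer_right - m$outer_left
  m$T_left <- m$inner_left - m$outer_left
  m$T_right <- m$outer_right - m$inner_right
  m$T <- (m$T_left + m$T_right) / 2
  if (!(m$T > 0 && m$T < m$W / 2))
    return(invalid("cortical thickness outside (0, W/2)"))
  m$valid <- TRUE; m$reason <- NA_character_
  structure(m, class = "profile_measurement")
}

# Root of the linear fit to 1/grad^2 on the singular flank of an outer
# border. `idx` is the coarse gradient-extremum sample; `flank = +1` means
# the bone interior lies at increasing index (left border), -1 the reverse.
# The fit is weighted by grad^6 (inverse variance of 1/grad^2), so the
# sample nearest the singularity dominates. The root is accepted only if
# the fitted line slopes away from the border and the root stays within two
# samples of the coarse estimate.
.edge_root <- function(pos, grad, idx, flank, fallback, spacing,
                       offsets = 0:2) {
  sel <- idx + flank * offsets
  if (any(sel < 1L | sel > length(grad))) return(fallback)
  g <- grad[sel]
  if (any(!is.finite(g)) || any(abs(g) < 1e-12)) return(fallback)
  y <- 1 / g^2
  x <- pos[sel]
  xm <- mean(x); ym <- mean(y)
  sl <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  if (!is.finite(sl) || sl * flank <= 0) return(fallback)
  root <- xm - ym / sl
  if (abs(root - pos[idx]) > 2 * spacing) return(fallback)
  root
}

# Refine an inner (endosteal) border: around the coarse radio-opacity
# maximum at `cusp_pos`, fit the medullary radius r of the annulus
# projection model bg + 2*sqrt(R^2-x^2) - 2*sqrt(r^2-x^2) by least squares,
# with centre c0, outer radius Rhat and background fixed from the outer
# borders. `side` is -1 for the left cortex, +1 for the right. Falls back
# to the coarse estimate if the fit window or geometry degenerates.
.fit_inner_border <- function(intensity, pos, c0, Rhat, bg, cusp_pos, side,
                              spacing) {
  r0 <- abs(cusp_pos - c0)
  if (!is.finite(r0) || Rhat <= 2 * spacing || r0 >= Rhat) return(cusp_pos)
  win <- which(abs(pos - cusp_pos) <= 4 * spacing)
  if (length(win) < 5) return(cusp_pos)
  x <- pos[win] - c0
  y <- intensity[win]
  sse <- function(r) {
    m <- bg + 2 * sqrt(pmax(Rhat^2 - x^2, 0)) - 2 * sqrt(pmax(r^2 - x^2, 0))
    sum((m - y)^2)
  }
  lo <- max(r0 - 3 * spacing, spacing)
  hi <- min(r0 + 3 * spacing, Rhat)
  if (hi <= lo) return(cusp_pos)
  opt <- stats::optimize(sse, c(lo, hi), tol = spacing * 1e-4)
  c0 + side * opt$minimum
}

# sub-pixel maximum of v over the index window [lo, hi]; interior peaks only
.subpixel_peak <- function(v, lo, hi, pos, prefer_last = FALSE) {
  lo <- max(lo, 2L); hi <- min(hi, length(v) - 1L)
  if (hi < lo) return(NULL)
  w <- v[lo:hi]
  if (all(is.na(w))) return(NULL)
  i <- if (prefer_last) lo + length(w) - which.max(rev(w))
       else lo + which.max(w) - 1L
  # reject peaks on the window edge that continue to rise outside: a true
  # interior extremum is required only at the profile scale, so only the
  # global profile boundary disqualifies
  if (i <= 1L || i >= length(v)) return(NULL)
  a <- v[i - 1L]; b <- v[i]; c <- v[i + 1L]
  if (any(is.na(c(a, b, c)))) return(list(idx = i, pos = pos[i]))
  off <- .parabolic_offset(a, b, c)
  list(idx = i, pos = pos[i] + off * (pos[2] - pos[1]))
}

#' @export
print.profile_measurement <- function(x, ...) {
  if (x$valid)
    cat(sprintf("profile: W = %.3f mm, T = %.3f mm (left %.3f / right %.3f)\n",
                x$W, x$T, x$T_left, x$T_right))
  else cat("profile: invalid (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Measure cortical thickness and width over a measurement region
#'
#' Samples scanlines strictly perpendicular to the bone axis at one-pixel
#' axial steps across the ROI, measures each with [measure_profile()], and
#' aggregates with a central-80% trimmed mean over the valid profiles (the
#' trimming guards against isolated noise spikes).
#'
#' @param image a `phantom_image`.
#' @param roi a `roi_spec` from [place_roi_bx()] or [place_roi_xp()].
#' @param contour the `bone_contour` the ROI refers to.
#' @param min_valid minimum number of valid profiles required.
#' @return object of class `bone_measurement`: list with `T_mean`, `W_mean`,
#'   `L` (mm), `n_profiles`, `n_valid`, `roi`, `profiles` (data frame with
#'   per-scanline `u`, `W`, `T`, `valid`).
#' @export
measure_roi <- function(image, roi, contour, min_valid = 10L) {
  stopifnot(inherits(roi, "roi_spec"), inherits(contour, "bone_contour"))
  s <- image$pixel_spacing_mm
  du <- s / contour$length_mm
  us <- seq(roi$u_range[1], roi$u_range[2], by = du)
  b <- .scanline_batch(image, contour, us)
  prof <- lapply(seq_along(us), function(i) {
    tryCatch(measure_profile(b$intensity[, i], b$spacing_mm,
                             b$axis_offset_mm[i]),
             dxr_error = function(e) NULL)
  })
  W <- vapply(prof, function(p) if (is.null(p)) NA_real_ else p$W, 0)
  Tt <- vapply(prof, function(p) if (is.null(p)) NA_real_ else p$T, 0)
  valid <- vapply(prof, function(p) !is.null(p) && isTRUE(p$valid), TRUE)
  n_valid <- sum(valid)
  if (n_valid < min_valid)
    .dxr_stop("dxr_insufficient_profiles_error",
              "only %d valid profiles in ROI (need >= %d)", n_valid, min_valid)
  structure(list(
    T_mean = mean(Tt[valid], trim = 0.1),
    W_mean = mean(W[valid], trim = 0.1),
    L = contour$length_mm,
    n_profiles = length(us), n_valid = n_valid, roi = roi,
    profiles = data.frame(u = us, W = W, T = Tt, valid = valid)),
    class = "bone_measurement")
}

#' @export
print.bone_measurement <- function(x, ...) {
  cat(sprintf("bone measurement (%s ROI): T = %.4f mm, W = %.4f mm, L = %.3f mm (%d/%d profiles valid)\n",
              x$roi$mode, x$T_mean, x$W_mean, x$L, x$n_valid, x$n_profiles))
  invisible(x)
}
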