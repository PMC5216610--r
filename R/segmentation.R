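#' Detect metacarpal contours on a phantom radiograph
#'
#' Finds each bone as a closed iso-intensity contour slightly above the
#' background level, identifies the proximal and distal end points, refines
#' both end points to sub-pixel precision by the maximum-gradient criterion
#' along the bone axis, and resamples the boundary to 32 marks at (near)
#' equal arc length. This is a high-contrast counterpart of statistical
#' appearance-model landmarking: adequate for phantoms, not for clinical
#' radiographs.
#'
#' Marks are ordered starting at the distal end point and proceed with a
#' consistent (positive shoelace) orientation; `proximal_idx` is the mark at
#' the proximal end. `length_mm` is the distance between the two end marks.
#'
#' @param image a `phantom_image` or list with `pixels` and
#'   `pixel_spacing_mm`.
#' @param n_expected number of bones expected in the image.
#' @param level_fraction iso-contour level as a fraction of the dynamic
#'   range above background. Chosen low (default 0.15) because projection
#'   images of tubes have gradual square-root edges, so a low level hugs the
#'   true outline; it must stay above the noise floor.
#' @param min_perimeter_mm contours shorter than this are discarded as
#'   noise artefacts.
#' @return list of `bone_contour` objects ordered left to right, each with
#'   fields `marks` (32 x 2 matrix, mm), `proximal_idx`, `distal_idx`,
#'   `axis_unit` (proximal to distal), `length_mm`, `fit_residual_mm`.
#' @export
detect_bone_contours <- function(image, n_expected,
                                 level_fraction = 0.15,
                                 min_perimeter_mm = 25) {
  px <- image$pixels; s <- image$pixel_spacing_mm
  stopifnot(is.matrix(px), s > 0)
  border <- c(px[1, ], px[nrow(px), ], px[, 1], px[, ncol(px)])
  bg <- stats::median(border)
  hi <- stats::quantile(px, 0.999, names = FALSE)
  if (hi - bg < 1e-9) {
    if (n_expected > 0)
      .dxr_stop("dxr_detection_count_error",
                "expected %d bones, found 0 (flat image)", n_expected)
    return(list())
  }
  level <- bg + level_fraction * (hi - bg)

  row_mm <- (seq_len(nrow(px)) - 1) * s
  col_mm <- (seq_len(ncol(px)) - 1) * s
  cl <- grDevices::contourLines(row_mm, col_mm, px, levels = level)

  contours <- list()
  for (cv in cl) {
    # contourLines: $x follows rows of z, $y follows columns
    pts <- cbind(x = cv$y, y = cv$x)
    closed <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9
    per <- sum(sqrt(rowSums(diff(pts)^2)))
    if (per < min_perimeter_mm) next
    if (!closed)
      .dxr_stop("dxr_degenerate_contour_error",
                "open boundary: a bone touches the image border")
    contours[[length(contours) + 1L]] <- pts[-nrow(pts), , drop = FALSE]
  }
  # keep only outermost boundaries: an iso-contour inside another contour
  # is a hole (e.g. where a deep erosion pushes the medullary stripe below
  # the contour level), not a bone
  if (length(contours) > 1) {
    nested <- vapply(seq_along(contours), function(i) {
      p <- contours[[i]][1, ]
      any(vapply(seq_along(contours)[-i], function(j)
        .point_in_polygon(p, contours[[j]]), TRUE))
    }, TRUE)
    contours <- contours[!nested]
  }
  if (length(contours) != n_expected)
    .dxr_stop("dxr_detection_count_error",
              "expected %d bones, found %d", n_expected, length(contours))
  if (n_expected == 0L) return(list())

  out <- lapply(contours, .contour_from_boundary, image = image)
  ord <- order(vapply(out, function(ct) mean(ct$marks[, 1]), 0))
  out[ord]
}

# Build a bone_contour from a raw closed boundary polygon (n x 2, mm).
.contour_from_boundary <- function(bnd, image) {
  ctr <- colMeans(bnd)
  pc <- stats::prcomp(bnd, center = TRUE)$rotation[, 1]
  proj <- (bnd[, 1] - ctr[1]) * pc[1] + (bnd[, 2] - ctr[2]) * pc[2]
  i_lo <- which.min(proj); i_hi <- which.max(proj)
  ends <- rbind(bnd[i_lo, ], bnd[i_hi, ])
  # proximal = end at the lower row index (smaller y)
  if (ends[1, 2] > ends[2, 2]) { tmp <- i_lo; i_lo <- i_hi; i_hi <- tmp }
  p_prox <- bnd[i_lo, ]; p_dist <- bnd[i_hi, ]

  # iterate: refine tips along the current axis, then recompute the axis
  # from the refined tips (the initial PCA axis can be tilted because the
  # boundary vertices are unevenly spaced)
  for (it in 1:2) {
    axis <- p_dist - p_prox; axis <- axis / sqrt(sum(axis^2))
    p_prox <- .refine_tip(image, p_prox, -axis)
    p_dist <- .refine_tip(image, p_dist, axis)
  }
  L <- sqrt(sum((p_dist - p_prox)^2))
  if (L < 1e-9)
    .dxr_stop("dxr_degenerate_contour_error", "coincident end points")
  axis <- unname((p_dist - p_prox) / L)

  marks <- .resample_marks(bnd, i_hi, i_lo, p_dist, p_prox, n = 32L)
  res <- .polygon_rms_distance(bnd, marks)

  structure(list(marks = marks, proximal_idx = 17L, distal_idx = 1L,
                 axis_unit = axis, length_mm = L, fit_residual_mm = res),
            class = "bone_contour")
}

# Sub-pixel bone end point. The projected opacity of a capped tube rises
# from the background with infinite slope exactly at the anatomical end, so
# the end is localised as the (sub-pixel, linearly interpolated) crossing of
# a low intensity level just above the background along the axis direction.
# The level adapts to the image noise floor (estimated from border pixels):
# low levels minimise the inward bias of the crossing, but must stay well
# clear of the noise.
.refine_tip <- function(image, tip, outward, half_window_mm = 2.5) {
  s <- image$pixel_spacing_mm
  px <- image$pixels
  border <- c(px[1, ], px[nrow(px), ], px[, 1], px[, ncol(px)])
  bg <- stats::median(border)
  noise <- stats::mad(border)
  level <- bg + max(0.3, 6 * noise)
  step <- s / 2
  t <- seq(half_window_mm, -half_window_mm, by = -step)  # outside -> inside
  v <- .interp_image(image, tip[1] + t * outward[1], tip[2] + t * outward[2])
  above <- v > level
  # first index (coming from outside) where 3 consecutive samples exceed
  run <- above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE)
  i <- which(run)[1]
  if (is.na(i) || i <= 1) return(tip)
  tt <- t[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
  c(tip[1] + tt * outward[1], tip[2] + tt * outward[2])
}

# vertex offset of the parabola through (-1,a),(0,b),(1,c); clamped to [-1,1]
.parabolic_offset <- function(a, b, c) {
  den <- a - 2 * b + c
  if (!is.finite(den) || abs(den) < 1e-300) return(0)
  max(-1, min(1, 0.5 * (a - c) / den))
}

# bilinear interpolation of image intensities at mm positions (x = cols);
# positions are clamped to the image extent
.interp_image <- function(image, x_mm, y_mm) {
  s <- image$pixel_spacing_mm; px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  cx <- pmin(pmax(x_mm / s, 0), nc - 1)
  cy <- pmin(pmax(y_mm / s, 0), nr - 1)
  j0 <- pmin(floor(cx), nc - 2); i0 <- pmin(floor(cy), nr - 2)
  fx <- cx - j0; fy <- cy - i0
  base <- i0 + 1 + j0 * nr  # linear index of (i0+1, j0+1)
  (1 - fx) * ((1 - fy) * px[base] + fy * px[base + 1]) +
    fx * ((1 - fy) * px[base + nr] + fy * px[base + nr + 1])
}

# Resample the closed boundary into n marks: the polygon is split at the
# vertices nearest the two end points into two arcs; each arc is resampled
# at equal arc length (n/2 + 1 points including its end points), the arc
# ends are snapped to the refined tips, and the arcs are joined. Mark 1 is
# the distal end, mark n/2 + 1 the proximal end.
.resample_marks <- function(bnd, i_dist, i_prox, p_dist, p_prox, n = 32L) {
  m <- nrow(bnd)
  idx <- function(i) ((i - 1) %% m) + 1
  half <- n %/% 2L
  arc_idx_1 <- idx(seq(i_dist, i_dist + ((i_prox - i_dist) %% m)))
  arc_idx_2 <- idx(seq(i_prox, i_prox + ((i_dist - i_prox) %% m)))
  a1 <- bnd[arc_idx_1, , drop = FALSE]
  a2 <- bnd[arc_idx_2, , drop = FALSE]
  a1[1, ] <- p_dist; a1[nrow(a1), ] <- p_prox
  a2[1, ] <- p_prox; a2[nrow(a2), ] <- p_dist
  r1 <- .resample_polyline(a1, half + 1L)
  r2 <- .resample_polyline(a2, half + 1L)
  marks <- rbind(r1, r2[-c(1L, nrow(r2)), , drop = FALSE])
  # enforce a consistent orientation (positive shoelace sum)
  if (.shoelace(marks) < 0) {
    marks <- marks[c(1L, rev(seq_len(nrow(marks))[-1L])), , drop = FALSE]
  }
  dimnames(marks) <- list(NULL, c("x", "y"))
  marks
}

.resample_polyline <- function(p, k) {
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  tot <- cum[length(cum)]
  tq <- seq(0, tot, length.out = k)
  cbind(stats::approx(cum, p[, 1], xout = tq, ties = "ordered")$y,
        stats::approx(cum, p[, 2], xout = tq, ties = "ordered")$y)
}

# even-odd (ray casting) point-in-polygon test
.point_in_polygon <- function(p, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  crosses <- ((y > p[2]) != (y[j] > p[2])) &
    (p[1] < (x[j] - x) * (p[2] - y) / (y[j] - y) + x)
  sum(crosses, na.rm = TRUE) %% 2 == 1
}

# signed shoelace area of a polygon (rows = vertices)
.shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Signed area enclosed by a contour's 32 marks
#' @param contour a `bone_contour`.
#' @return area in mm^2 (positive).
#' @export
contour_area <- function(contour) abs(.shoelace(contour$marks))

# RMS distance from points to the closed polygon through `marks`
.polygon_rms_distance <- function(pts, marks) {
  m <- rbind(marks, marks[1, ])
  a <- m[-nrow(m), , drop = FALSE]
  b <- m[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  d2min <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(a))) {
    t <- ((pts[, 1] - a[k, 1]) * ab[k, 1] + (pts[, 2] - a[k, 2]) * ab[k, 2]) /
      max(len2[k], 1e-300)
    t <- pmin(pmax(t, 0), 1)
    d2 <- (pts[, 1] - (a[k, 1] + t * ab[k, 1]))^2 +
          (pts[, 2] - (a[k, 2] + t * ab[k, 2]))^2
    d2min <- pmin(d2min, d2)
  }
  sqrt(mean(d2min))
}

#' Recompute the bone axis and length from a contour's end marks
#'
#' Idempotent: the axis is the unit vector from the proximal to the distal
#' mark and the length their Euclidean distance.
#'
#' @param contour a `bone_contour`.
#' @return list with `axis_unit` and `length_mm`.
#' @export
bone_axis_and_length <- function(contour) {
  p <- contour$marks[contour$proximal_idx, ]
  d <- contour$marks[contour$distal_idx, ]
  L <- sqrt(sum((d - p)^2))
  if (L < 1e-12)
    .dxr_stop("dxr_degenerate_contour_error",
              "proximal and distal marks coincide")
  list(axis_unit = (d - p) / L, length_mm = L)
}

#' @export
print.bone_contour <- function(x, ...) {
  cat(sprintf("bone contour: 32 marks, L = %.3f mm, axis (%.3f, %.3f), fit RMS %.4f mm\n",
              x$length_mm, x$axis_unit[1], x$axis_unit[2], x$fit_residual_mm))
  invisible(x)
}

#' Serialise a bone contour to JSON
#' @param contour a `bone_contour`.
#' @return a JSON string.
#' @export
contour_to_json <- function(contour) {
  jsonlite::toJSON(list(
    marks = unname(contour$marks),
    proximal_idx = contour$proximal_idx, distal_idx = contour$distal_idx,
    axis_unit = contour$axis_unit, length_mm = contour$length_mm,
    fit_residual_mm = contour$fit_residual_mm),
    auto_unbox = TRUE, digits = NA)
}

#' Reconstruct a bone contour from its JSON serialisation
#' @param txt JSON string produced by [contour_to_json()].
#' @return a `bone_contour`.
#' @export
contour_from_json <- function(txt) {
  o <- jsonlite::fromJSON(txt)
  structure(list(marks = matrix(o$marks, ncol = 2,
                                dimnames = list(NULL, c("x", "y"))),
                 proximal_idx = as.integer(o$proximal_idx),
                 distal_idx = as.integer(o$distal_idx),
                 axis_unit = as.numeric(o$axis_unit),
                 length_mm = o$length_mm,
                 fit_residual_mm = o$fit_residual_mm),
            class = "bone_contour")
}
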