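#' Metacarpal index (classical definition)
#'
#' The classical metacarpal index is the ratio of the combined cortical
#' thickness to the outer bone width, `2 * T / W`. It is dimensionless and
#' therefore invariant to radiographic magnification.
#'
#' @param T cortical thickness (mm), one cortex.
#' @param W outer bone width (mm).
#' @return `2 * T / W`.
#' @examples
#' mci_xp(2, 10)  # 0.4
#' @export
mci_xp <- function(T, W) {
  .check_tw(T, W, allow_half = FALSE)
  2 * T / W
}

#' Cortical cross-sectional area
#'
#' The cortical shell of a tubular bone with outer width `W` and cortical
#' thickness `T` has cross-sectional area `pi * T * W * (1 - T/W)`, which is
#' exactly the area of the annulus with outer diameter `W` and inner
#' diameter `W - 2T`.
#'
#' @inheritParams mci_xp
#' @return area in mm^2.
#' @examples
#' cortical_area(1, 10)       # 9 * pi
#' cortical_area(5, 10)       # full disc: 25 * pi
#' @export
cortical_area <- function(T, W) {
  .check_tw(T, W, allow_half = TRUE)
  pi * T * W * (1 - T / W)
}

#' Bone health index
#'
#' A size-adjusted cortical index, `A / (W^1.333 * L^0.333)`. Unlike the
#' metacarpal index it is not dimensionless: under uniform scaling of all
#' lengths by `f` it changes by `f^(2 - 1.666)`, so it is not invariant to
#' radiographic magnification. The exponents are used as printed (1.333,
#' 0.333); set `exact_thirds = TRUE` for 4/3 and 1/3.
#'
#' @param area cortical area (mm^2).
#' @param W outer bone width (mm).
#' @param L bone length (mm).
#' @param exact_thirds use exponents 4/3 and 1/3 instead of 1.333 and 0.333.
#' @return the index value.
#' @examples
#' bone_health_index(cortical_area(1, 10), 10, 60)
#' @export
bone_health_index <- function(area, W, L, exact_thirds = FALSE) {
  if (any(area <= 0) || any(W <= 0) || any(L <= 0))
    .dxr_stop("dxr_geometry_error", "area, W and L must be positive")
  ew <- if (exact_thirds) 4 / 3 else 1.333
  el <- if (exact_thirds) 1 / 3 else 0.333
  area / (W^ew * L^el)
}

#' Metacarpal index (area definition)
#'
#' The area-based metacarpal index `A / W^2`, algebraically equal to
#' `pi * (T/W) * (1 - T/W)`. Dimensionless, maximal at `pi/4` for a bone
#' with no medullary cavity (`T = W/2`).
#'
#' @param area cortical area (mm^2).
#' @param W outer bone width (mm).
#' @return `area / W^2`.
#' @examples
#' mci_bx(cortical_area(1, 10), 10)  # 9 * pi / 100
#' @export
mci_bx <- function(area, W) {
  if (any(area <= 0) || any(W <= 0))
    .dxr_stop("dxr_geometry_error", "area and W must be positive")
  area / W^2
}

#' Divisor used to adjust the thickness-ratio index for ROI-length bias
#'
#' A narrowest-point ROI is in general longer (about 30% of bone length)
#' than the proportional 25% ROI, so the proportional rule yields on
#' average larger thickness-ratio values; dividing by this empirically
#' derived constant aligns the two scales.
#' @export
mci_adjustment_divisor <- 1.084

#' Thickness-ratio index with and without the ROI-size adjustment
#'
#' Computes the naive thickness-ratio index `2 * T / W` from a
#' proportional-ROI measurement, together with the adjusted variant
#' `naive / divisor` that compensates the systematic offset against
#' narrowest-point measurements.
#'
#' @inheritParams mci_xp
#' @param divisor adjustment divisor; defaults to
#'   [mci_adjustment_divisor].
#' @return list with `naive` and `adjusted`.
#' @examples
#' mci_naive_adjusted(2, 10)
#' @export
mci_naive_adjusted <- function(T, W, divisor = mci_adjustment_divisor) {
  naive <- mci_xp(T, W)
  if (any(divisor <= 0))
    .dxr_stop("dxr_geometry_error", "divisor must be positive")
  list(naive = naive, adjusted = naive / divisor)
}

.check_tw <- function(T, W, allow_half) {
  bad <- if (allow_half) any(T <= 0) || any(W <= 0) || any(T > W / 2)
         else any(T <= 0) || any(W <= 0) || any(T >= W / 2)
  if (bad)
    .dxr_stop("dxr_geometry_error",
              "need 0 < T %s W/2 (cortices may not overlap); got T=%g, W=%g",
              if (allow_half) "<=" else "<", T[1], W[1])
  invisible(TRUE)
}

#' Compute the full index set for one hand
#'
#' Averages the per-bone measurements (cortical thickness, width, length)
#' across the selected bones first, then computes every index from the
#' means — the aggregation order used by both measurement systems, which
#' report T and W as means over the three middle metacarpals (II, III, IV)
#' before forming the index.
#'
#' @param bones data frame (or list of lists) with columns/fields `T`, `W`,
#'   `L` in mm, one row per bone, ordered II..V (or any identified order).
#' @param selection indices of the bones to aggregate (default 1:3,
#'   i.e. metacarpals II-IV of a hand measured left to right).
#' @param policy `"require-all"` errors when a selected bone is missing
#'   (non-finite T/W/L); `"available"` averages over the bones present.
#' @param divisor adjustment divisor for the adjusted thickness-ratio
#'   index.
#' @param ratio_then_mean compute per-bone indices first and average those
#'   instead (alternative aggregation, off by default).
#' @return an object of class `index_set`: list with `t_mm`, `w_mm`,
#'   `l_mm`, `mci_xp`, `area`, `bhi`, `mci_bx`, `mci_naive`, `mci_adj`,
#'   `n_bones`.
#' @examples
#' aggregate_indices(data.frame(T = c(1.5, 1.8, 2.1), W = 9, L = 60))
#' @export
aggregate_indices <- function(bones, selection = NULL,
                              policy = c("require-all", "available"),
                              divisor = mci_adjustment_divisor,
                              ratio_then_mean = FALSE) {
  policy <- match.arg(policy)
  if (is.data.frame(bones)) df <- bones
  else df <- do.call(rbind, lapply(bones, function(b)
    data.frame(T = b$T, W = b$W, L = b$L)))
  if (is.null(selection)) selection <- seq_len(min(3L, nrow(df)))
  if (length(selection) == 0)
    .dxr_stop("dxr_aggregate_error", "empty bone selection")
  if (any(selection < 1 | selection > nrow(df)))
    .dxr_stop("dxr_aggregate_error", "bone selection out of range")
  df <- df[selection, , drop = FALSE]
  okrow <- is.finite(df$T) & is.finite(df$W) & is.finite(df$L)
  if (policy == "require-all" && !all(okrow))
    .dxr_stop("dxr_aggregate_error",
              "%d of %d selected bones missing a measurement",
              sum(!okrow), nrow(df))
  df <- df[okrow, , drop = FALSE]
  if (nrow(df) == 0)
    .dxr_stop("dxr_aggregate_error", "no measurable bones in selection")

  if (ratio_then_mean) {
    per <- lapply(seq_len(nrow(df)), function(i)
      .index_set_one(df$T[i], df$W[i], df$L[i], divisor))
    out <- per[[1]]
    for (f in c("mci_xp", "area", "bhi", "mci_bx", "mci_naive", "mci_adj"))
      out[[f]] <- mean(vapply(per, `[[`, 0, f))
    out$t_mm <- mean(df$T); out$w_mm <- mean(df$W); out$l_mm <- mean(df$L)
  } else {
    out <- .index_set_one(mean(df$T), mean(df$W), mean(df$L), divisor)
  }
  out$n_bones <- nrow(df)
  structure(out, class = "index_set")
}

.index_set_one <- function(T, W, L, divisor) {
  A <- cortical_area(T, W)
  na <- mci_naive_adjusted(T, W, divisor)
  list(t_mm = T, w_mm = W, l_mm = L,
       mci_xp = mci_xp(T, W), area = A,
       bhi = bone_health_index(A, W, L),
       mci_bx = mci_bx(A, W),
       mci_naive = na$naive, mci_adj = na$adjusted)
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf(
    "bone indices (%d bones): T %.4f mm, W %.4f mm, L %.3f mm\n  MCI 2T/W %.4g | MCI A/W^2 %.4g (adj %.4g) | A %.4g mm^2 | BHI %.4g\n",
    x$n_bones, x$t_mm, x$w_mm, x$l_mm, x$mci_xp, x$mci_bx, x$mci_adj,
    x$area, x$bhi))
  invisible(x)
}
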