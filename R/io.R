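#' Write a phantom radiograph to disk with a ground-truth sidecar
#'
#' Images are written with intensities rescaled to `[0, 1]` (offset and
#' scale recorded in the sidecar, so loading restores the original values):
#' as 32-bit float TIFF for faithful round trips, or as 8-bit grayscale PNG
#' for quick viewing (quantised to 1/255 of the dynamic range). A JSON
#' sidecar `<image>.json` stores the pixel spacing, seed, intensity scaling
#' and the ground-truth bone geometry sampled on a fixed axial grid.
#'
#' @param image a `phantom_image`.
#' @param path output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  lo <- min(image$pixels); hi <- max(image$pixels)
  scale <- if (hi > lo) hi - lo else 1
  if (ext == "png") {
    png::writePNG((image$pixels - lo) / scale, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF((image$pixels - lo) / scale, path,
                    bits.per.sample = 32L, reduce = FALSE)
  } else .dxr_stop("dxr_io_error", "unsupported image format: .%s", ext)

  truth <- lapply(image$truth, function(s) {
    ug <- seq(0, 1, length.out = 201)
    list(length_mm = s$length_mm,
         proximal_origin_mm = s$proximal_origin_mm,
         axis_angle_deg = s$axis_angle_deg,
         u = ug,
         outer_radius_mm = s$outer_radius_mm(ug),
         cortical_thickness_mm = s$cortical_thickness_mm(ug),
         erosion = s$erosion)
  })
  jsonlite::write_json(
    list(pixel_spacing_mm = image$pixel_spacing_mm, seed = image$seed,
         rng_kind = image$rng_kind, noise_sd = image$noise_sd,
         background_level = image$background_level,
         intensity_offset = lo, intensity_scale = scale, bones = truth),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a radiograph-like image with pixel-spacing calibration
#'
#' Reads a PNG or TIFF image into the matrix-plus-spacing structure the
#' measurement functions use. Radiogrammetry is meaningless without a
#' physical calibration, so the pixel spacing must come from somewhere:
#' the JSON sidecar written by [write_phantom()] if present, else the
#' `spacing_mm` argument; with neither, loading fails.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @param spacing_mm pixel spacing fallback when no sidecar is present.
#' @return a `phantom_image`-compatible list (without ground truth unless a
#'   sidecar provides rendering metadata).
#' @export
load_image <- function(path, spacing_mm = NULL) {
  if (!file.exists(path)) .dxr_stop("dxr_io_error", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .dxr_stop("dxr_io_error", "unsupported image format: .%s", ext))
  if (length(dim(px)) == 3) px <- px[, , 1]

  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else NULL
  spacing <- if (!is.null(meta$pixel_spacing_mm)) meta$pixel_spacing_mm
             else spacing_mm
  if (is.null(spacing) || !is.finite(spacing) || spacing <= 0)
    .dxr_stop("dxr_io_error",
              "unknown pixel spacing for %s: provide a sidecar or spacing_mm",
              path)
  if (!is.null(meta$intensity_scale))
    px <- px * meta$intensity_scale + meta$intensity_offset
  structure(list(pixels = px, pixel_spacing_mm = spacing,
                 truth = NULL, noise_sd = meta$noise_sd %||% NA_real_,
                 background_level = meta$background_level %||% NA_real_,
                 seed = meta$seed %||% NA_integer_,
                 rng_kind = meta$rng_kind %||% NA_character_),
            class = "phantom_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-bone measurements as CSV
#'
#' One row per bone: `bone_id, mode, L_mm, T_mm, W_mm, n_profiles, n_valid,
#' status`.
#'
#' @param hand a `hand_measurement` from [run_pipeline()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(hand, path) {
  df <- do.call(rbind, lapply(seq_along(hand$bones), function(i) {
    b <- hand$bones[[i]]
    data.frame(bone_id = i, mode = b$measurement$roi$mode,
               L_mm = b$measurement$L, T_mm = b$measurement$T_mean,
               W_mm = b$measurement$W_mean,
               n_profiles = b$measurement$n_profiles,
               n_valid = b$measurement$n_valid,
               status = b$validation$status)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a hand measurement (indices + validation) to JSON
#' @param hand a `hand_measurement`.
#' @return JSON string.
#' @export
hand_to_json <- function(hand) {
  idx <- hand$indices
  jsonlite::toJSON(list(
    mode = hand$mode,
    bones_used = hand$bones_used,
    indices = idx[c("t_mm", "w_mm", "l_mm", "mci_xp", "area", "bhi",
                    "mci_bx", "mci_naive", "mci_adj")],
    per_bone = lapply(hand$bones, function(b) list(
      T_mm = b$measurement$T_mean, W_mm = b$measurement$W_mean,
      L_mm = b$measurement$L, n_valid = b$measurement$n_valid,
      status = b$validation$status)),
    status = hand$status,
    provenance = hand$provenance),
    auto_unbox = TRUE, digits = NA)
}
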