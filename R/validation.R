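#' Default self-validation configuration
#'
#' The measurement system has no published validation criteria, so this
#' check set is the package's own, chosen from adult metacarpal anatomy and
#' from the statistical quality of the profile measurements. Hard checks
#' encode anatomy (a result outside them cannot be a metacarpal shaft
#' measurement); soft checks encode measurement quality. Every threshold is
#' configurable.
#'
#' @param w_range plausible mean shaft width (mm), hard bounds.
#' @param l_range plausible adult metacarpal length (mm), hard bounds.
#' @param cv_w_max maximum coefficient of variation of W across profiles
#'   (soft).
#' @param valid_frac_min minimum fraction of valid profiles (soft).
#' @param residual_max maximum contour fit residual, mm (soft).
#' @param margin_min margin required to auto-accept, as a fraction of each
#'   soft bound's allowed interval width.
#' @return a named list of thresholds.
#' @export
validation_config <- function(w_range = c(4, 15), l_range = c(40, 90),
                              cv_w_max = 0.08, valid_frac_min = 0.8,
                              residual_max = 0.5, margin_min = 0.1) {
  list(w_range = w_range, l_range = l_range, cv_w_max = cv_w_max,
       valid_frac_min = valid_frac_min, residual_max = residual_max,
       margin_min = margin_min)
}

#' Self-validate a bone measurement
#'
#' Classifies an analysis as `"accept"`, `"questionable"` or `"reject"`,
#' mirroring the three-way outcome of a self-validating radiogrammetry
#' system: results are auto-accepted when every check passes with a safety
#' margin, auto-rejected when an anatomical (hard) check fails, and flagged
#' questionable — i.e. for human review — in between.
#'
#' Hard checks: mean width within `w_range`; cortical thickness below half
#' the width; bone length within `l_range`. Soft checks: coefficient of
#' variation of the width across profiles at most `cv_w_max`; fraction of
#' valid profiles at least `valid_frac_min`; contour fit residual at most
#' `residual_max`. A soft check passes "with margin" when it clears its
#' threshold by at least `margin_min` of the allowed interval's width.
#'
#' @param bone a `bone_measurement` from [measure_roi()].
#' @param contour the corresponding `bone_contour` (for the fit residual);
#'   may be `NULL`, which skips the residual check.
#' @param config thresholds from [validation_config()].
#' @return object of class `validation_report`: list with `status`,
#'   `checks` (data frame: name, value, ok, hard, margin), `reasons`.
#' @export
self_validate <- function(bone, contour = NULL,
                          config = validation_config()) {
  stopifnot(inherits(bone, "bone_measurement"))
  Wv <- bone$profiles$W[bone$profiles$valid]
  cv_w <- if (length(Wv) >= 2) stats::sd(Wv) / mean(Wv) else Inf
  valid_frac <- bone$n_valid / bone$n_profiles

  checks <- list(
    .check_hard("width_mm", bone$W_mean, config$w_range),
    .check_hard("thickness_vs_width", bone$T_mean,
                c(0, bone$W_mean / 2), open_upper = TRUE),
    .check_hard("length_mm", bone$L, config$l_range),
    .check_soft("cv_width", cv_w, upper = config$cv_w_max,
                width = config$cv_w_max),
    .check_soft("valid_profile_fraction", valid_frac,
                lower = config$valid_frac_min,
                width = 1 - config$valid_frac_min))
  if (!is.null(contour))
    checks <- c(checks, list(
      .check_soft("contour_fit_residual_mm", contour$fit_residual_mm,
                  upper = config$residual_max, width = config$residual_max)))

  df <- do.call(rbind, lapply(checks, as.data.frame))
  hard_fail <- any(!df$ok & df$hard)
  all_with_margin <- all(df$ok & (df$hard | df$margin >= config$margin_min))
  status <- if (hard_fail) "reject"
            else if (all_with_margin) "accept"
            else "questionable"
  reasons <- character(0)
  bad <- df[!df$ok | (!df$hard & df$margin < config$margin_min), ]
  if (nrow(bad))
    reasons <- sprintf("%s = %.4g %s", bad$name, bad$value,
                       ifelse(bad$ok, "(insufficient margin)", "(failed)"))
  structure(list(status = status, checks = df, reasons = reasons),
            class = "validation_report")
}

# hard anatomical bound: pass/fail, no margin notion
.check_hard <- function(name, value, range, open_upper = FALSE) {
  ok <- is.finite(value) && value >= range[1] &&
    (if (open_upper) value < range[2] else value <= range[2])
  list(name = name, value = value, ok = ok, hard = TRUE, margin = NA_real_)
}

# soft quality bound: margin = distance to the threshold as a fraction of
# the allowed interval's width
.check_soft <- function(name, value, lower = NULL, upper = NULL, width) {
  if (!is.null(upper)) { ok <- is.finite(value) && value <= upper
                         margin <- (upper - value) / width }
  else { ok <- is.finite(value) && value >= lower
         margin <- (value - lower) / width }
  list(name = name, value = value, ok = ok, hard = FALSE,
       margin = if (is.finite(margin)) margin else -Inf)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("self-validation:", toupper(x$status), "\n")
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}
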