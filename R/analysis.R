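#' Construct a 32-joint ordinal damage assessment
#'
#' The modified Larsen scheme grades 32 joints of the hands and feet on an
#' ordinal 0-5 scale (0 normal; 1 periarticular demineralisation / soft
#' tissue swelling / initial joint-space narrowing; 2 initial erosions;
#' 3 multiple erosions; 4 partial ankylosis; 5 ankylosis or mutilation),
#' for a maximum total of 160 points. The per-patient summary is the sum of
#' points divided by the number of evaluated joints.
#'
#' @param joint_scores integer vector of length 32 with values 0-5; `NA`
#'   marks joints that could not be evaluated.
#' @param evaluated logical mask of evaluated joints; defaults to
#'   `!is.na(joint_scores)`.
#' @param erosions_present optional explicit erosion flag; when absent it
#'   is derived from the scores (any evaluated joint at grade 2 or higher
#'   implies erosive disease).
#' @return object of class `larsen_assessment` with fields `joint_scores`,
#'   `evaluated`, `mean_score`, `erosions_present`.
#' @export
larsen_assessment <- function(joint_scores, evaluated = NULL,
                              erosions_present = NULL) {
  if (length(joint_scores) != 32L)
    .dxr_stop("dxr_larsen_error", "need exactly 32 joint scores")
  if (is.null(evaluated)) evaluated <- !is.na(joint_scores)
  sc <- joint_scores[evaluated]
  if (any(is.na(sc)) || any(sc < 0 | sc > 5) || any(sc != round(sc)))
    .dxr_stop("dxr_larsen_error",
              "evaluated joint scores must be integers in 0..5")
  if (sum(evaluated) == 0)
    .dxr_stop("dxr_larsen_error", "no evaluated joints")
  if (is.null(erosions_present)) erosions_present <- any(sc >= 2)
  structure(list(joint_scores = joint_scores, evaluated = evaluated,
                 mean_score = sum(sc) / sum(evaluated),
                 erosions_present = isTRUE(erosions_present)),
            class = "larsen_assessment")
}

#' Mean ordinal damage score over evaluated joints
#' @param assessment a [larsen_assessment()].
#' @return the sum of scoring points divided by the number of evaluated
#'   joints.
#' @export
larsen_mean <- function(assessment) {
  stopifnot(inherits(assessment, "larsen_assessment"))
  assessment$mean_score
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the argument checks the
#' downstream bootstrap relies on (equal lengths, minimum n, non-degenerate
#' variance).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) .dxr_stop("dxr_stat_error", "unequal lengths")
  if (length(x) < 3) .dxr_stop("dxr_stat_error", "need n >= 3")
  if (anyNA(x) || anyNA(y)) .dxr_stop("dxr_stat_error", "missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .dxr_stop("dxr_undefined_correlation_error",
              "zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Bootstrap comparison of two dependent correlations
#'
#' Tests whether two indices `yA` and `yB` correlate differently with a
#' common covariate `x` (e.g. two metacarpal-index variants against a
#' clinical severity score), by resampling patients (rows) with
#' replacement, preserving the pairing of `(x, yA, yB)`. For each replicate
#' the difference `d* = r(x*, yA*) - r(x*, yB*)` is computed; the two-sided
#' p-value is the fraction-based tail probability of 0 under the bootstrap
#' distribution of `d*` (percentile-interval inversion), and
#' `critical_diff` is the half-width of the central 95% interval of `d*`:
#' an observed difference larger in magnitude than `critical_diff`
#' corresponds to a 95% percentile interval excluding zero.
#'
#' @param x common covariate.
#' @param yA,yB the two index vectors, paired with `x`.
#' @param reps number of bootstrap replicates (>= 1000).
#' @param seed integer seed (mandatory: results are deterministic given the
#'   seed).
#' @param conf confidence level for `critical_diff`.
#' @return object of class `correlation_comparison`: list with `r1`, `r2`,
#'   `diff`, `boot_reps`, `critical_diff`, `p_value`, `seed`.
#' @export
bootstrap_compare_correlations <- function(x, yA, yB, reps = 2000, seed,
                                           conf = 0.95) {
  n <- length(x)
  if (length(yA) != n || length(yB) != n)
    .dxr_stop("dxr_stat_error", "unequal lengths")
  if (n < 10) .dxr_stop("dxr_stat_error", "need n >= 10")
  if (reps < 1000) .dxr_stop("dxr_stat_error", "need reps >= 1000")
  r1 <- pearson_r(x, yA); r2 <- pearson_r(x, yB)
  d_obs <- r1 - r2

  dstar <- with_dxr_seed(seed, {
    out <- numeric(reps)
    filled <- 0L; tries <- 0L
    while (filled < reps) {
      tries <- tries + 1L
      if (tries > 20L)
        .dxr_stop("dxr_stat_error",
                  "too many degenerate bootstrap resamples")
      m <- reps - filled
      idx <- matrix(sample.int(n, n * m, replace = TRUE), m, n)
      X <- matrix(x[idx], m, n)
      A <- matrix(yA[idx], m, n)
      B <- matrix(yB[idx], m, n)
      rr <- .row_cor(X, A) - .row_cor(X, B)
      good <- is.finite(rr)
      k <- sum(good)
      if (k) out[filled + seq_len(k)] <- rr[good]
      filled <- filled + k
    }
    out
  })

  q <- stats::quantile(dstar, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  p <- 2 * min(mean(dstar <= 0), mean(dstar >= 0))
  structure(list(r1 = r1, r2 = r2, diff = d_obs, boot_reps = reps,
                 critical_diff = (q[2] - q[1]) / 2,
                 p_value = min(p, 1), seed = as.integer(seed)),
            class = "correlation_comparison")
}

# row-wise Pearson correlation of two matrices (rows = replicates)
.row_cor <- function(X, Y) {
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  rowSums(Xc * Yc) / sqrt(rowSums(Xc^2) * rowSums(Yc^2))
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "correlation comparison: r1 = %.3f, r2 = %.3f, diff = %.4f\n  bootstrap (%d reps, seed %d): critical difference %.4f, p = %.4f\n",
    x$r1, x$r2, x$diff, x$boot_reps, x$seed, x$critical_diff, x$p_value))
  invisible(x)
}

#' Percent difference of group means
#'
#' `100 * (mean(flagged) - mean(unflagged)) / mean(unflagged)`: the percent
#' change of the flagged group (e.g. patients with erosions) relative to
#' the unflagged group.
#'
#' @param values numeric vector.
#' @param group_flags logical vector of the same length.
#' @return percent difference (negative when the flagged group is lower).
#' @export
group_percent_difference <- function(values, group_flags) {
  if (length(values) != length(group_flags))
    .dxr_stop("dxr_stat_error", "unequal lengths")
  g1 <- values[group_flags]; g0 <- values[!group_flags]
  if (!length(g1) || !length(g0))
    .dxr_stop("dxr_stat_error", "both groups must be non-empty")
  100 * (mean(g1) - mean(g0)) / mean(g0)
}

#' Paired agreement: SD of differences as percent of the mean
#'
#' `100 * sd(a - b) / mean((a + b)/2)`: the standard deviation between two
#' paired measurement series expressed as a percentage of their common
#' mean. A pure constant offset gives 0%.
#'
#' @param a,b paired numeric vectors.
#' @return percent.
#' @export
paired_agreement_sd_percent <- function(a, b) {
  if (length(a) != length(b)) .dxr_stop("dxr_stat_error", "unequal lengths")
  if (length(a) < 3) .dxr_stop("dxr_stat_error", "need n >= 3")
  m <- mean((a + b) / 2)
  if (abs(m) < 1e-12)
    .dxr_stop("dxr_stat_error", "zero mean: percent scale undefined")
  100 * stats::sd(a - b) / m
}

#' Classify erosive disease by a fixed index threshold
#'
#' Flags patients whose cortical index falls below a fixed threshold and,
#' when truth labels are supplied, tabulates the confusion counts.
#'
#' @param mci numeric vector of index values.
#' @param threshold classification threshold (flag when `mci < threshold`).
#' @param truth optional logical vector of true erosion status.
#' @return list with `flags` and (when truth given) `tp`, `fp`, `tn`,
#'   `fn`, `misclassification_rate`.
#' @export
erosion_threshold_classify <- function(mci, threshold, truth = NULL) {
  if (length(threshold) != 1L || is.na(threshold))
    .dxr_stop("dxr_stat_error", "threshold must be a single number")
  flags <- mci < threshold
  out <- list(flags = flags)
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    out$tp <- sum(flags & truth); out$fp <- sum(flags & !truth)
    out$tn <- sum(!flags & !truth); out$fn <- sum(!flags & truth)
    out$misclassification_rate <- (out$fp + out$fn) / length(mci)
  }
  out
}
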