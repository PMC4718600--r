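#' Sample a fitted tuning curve on a fine angular grid
#'
#' @param fit a `"tunefit"` object.
#' @param resolution grid step in degrees; must divide 360 (default 1).
#' @return list with `theta` (angles `0, r, 2r, ... < 360`), `values` and
#'   `source = "fitted"`, suitable for [extract_features()].
#' @export
sample_curve <- function(fit, resolution = 1) {
  if (360 %% resolution != 0) stop("resolution must divide 360")
  theta <- seq(0, 360 - resolution, by = resolution)
  list(theta = theta,
       values = eval_tuning(fit$family, fit$params, theta, fit$modality),
       source = "fitted")
}

# Tie-break helper: among candidate indices attaining an extremum, prefer the
# angle closest to `prefer` (if given), then the smallest angle.
pick_angle <- function(theta, idx, prefer = NULL) {
  if (!is.null(prefer)) {
    d <- abs(theta[idx] - prefer)
    d <- pmin(d, 360 - d)
    idx <- idx[d == min(d)]
  }
  idx[which.min(theta[idx])]
}

# Walk outward from peak index `p` (wrapped) while the baseline-subtracted
# value stays at or above `thr`; returns the angular span covered.
bandwidth_walk <- function(values, p, thr, res) {
  n <- length(values)
  right <- 0L
  while (right < n - 1L && values[(p - 1L + right + 1L) %% n + 1L] >= thr) {
    right <- right + 1L
  }
  left <- 0L
  while (left + right < n - 1L && values[(p - 1L - left - 1L) %% n + 1L] >= thr) {
    left <- left + 1L
  }
  if (left + right >= n - 1L) 360 else (left + right) * res
}

# Weighted third standardized moment of angle over an index arc (already
# ordered along the curve, with unwrapped angles).
weighted_skewness <- function(theta_unwrapped, w) {
  w <- pmax(w, 0)
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  mu <- sum(w * theta_unwrapped) / sw
  v <- sum(w * (theta_unwrapped - mu)^2) / sw
  if (v <= 0) return(NA_real_)
  sum(w * (theta_unwrapped - mu)^3) / sw / v^1.5
}

FEATURE_NAMES <- c(
  "GlobalMinimum", "GlobalMaximum", "GlobalMinimumAngle",
  "MaximumLeft", "MaximumRight", "MaximumAngleLeft", "MaximumAngleRight",
  "PeakToPeakLeft", "PeakToPeakRight", "DeltaPeakToPeak",
  "InnerMinimum", "InnerMinimumAngle", "OuterMinimumAngle",
  "InnerWidthLeft", "InnerWidthRight", "DeltaInnerWidth",
  "OuterWidthLeft", "OuterWidthRight", "DeltaOuterWidth",
  "Bandwidth25Left", "Bandwidth25Right", "Bandwidth50Left", "Bandwidth50Right",
  "Bandwidth75Left", "Bandwidth75Right",
  "SkewnessRight", "minusSkewnessLeft", "DeltaSkewness",
  "CircularVariance",
  "normalizedGlobalMinimum", "normalizedGlobalMaximum",
  "normalizedMaximumLeft", "normalizedMaximumRight",
  "normalizedPeakToPeakLeft", "normalizedPeakToPeakRight",
  "normalizedInnerMinimum"
)

#' Algorithmic ("direct") extraction of tuning-curve shape features
#'
#' Extracts named scalar shape features from a sampled tuning curve -- either
#' the 12 trial-mean data points themselves (the direct method) or a finely
#' sampled fitted profile -- without reference to any model parameters.
#' The curve is assumed aligned so the preferred direction (right peak) sits
#' at 240 degrees.
#'
#' For bimodal (two-stimulus) curves the left peak is the maximum over
#' angles in \[0, 180) and the right peak over \[180, 360); the inner minimum
#' is the minimum strictly between the two peak angles and the outer minimum
#' the minimum on the complementary wrapped arc.  Widths are peak-to-minimum
#' angular distances, `Bandwidth X%` is the angular span around a peak over
#' which the baseline-subtracted rate stays at or above `X`% of that peak's
#' elevation (no interpolation: on the 12-point grid all angular features are
#' multiples of 30 degrees), and peak skewnesses are weighted third
#' standardized moments of angle over each peak's support with
#' baseline-subtracted rates as weights.  Unimodal curves report the global
#' peak as the right peak plus the circular variance
#' `1 - |sum(v * exp(i w theta))| / sum(v)`; two-peak features are `NA`, and
#' conversely `CircularVariance` is `NA` for bimodal curves.  Rate-valued
#' features additionally get `normalized` variants divided by `uni_max`, the
#' cell's maximum rate in the unidirectional condition.
#'
#' `GlobalMinimumAngle` is reported in the range (-120, 240].  Argmax/argmin
#' ties resolve to the smallest angle, except bimodal peak ties which
#' resolve toward 120 (left) / 240 (right) degrees.
#'
#' @param curve a [tuning_curve()], a `"tunefit"` (sampled at `resolution`),
#'   or a list with `theta` and `values` on a uniform grid starting at 0.
#' @param modality `"unimodal"` or `"bimodal"`; if `NULL`, inferred from the
#'   curve's condition when available (default unimodal).
#' @param uni_max optional maximum unidirectional rate used for normalized
#'   features; when missing these are `NA`.
#' @param resolution sampling step for `"tunefit"` input (default 1 degree).
#' @return named numeric vector of features (`NA` where undefined).
#' @examples
#' v <- c(5, 6, 9, 15, 22, 14, 8, 4, 10, 21, 28, 12)
#' extract_features(list(theta = seq(0, 330, 30), values = v),
#'                  modality = "bimodal")
#' @export
extract_features <- function(curve, modality = NULL, uni_max = NULL,
                             resolution = 1) {
  if (inherits(curve, "tunefit")) {
    if (is.null(modality)) modality <- curve$modality
    curve <- sample_curve(curve, resolution)
  }
  theta <- curve$theta
  values <- if (!is.null(curve$values)) curve$values else curve$y
  if (is.null(modality)) {
    modality <- if (isTRUE(curve$condition %in% c("afix", "ain"))) "bimodal" else "unimodal"
  }
  modality <- match.arg(modality, c("unimodal", "bimodal"))
  n <- length(theta)
  res <- 360 / n
  f <- stats::setNames(rep(NA_real_, length(FEATURE_NAMES)), FEATURE_NAMES)

  gmin <- min(values); gmax <- max(values)
  f["GlobalMinimum"] <- gmin
  f["GlobalMaximum"] <- gmax
  gmin_i <- pick_angle(theta, which(values == gmin))
  gma <- theta[gmin_i]
  f["GlobalMinimumAngle"] <- if (gma > 240) gma - 360 else gma

  if (modality == "unimodal") {
    p <- pick_angle(theta, which(values == gmax))
    f["MaximumRight"] <- gmax
    f["MaximumAngleRight"] <- theta[p]
    ptp <- gmax - gmin
    f["PeakToPeakRight"] <- ptp
    for (X in c(25, 50, 75)) {
      f[sprintf("Bandwidth%dRight", X)] <-
        bandwidth_walk(values - gmin, p, X / 100 * ptp, res)
    }
    sv <- sum(values)
    if (sv > 0) {
      f["CircularVariance"] <- 1 - Mod(sum(values * exp(1i * OMEGA * theta))) / sv
    }
  } else {
    left <- theta < 180
    vmax_l <- max(values[left]); vmax_r <- max(values[!left])
    pl <- pick_angle(theta, which(left & values == vmax_l), prefer = 120)
    pr <- pick_angle(theta, which(!left & values == vmax_r), prefer = 240)
    mal <- theta[pl]; mar <- theta[pr]
    f["MaximumLeft"] <- vmax_l; f["MaximumRight"] <- vmax_r
    f["MaximumAngleLeft"] <- mal; f["MaximumAngleRight"] <- mar
    f["PeakToPeakLeft"] <- vmax_l - gmin
    f["PeakToPeakRight"] <- vmax_r - gmin
    f["DeltaPeakToPeak"] <- f["PeakToPeakRight"] - f["PeakToPeakLeft"]

    inner <- which(theta > mal & theta < mar)
    if (length(inner)) {
      imin <- min(values[inner])
      ii <- pick_angle(theta, inner[values[inner] == imin])
      ima <- theta[ii]
      f["InnerMinimum"] <- imin
      f["InnerMinimumAngle"] <- ima
      f["InnerWidthLeft"] <- ima - mal
      f["InnerWidthRight"] <- mar - ima
      f["DeltaInnerWidth"] <- f["InnerWidthRight"] - f["InnerWidthLeft"]
    }
    outer <- which(theta > mar | theta < mal)
    if (length(outer)) {
      omin <- min(values[outer])
      oi <- pick_angle(theta, outer[values[outer] == omin])
      oma <- theta[oi]
      f["OuterMinimumAngle"] <- oma
      f["OuterWidthLeft"] <- (mal - oma) %% 360
      f["OuterWidthRight"] <- (oma - mar) %% 360
      f["DeltaOuterWidth"] <- f["OuterWidthRight"] - f["OuterWidthLeft"]
    }
    for (X in c(25, 50, 75)) {
      f[sprintf("Bandwidth%dLeft", X)] <-
        bandwidth_walk(values - gmin, pl, X / 100 * f[["PeakToPeakLeft"]], res)
      f[sprintf("Bandwidth%dRight", X)] <-
        bandwidth_walk(values - gmin, pr, X / 100 * f[["PeakToPeakRight"]], res)
    }
    if (length(inner) && length(outer)) {
      # right peak support: arc inner-min -> right peak -> outer-min
      arc_r <- arc_indices(n, ii, oi)
      th_r <- unwrap_arc(theta, arc_r)
      f["SkewnessRight"] <- weighted_skewness(th_r, values[arc_r] - gmin)
      # left peak support: arc outer-min -> left peak -> inner-min
      arc_l <- arc_indices(n, oi, ii)
      th_l <- unwrap_arc(theta, arc_l)
      f["minusSkewnessLeft"] <- -weighted_skewness(th_l, values[arc_l] - gmin)
      f["DeltaSkewness"] <- f["SkewnessRight"] - f["minusSkewnessLeft"]
    }
  }

  if (!is.null(uni_max) && is.finite(uni_max) && uni_max > 0) {
    for (nm in c("GlobalMinimum", "GlobalMaximum", "MaximumLeft",
                 "MaximumRight", "PeakToPeakLeft", "PeakToPeakRight",
                 "InnerMinimum")) {
      f[paste0("normalized", nm)] <- f[nm] / uni_max
    }
  }
  f
}

# Indices along the wrapped grid from index `from` to index `to` inclusive,
# moving in the direction of increasing angle.
arc_indices <- function(n, from, to) {
  if (to >= from) from:to else c(from:n, 1:to)
}

# Angles along an arc, unwrapped so they increase monotonically.
unwrap_arc <- function(theta, idx) {
  th <- theta[idx]
  wrap <- c(FALSE, diff(th) < 0)
  th + cumsum(wrap) * 360
}

#' z-scored agreement between model-based and direct feature values
#'
#' For each feature, `z = (mean(model) - mean(direct)) / sd(direct)` across
#' cells.  `|z| < 1` indicates that the model-based population mean lies
#' within one direct-method standard deviation of the direct-method mean.
#'
#' @param model_values numeric matrix or data frame (cells x features) of
#'   model-derived feature values.
#' @param direct_values same shape, from the direct method.
#' @return named numeric vector of z-scores (`NA` where the direct standard
#'   deviation is zero or a feature is all-`NA`).
#' @export
feature_zscores <- function(model_values, direct_values) {
  model_values <- as.matrix(model_values)
  direct_values <- as.matrix(direct_values)
  stopifnot(identical(colnames(model_values), colnames(direct_values)))
  out <- stats::setNames(rep(NA_real_, ncol(model_values)), colnames(model_values))
  for (j in seq_len(ncol(model_values))) {
    d <- direct_values[, j]; m <- model_values[, j]
    sdd <- stats::sd(d, na.rm = TRUE)
    if (is.na(sdd) || sdd == 0) {
      if (!is.na(sdd)) warning("zero direct-method spread for feature ",
                               colnames(model_values)[j])
      next
    }
    out[j] <- (mean(m, na.rm = TRUE) - mean(d, na.rm = TRUE)) / sdd
  }
  out
}
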