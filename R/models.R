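#' @keywords internal
"_PACKAGE"

# Angular frequency converting degrees to radians: Omega = 2*pi/360.
OMEGA <- 2 * pi / 360

# Number of wrap terms on each side for wrapped families (i = -N..N).
WRAP_N <- 4L

# Floor for the von Mises concentration parameter; k = 0 makes the
# normalising denominator vanish, so it is replaced by 0.001.
VM_K_FLOOR <- 0.001

#' Registry of tuning-curve model families
#'
#' Eight parametric families are available for describing direction tuning
#' curves: five peaked functions -- wrapped Gaussian (`wG`), wrapped Cauchy
#' (`wC`), modified von Mises (`vM`), symmetric Beta (`sbeta`) and wrapped
#' generalized bell-shaped membership function (`wB`) -- and Fourier series
#' of order 2, 3 and 4 (`F2`, `F3`, `F4`).  The peaked families describe a
#' unimodal profile with 4 parameters (5 for `wB`); responses to composite
#' stimuli (two moving patterns) are modelled as the sum of two copies of the
#' same function sharing a common baseline, giving 7 (9 for `wB`) free
#' parameters.  Fourier series have `2n + 1` coefficients and share one
#' functional form across modalities.
#'
#' @param family optional family name; if given, the registry row for that
#'   family is returned as a list.
#' @return A data frame with one row per family (columns `family`,
#'   `fourier`, `order`, `n_params_unimodal`, `n_params_bimodal`), or a
#'   one-row list when `family` is supplied.
#' @examples
#' tune_families()
#' tune_families("wB")
#' @export
tune_families <- function(family = NULL) {
  if (is.null(family)) return(FAMILY_REGISTRY)
  i <- match(family, FAMILY_REGISTRY$family)
  if (is.na(i)) stop("unknown model family: ", family)
  lapply(FAMILY_REGISTRY, `[`, i)
}

FAMILY_REGISTRY <- data.frame(
  family = c("wG", "wC", "vM", "sbeta", "wB", "F2", "F3", "F4"),
  fourier = c(rep(FALSE, 5L), rep(TRUE, 3L)),
  order = c(rep(NA_integer_, 5L), 2L, 3L, 4L),
  n_params_unimodal = c(4L, 4L, 4L, 4L, 5L, 5L, 7L, 9L),
  n_params_bimodal = c(7L, 7L, 7L, 7L, 9L, 5L, 7L, 9L),
  stringsAsFactors = FALSE
)

#' Number of free parameters of a family
#'
#' @param family family name (see [tune_families()]).
#' @param modality `"unimodal"` or `"bimodal"`.
#' @return integer parameter count.
#' @export
n_params <- function(family, modality = "unimodal") {
  fam <- tune_families(family)
  modality <- match.arg(modality, c("unimodal", "bimodal"))
  if (modality == "unimodal") fam$n_params_unimodal else fam$n_params_bimodal
}

# --- unimodal kernels -------------------------------------------------------
# Each returns the model value at angles theta (degrees) for one component.

# Wrap an angle difference into [-180, 180) so finite wrap sums are exactly
# 360-degree periodic.
wrap180 <- function(delta) ((delta + 180) %% 360) - 180

wg_eval <- function(theta, a, b, c, d) {
  delta <- wrap180(theta - c)
  v <- numeric(length(theta))
  for (i in -WRAP_N:WRAP_N) {
    v <- v + exp(-0.5 * ((delta + 360 * i) / b)^2)
  }
  a * v + d
}

wc_eval <- function(theta, a, b, c, d) {
  a * sinh(b) / (cosh(b) - cos(OMEGA * (theta - c))) + d
}

vm_eval <- function(theta, a, k, c, d) {
  k <- max(k, VM_K_FLOOR)
  a * (exp(k * cos(OMEGA * (theta - c))) - exp(-k)) / (exp(k) - exp(-k)) + d
}

sbeta_eval <- function(theta, a, b, c, d) {
  x <- ((OMEGA * (theta - c) + pi) / (2 * pi)) %% 1
  a * (4 * x * (1 - x))^b + d
}

wb_eval <- function(theta, a, b, c, d, s) {
  i <- -WRAP_N:WRAP_N
  alpha <- sum(1 / (1 + abs(360 * i / b)^(2 * s)))
  beta <- sum(1 / (1 + abs((180 + 360 * i) / b)^(2 * s)))
  delta <- wrap180(theta - c)
  v <- numeric(length(theta))
  for (j in i) {
    v <- v + 1 / (1 + abs((delta + 360 * j) / b)^(2 * s))
  }
  a * (v - beta) / (alpha - beta) + d
}

#' Fourier design row / matrix
#'
#' Basis values `(1, cos(w t), sin(w t), ..., cos(n w t), sin(n w t))` with
#' `w = 2 pi / 360`, evaluated at angles in degrees.
#'
#' @param theta angles in degrees (vector).
#' @param order Fourier order, one of 2, 3, 4.
#' @return A `length(theta) x (2 * order + 1)` design matrix.
#' @examples
#' fourier_design(c(0, 90), order = 2)
#' @export
fourier_design <- function(theta, order) {
  if (!order %in% 2:4) stop("Fourier order must be 2, 3 or 4")
  X <- matrix(1, nrow = length(theta), ncol = 2L * order + 1L)
  for (i in seq_len(order)) {
    X[, 2L * i] <- cos(i * OMEGA * theta)
    X[, 2L * i + 1L] <- sin(i * OMEGA * theta)
  }
  X
}

#' Evaluate a tuning model
#'
#' Computes the firing rate predicted by a model family at arbitrary angles.
#' Parameter layout by family (all angles in degrees, rates in 1/s):
#' * `wG`, `wC`: `(a, b, c, d)` -- amplitude, width, peak position, baseline;
#' * `vM`: `(a, k, c, d)` with concentration `k` (floored at 0.001);
#' * `sbeta`: `(a, b, c, d)` with shape exponent `b`;
#' * `wB`: `(a, b, c, d, s)` with width `b` and steepness `s`;
#' * `F2`/`F3`/`F4`: `(a0, a1, b1, ..., an, bn)` Fourier coefficients.
#'
#' Bimodal (two-stimulus) layouts for the peaked families are
#' `(a1, b1, c1, a2, b2, c2, d)` (`wB`: `(a1, b1, c1, a2, b2, c2, d, s1, s2)`),
#' evaluated as the sum of two unimodal components each carrying baseline
#' `d/2`.  Fourier families use the same coefficients in either modality.
#'
#' Wrapped families (`wG`, `wB`) sum wrap terms `i = -4..4`; all evaluations
#' are 360-degree periodic.
#'
#' @param family family name, see [tune_families()].
#' @param params numeric parameter vector in the family's layout.
#' @param theta angles in degrees (any reals).
#' @param modality `"unimodal"` or `"bimodal"`.
#' @return numeric vector of model values at `theta`.
#' @examples
#' eval_tuning("wG", c(a = 10, b = 30, c = 240, d = 5), seq(0, 330, 30))
#' eval_tuning("wG", c(10, 30, 120, 10, 30, 240, 4), 180, modality = "bimodal")
#' @export
eval_tuning <- function(family, params, theta,
                        modality = c("unimodal", "bimodal")) {
  modality <- match.arg(modality)
  fam <- tune_families(family)
  params <- as.numeric(params)
  want <- if (modality == "unimodal") fam$n_params_unimodal else fam$n_params_bimodal
  if (length(params) != want) {
    stop(sprintf("family %s (%s) expects %d parameters, got %d",
                 family, modality, want, length(params)))
  }
  if (fam$fourier) {
    return(drop(fourier_design(theta, fam$order) %*% params))
  }
  if (modality == "unimodal") {
    return(eval_unimodal(family, params, theta))
  }
  # sum of two components, shared baseline d split d/2 per component
  if (family == "wB") {
    p1 <- c(params[1:3], params[7] / 2, params[8])
    p2 <- c(params[4:6], params[7] / 2, params[9])
  } else {
    p1 <- c(params[1:3], params[7] / 2)
    p2 <- c(params[4:6], params[7] / 2)
  }
  eval_unimodal(family, p1, theta) + eval_unimodal(family, p2, theta)
}

eval_unimodal <- function(family, p, theta) {
  switch(family,
    wG = wg_eval(theta, p[1], p[2], p[3], p[4]),
    wC = wc_eval(theta, p[1], p[2], p[3], p[4]),
    vM = vm_eval(theta, p[1], p[2], p[3], p[4]),
    sbeta = sbeta_eval(theta, p[1], p[2], p[3], p[4]),
    wB = wb_eval(theta, p[1], p[2], p[3], p[4], p[5]),
    stop("unknown peaked family: ", family)
  )
}
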