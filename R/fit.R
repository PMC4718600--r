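# Floor applied to per-direction standard deviations before weighting;
# identical trials would otherwise give infinite weight.
SIGMA_FLOOR <- 1e-6

#' Weighted chi-square statistic
#'
#' `sum(((y - f) / sigma)^2)` over the sampled directions.
#'
#' @param y observed trial-mean rates.
#' @param f model values at the same directions.
#' @param sigma per-direction trial standard deviations (floored at 1e-6).
#' @return non-negative scalar.
#' @export
chi_squared <- function(y, f, sigma) {
  if (length(y) != length(f) || length(y) != length(sigma)) {
    stop("y, f and sigma must have equal length")
  }
  s <- pmax(sigma, SIGMA_FLOOR)
  sum(((y - f) / s)^2)
}

# Width starts per family for half-widths-at-half-maximum of 15, 45, 90 deg.
# sbeta and vM values follow the published correspondence; wG converts via
# b = HWHM / sqrt(2 log 2); wC solves cos(Omega*HWHM) = 2 - cosh(b); for wB
# the width parameter b equals the HWHM directly.
width_starts <- function(family) {
  switch(family,
    wG = c(15, 45, 90) / sqrt(2 * log(2)),
    wC = vapply(c(15, 45, 90), function(h) acosh(2 - cos(OMEGA * h)), 0),
    vM = c(20.34, 2.3, 0.001),
    sbeta = c(100, 10.74, 2.41),
    wB = c(15, 45, 90),
    stop("no width starts for family ", family)
  )
}

width_bounds <- function(family) {
  switch(family,
    wG = c(3, 200),
    wC = c(0.01, 5),
    vM = c(VM_K_FLOOR, 500),
    sbeta = c(0.5, 400),
    wB = c(3, 200),
    stop("no width bounds for family ", family)
  )
}

# Build the multistart table and box bounds for a peaked-family fit.
# u = min(y) + 1.2 * (max(y) - min(y)) bounds amplitudes and baseline.
fit_setup <- function(family, modality, theta, y) {
  u <- min(y) + 1.2 * (max(y) - min(y))
  u <- max(u, SIGMA_FLOOR)
  wb <- width_bounds(family)
  ws <- width_starts(family)
  if (modality == "unimodal") {
    c0 <- theta[which.max(y)]
    a0 <- max(max(y) - min(y), SIGMA_FLOOR)
    d0 <- min(y)
    starts <- lapply(ws, function(w) c(a0, w, c0, d0))
    lower <- c(0, wb[1], c0 - 90, 0)
    upper <- c(u, wb[2], c0 + 90, u)
    if (family == "wB") {
      starts <- lapply(starts, function(p) c(p, 2))
      lower <- c(lower, 0.5); upper <- c(upper, 10)
    }
  } else {
    left <- theta >= 0 & theta < 180
    c1 <- if (any(left)) theta[left][which.max(y[left])] else 120
    c2 <- if (any(!left)) theta[!left][which.max(y[!left])] else 240
    a1 <- max(if (any(left)) max(y[left]) - min(y) else diff(range(y)), SIGMA_FLOOR)
    a2 <- max(if (any(!left)) max(y[!left]) - min(y) else diff(range(y)), SIGMA_FLOOR)
    d0 <- min(y)
    starts <- lapply(ws, function(w) c(a1, w, c1, a2, w, c2, d0))
    lower <- c(0, wb[1], c1 - 90, 0, wb[1], c2 - 90, 0)
    upper <- c(u, wb[2], c1 + 90, u, wb[2], c2 + 90, u)
    if (family == "wB") {
      starts <- lapply(starts, function(p) c(p, 2, 2))
      lower <- c(lower, 0.5, 0.5); upper <- c(upper, 10, 10)
    }
  }
  list(starts = starts, lower = lower, upper = upper)
}

param_names <- function(family, modality) {
  fam <- tune_families(family)
  if (fam$fourier) {
    n <- fam$order
    return(c("a0", as.vector(rbind(paste0("a", 1:n), paste0("b", 1:n)))))
  }
  w <- if (family == "vM") "k" else "b"
  if (modality == "unimodal") {
    if (family == "wB") c("a", w, "c", "d", "s") else c("a", w, "c", "d")
  } else {
    base <- c("a1", paste0(w, 1), "c1", "a2", paste0(w, 2), "c2", "d")
    if (family == "wB") c(base, "s1", "s2") else base
  }
}

#' Fit a tuning-curve model by weighted least squares
#'
#' Minimises the chi-square statistic [chi_squared()] of a model family over
#' its parameters, subject to box constraints.  Fourier families (`F2`, `F3`,
#' `F4`) are linear in their coefficients and are solved exactly by singular
#' value decomposition (see [fit_fourier()]); the peaked families are fitted
#' by bounded Levenberg-Marquardt from a small multistart grid over plausible
#' peak widths (half-widths at half-maximum of 15, 45 and 90 degrees),
#' keeping the best start and polishing it with a short bounded quasi-Newton
#' pass.  Amplitudes and baseline are bounded in
#' `[0, u]` with `u = min(y) + 1.2 * (max(y) - min(y))`; peak positions start
#' at the grid argmax (unimodal) or at the argmax of each half of the grid
#' (bimodal, defaulting to 120 and 240 degrees).
#'
#' @param curve a [tuning_curve()] (or any list with `theta`, `y`, `sigma`).
#' @param family model family name, see [tune_families()].
#' @param modality `"unimodal"` or `"bimodal"`; if `NULL`, inferred from the
#'   curve's condition (`afix`/`ain` are bimodal) and otherwise unimodal.
#' @param start optional explicit start vector replacing the multistart grid.
#' @param control control list for the quasi-Newton polish
#'   ([stats::optim()], method `"L-BFGS-B"`).
#' @return An object of class `"tunefit"`: a list with the fitted `params`
#'   (named), `fitted` values on the curve's grid, the weighted `chi2`, the
#'   unweighted `sse`, sample count `K`, parameter count `M`, a `converged`
#'   flag, and `Q` (`NA` until [goodness_of_fit()] is called).
#' @seealso [goodness_of_fit()], [select_model()], [sample_curve()]
#' @examples
#' th <- seq(0, 330, 30)
#' y <- eval_tuning("wG", c(20, 40, 240, 5), th)
#' fit <- tunefit(tuning_curve(y, sigma = rep(1, 12)), "wG")
#' coef(fit)
#' @export
tunefit <- function(curve, family, modality = NULL, start = NULL,
                    control = list(maxit = 500)) {
  fam <- tune_families(family)
  if (is.null(modality)) {
    modality <- if (isTRUE(curve$condition %in% c("afix", "ain"))) "bimodal" else "unimodal"
  }
  modality <- match.arg(modality, c("unimodal", "bimodal"))
  theta <- curve$theta; y <- curve$y
  sigma <- pmax(curve$sigma, SIGMA_FLOOR)
  if (fam$fourier) {
    res <- fit_fourier(curve, fam$order)
    res$modality <- modality
    return(res)
  }
  # direct evaluator avoiding per-call registry/arity overhead in the
  # optimiser inner loop
  evalfun <- if (modality == "unimodal") {
    function(p) eval_unimodal(family, p, theta)
  } else if (family == "wB") {
    function(p) eval_unimodal(family, c(p[1:3], p[7] / 2, p[8]), theta) +
      eval_unimodal(family, c(p[4:6], p[7] / 2, p[9]), theta)
  } else {
    function(p) eval_unimodal(family, c(p[1:3], p[7] / 2), theta) +
      eval_unimodal(family, c(p[4:6], p[7] / 2), theta)
  }
  setup <- fit_setup(family, modality, theta, y)
  starts <- if (is.null(start)) setup$starts else list(as.numeric(start))
  best <- wls_minimize(evalfun, y, sigma, starts, setup$lower, setup$upper,
                       polish_control = control)
  params <- stats::setNames(best$par, param_names(family, modality))
  f <- eval_tuning(family, params, theta, modality)
  new_tunefit(family, modality, params, curve, f, converged = best$converged)
}

# Bounded weighted least squares: Levenberg-Marquardt from each start, then
# a short quasi-Newton polish of the best candidate (LM's quadratic model can
# stall on the plateau-prone width/steepness parameters).
wls_minimize <- function(evalfun, y, sigma, starts, lower, upper,
                         lm_maxiter = 150, polish_control = list(maxit = 200)) {
  resfun <- function(p) (y - evalfun(p)) / sigma
  obj <- function(p) sum(resfun(p)^2)
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    lm <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        p0, lower = lower, upper = upper, fn = resfun,
        control = minpack.lm::nls.lm.control(maxiter = lm_maxiter))),
      error = function(e) NULL)
    cand <- if (is.null(lm)) list(par = p0, value = obj(p0), info = -1L)
            else list(par = lm$par, value = sum(lm$fvec^2), info = lm$info)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  o <- tryCatch(
    stats::optim(pmin(pmax(best$par, lower), upper), obj, method = "L-BFGS-B",
                 lower = lower, upper = upper, control = polish_control),
    error = function(e) NULL)
  if (!is.null(o) && o$value <= best$value) {
    best <- list(par = o$par, value = o$value, info = 1L)
  }
  list(par = best$par, value = best$value,
       converged = best$info %in% c(1L, 2L, 3L, 4L) || !is.null(o))
}

new_tunefit <- function(family, modality, params, curve, fitted, converged,
                        dropped_modes = 0L) {
  s <- pmax(curve$sigma, SIGMA_FLOOR)
  structure(list(
    family = family, modality = modality, params = params,
    curve = curve, fitted = fitted,
    chi2 = sum(((curve$y - fitted) / s)^2),
    sse = sum((curve$y - fitted)^2),
    K = length(curve$y), M = length(params),
    converged = converged, dropped_modes = dropped_modes, Q = NA_real_
  ), class = "tunefit")
}

#' Exact weighted least-squares Fourier fit
#'
#' Solves the weighted linear least-squares problem for a Fourier series of
#' order `n` by singular value decomposition: with design `A[i, m] =
#' X_m(theta_i) / sigma_i` and target `b_i = y_i / sigma_i`, the coefficient
#' vector is `sum_m (u_m . b / w_m) v_m` over the singular triplets of `A`.
#' Singular values below `max(w) * 1e-12` are dropped (and counted in
#' `dropped_modes`), the standard regularisation for rank-deficient designs.
#'
#' @param curve a [tuning_curve()].
#' @param order Fourier order (2, 3 or 4).
#' @return a `"tunefit"` object (see [tunefit()]).
#' @export
fit_fourier <- function(curve, order) {
  s <- pmax(curve$sigma, SIGMA_FLOOR)
  X <- fourier_design(curve$theta, order)
  A <- X / s
  b <- curve$y / s
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-12
  coefs <- drop(sv$v[, keep, drop = FALSE] %*%
                  (crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep]))
  params <- stats::setNames(coefs, param_names(paste0("F", order), "unimodal"))
  f <- drop(X %*% coefs)
  new_tunefit(paste0("F", order), "unimodal", params, curve, f,
              converged = TRUE, dropped_modes = sum(!keep))
}
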