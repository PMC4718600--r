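#' Goodness-of-fit probability Q
#'
#' The probability, under the null hypothesis that the model is correct and
#' the per-direction measurement errors are independent zero-mean Gaussians
#' with the observed standard deviations, of a weighted sum of squared errors
#' at least as large as the observed chi-square.  Fits with `Q <= 0.1` are
#' conventionally termed "bad".
#'
#' For the Fourier families -- the only ones linear in their parameters --
#' `Q` is the regularized upper incomplete gamma function at shape
#' `(K - M) / 2` and argument `chi2 / 2`, i.e. the upper tail of a chi-square
#' distribution with `K - M` degrees of freedom.  For the non-linear peaked
#' families the chi-square of the fit does not follow that distribution, so
#' `Q` is estimated by Monte-Carlo resampling: `mc_replicas` synthetic curves
#' are drawn from the fitted model plus Gaussian noise with the observed
#' sigma, each is refitted by the same family (starting from the observed
#' fit), and `Q` is the fraction of replicas whose chi-square is at least the
#' observed one.
#'
#' @param fit a `"tunefit"` object.
#' @param mc_replicas number of Monte-Carlo replicas (default 10000).
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @param method `"auto"` (analytic for Fourier, Monte-Carlo otherwise),
#'   `"analytic"` (Fourier only) or `"mc"`.
#' @return the fit with its `Q` field set; retrieve with `fit$Q`.
#' @examples
#' th <- seq(0, 330, 30)
#' y <- eval_tuning("wG", c(20, 40, 240, 5), th) + c(1, -1)
#' fit <- tunefit(tuning_curve(y, sigma = rep(1.5, 12)), "F2")
#' goodness_of_fit(fit)$Q
#' @export
goodness_of_fit <- function(fit, mc_replicas = 10000, seed = NULL,
                            method = c("auto", "analytic", "mc")) {
  method <- match.arg(method)
  if (fit$K <= fit$M) stop("Q undefined: K <= M (no residual degrees of freedom)")
  fam <- tune_families(fit$family)
  if (method == "auto") method <- if (fam$fourier) "analytic" else "mc"
  if (method == "analytic") {
    if (!fam$fourier) stop("analytic Q is only valid for the linear (Fourier) families")
    fit$Q <- stats::pchisq(fit$chi2, df = fit$K - fit$M, lower.tail = FALSE)
    return(fit)
  }
  if (mc_replicas < 100) stop("mc_replicas must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  s <- pmax(fit$curve$sigma, SIGMA_FLOOR)
  K <- fit$K
  if (fam$fourier) {
    # Linear refits share one solve operator; replicas reduce to matrix algebra.
    X <- fourier_design(fit$curve$theta, fam$order)
    A <- X / s
    sv <- svd(A)
    keep <- sv$d > max(sv$d) * 1e-12
    P <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    B <- (fit$fitted + matrix(stats::rnorm(K * mc_replicas), K) * s) / s
    R <- B - A %*% (P %*% B)
    chi2_rep <- colSums(R^2)
  } else {
    chi2_rep <- numeric(mc_replicas)
    theta <- fit$curve$theta
    family <- fit$family; modality <- fit$modality
    setup <- fit_setup(family, modality, theta, fit$curve$y)
    start <- pmin(pmax(unname(fit$params), setup$lower), setup$upper)
    evalfun <- if (modality == "unimodal") {
      function(p) eval_unimodal(family, p, theta)
    } else if (family == "wB") {
      function(p) eval_unimodal(family, c(p[1:3], p[7] / 2, p[8]), theta) +
        eval_unimodal(family, c(p[4:6], p[7] / 2, p[9]), theta)
    } else {
      function(p) eval_unimodal(family, c(p[1:3], p[7] / 2), theta) +
        eval_unimodal(family, c(p[4:6], p[7] / 2), theta)
    }
    for (r in seq_len(mc_replicas)) {
      ystar <- fit$fitted + stats::rnorm(K, 0, s)
      ref <- wls_minimize(evalfun, ystar, s, list(start), setup$lower,
                          setup$upper, lm_maxiter = 100,
                          polish_control = list(maxit = 60, factr = 1e8))
      chi2_rep[r] <- ref$value
    }
  }
  fit$Q <- mean(chi2_rep >= fit$chi2)
  fit
}
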