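#' @export
print.tunefit <- function(x, digits = 4, ...) {
  cat(sprintf("Tuning-curve fit: %s (%s), %d parameters\n",
              x$family, x$modality, x$M))
  print(round(x$params, digits))
  cat(sprintf("chi-square %.4g on K = %d directions; SSE %.4g%s\n",
              x$chi2, x$K, x$sse,
              if (!is.na(x$Q)) sprintf("; Q = %.3f%s", x$Q,
                if (x$Q <= 0.1) " (bad fit)" else "") else ""))
  if (!x$converged) cat("warning: optimiser did not converge\n")
  invisible(x)
}

#' @export
summary.tunefit <- function(object, ...) {
  aic <- AIC(object)
  out <- list(fit = object, AIC = aic,
              AICc = if (object$K - object$M - 1 > 0) aicc(object) else NA_real_,
              residuals = object$curve$y - object$fitted)
  class(out) <- "summary.tunefit"
  out
}

#' @export
print.summary.tunefit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("AIC %.3f  AICc %s\n", x$AIC,
              if (is.na(x$AICc)) "undefined (K - M - 1 <= 0)" else sprintf("%.3f", x$AICc)))
  cat("residuals (data - fit):\n")
  print(round(x$residuals, 3))
  invisible(x)
}

#' @export
coef.tunefit <- function(object, ...) object$params

#' @export
fitted.tunefit <- function(object, ...) object$fitted

#' Residuals of a tuning fit
#'
#' @param object a `"tunefit"`.
#' @param type `"response"` (data minus fit, 1/s) or `"pearson"` (divided by
#'   the per-direction trial standard deviation, floored at 1e-6).
#' @param ... unused.
#' @return numeric vector over the curve's directions.
#' @export
residuals.tunefit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$curve$y - object$fitted
  if (type == "pearson") r <- r / pmax(object$curve$sigma, SIGMA_FLOOR)
  r
}

#' Predict firing rates at new directions
#'
#' @param object a `"tunefit"`.
#' @param newdata angles in degrees (default: the fitted grid).
#' @param ... unused.
#' @return predicted rates.
#' @export
predict.tunefit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  eval_tuning(object$family, object$params, as.numeric(newdata), object$modality)
}

#' Plot a tuning fit over the data
#'
#' Data points with +/- 1 SD error bars and the fitted profile sampled at
#' 1-degree resolution.
#'
#' @param x a `"tunefit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tunefit <- function(x, ...) {
  cur <- x$curve
  fine <- seq(0, 359, by = 1)
  yl <- range(0, cur$y + cur$sigma, cur$y - cur$sigma, x$fitted)
  graphics::plot(cur$theta, cur$y, pch = 19, xlab = "direction (deg)",
                 ylab = "firing rate (1/s)", ylim = yl,
                 main = sprintf("%s fit (%s)", x$family, x$modality), ...)
  graphics::arrows(cur$theta, cur$y - cur$sigma, cur$theta, cur$y + cur$sigma,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  graphics::lines(fine, predict(x, fine), col = "firebrick", lwd = 2)
  invisible(x)
}
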