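# Fixed family order used to break best-model ties deterministically
# (after preferring fewer parameters).
TIE_ORDER <- c("F2", "F3", "F4", "sbeta", "vM", "wC", "wG", "wB")

#' Akaike information criterion of a tuning fit
#'
#' `AIC = K * log(SSE / K) + 2 * M`, where `SSE` is the unweighted sum of
#' squared residuals over the `K` sampled directions and `M` the number of
#' free parameters.  A perfect fit (`SSE = 0`) would give `-Inf`; a large
#' negative sentinel (`-1e10 + 2M`) is returned instead, with a warning.
#'
#' @param object a `"tunefit"` object.
#' @param ... unused.
#' @param k unused (the penalty is fixed at 2 per parameter).
#' @return scalar AIC value.
#' @export
AIC.tunefit <- function(object, ..., k = 2) {
  if (object$sse <= 0) {
    warning("SSE = 0: AIC is -Inf; returning large negative sentinel")
    return(-1e10 + 2 * object$M)
  }
  object$K * log(object$sse / object$K) + 2 * object$M
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2 * M * (M + 1) / (K - M - 1)`.  With `K = 12` directions
#' the correction is 10 for 5-parameter models, 28 for 7 and 90 for 9;
#' models with `K - M - 1 <= 0` are undefined and raise an error.
#'
#' @param object a `"tunefit"` object.
#' @return scalar AICc value.
#' @export
aicc <- function(object) {
  if (object$K - object$M - 1 <= 0) {
    stop("AICc undefined: K - M - 1 <= 0")
  }
  AIC(object) + 2 * object$M * (object$M + 1) / (object$K - object$M - 1)
}

#' Per-cell model selection by (corrected) AIC
#'
#' Computes `delta = IC(m) - min(IC)` across the supplied fits of one curve,
#' the best family (`delta == 0`) and the contender set (`delta <=
#' threshold`, default 1, within which models are considered equally good).
#' Non-converged fits are excluded with a warning.  Ties for best are broken
#' by fewest parameters, then by the fixed family order
#' `F2, F3, F4, sbeta, vM, wC, wG, wB`.
#'
#' @param fits named list of `"tunefit"` objects for one (cell, condition);
#'   names default to each fit's family.
#' @param criterion `"AIC"` or `"AICc"`.
#' @param threshold contender threshold on the IC difference (default 1).
#' @return list with `table` (data frame: family, M, IC, delta, contender),
#'   `best` (family name) and `contenders` (character vector).
#' @examples
#' th <- seq(0, 330, 30)
#' y <- eval_tuning("wG", c(20, 40, 240, 5), th) + sin(th / 20)
#' cur <- tuning_curve(y, sigma = rep(1, 12))
#' sel <- select_model(list(tunefit(cur, "F2"), tunefit(cur, "F3")))
#' sel$best
#' @export
select_model <- function(fits, criterion = c("AIC", "AICc"), threshold = 1) {
  criterion <- match.arg(criterion)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$family, "")
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), NA)
  if (any(!ok)) {
    warning("excluding non-converged fits: ", paste(names(fits)[!ok], collapse = ", "))
    fits <- fits[ok]
  }
  if (length(fits) < 1) stop("no converged fits to select among")
  ic <- vapply(fits, if (criterion == "AIC") AIC else aicc, 0)
  delta <- ic - min(ic)
  M <- vapply(fits, function(f) as.numeric(f$M), 0)
  tab <- data.frame(family = names(fits), M = M, IC = ic, delta = delta,
                    contender = delta <= threshold, row.names = NULL,
                    stringsAsFactors = FALSE)
  tied <- tab$family[tab$delta == 0]
  if (length(tied) > 1) {
    tm <- tab$M[match(tied, tab$family)]
    tied <- tied[tm == min(tm)]
    tied <- tied[order(match(tied, TIE_ORDER))]
  }
  list(table = tab, best = tied[1], contenders = tab$family[tab$contender],
       criterion = criterion)
}

#' Population fractions of best and contender models
#'
#' For a list of per-cell selections (from [select_model()]), the fraction of
#' cells for which each family is the best model and the fraction for which
#' it is at least a contender.
#'
#' @param selections list of [select_model()] results.
#' @return data frame with columns `family`, `fraction_best`,
#'   `fraction_contender`.
#' @export
model_fractions <- function(selections) {
  if (length(selections) == 0) stop("no selections supplied")
  fams <- unique(unlist(lapply(selections, function(s) s$table$family)))
  fams <- fams[order(match(fams, TIE_ORDER))]
  n <- length(selections)
  best <- vapply(fams, function(f)
    mean(vapply(selections, function(s) identical(s$best, f), NA)), 0)
  cont <- vapply(fams, function(f)
    mean(vapply(selections, function(s) f %in% s$contenders, NA)), 0)
  data.frame(family = fams, fraction_best = unname(best),
             fraction_contender = unname(cont), row.names = NULL,
             stringsAsFactors = FALSE)
}
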