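#' Noise-matched surrogate curves from a fitted model
#'
#' Draws surrogate 12-point tuning curves from a fitted profile by adding
#' independent zero-mean Gaussian noise whose per-direction standard
#' deviation equals the one estimated from the observed trial variability.
#' This is the `simulate()` method of a `"tunefit"`, mirroring the surrogate
#' procedure used to probe model identifiability: fit `wG` or `F3` to a
#' measured curve, then resample it at the empirical noise level.
#'
#' @param object a `"tunefit"` object.
#' @param nsim number of surrogate curves (default 1).
#' @param seed optional integer seed.
#' @param sigma per-direction noise standard deviations; defaults to the
#'   fitted curve's observed trial standard deviations.
#' @param clip if `TRUE` (default) negative surrogate rates are clipped at 0
#'   to keep them physical; set `FALSE` for strict distributional checks.
#' @param ... unused.
#' @return list of [tuning_curve()] objects of length `nsim`, each carrying
#'   the same `sigma` and trial counts as the source curve.
#' @export
simulate.tunefit <- function(object, nsim = 1, seed = NULL,
                             sigma = NULL, clip = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- object$curve$sigma
  lapply(seq_len(nsim), function(r) {
    y <- object$fitted + stats::rnorm(object$K, 0, sigma)
    if (clip) y <- pmax(y, 0)
    tuning_curve(y, sigma = sigma, n_trials = object$curve$n_trials,
                 theta = object$curve$theta, cell_id = object$curve$cell_id,
                 paradigm = object$curve$paradigm,
                 condition = object$curve$condition)
  })
}

#' Surrogate curves for a population of fits
#'
#' Convenience wrapper applying [simulate.tunefit()] once per fitted cell.
#' By design surrogates are generated from `wG` or `F3` fits (the two
#' reference ensembles); pass `allow_any = TRUE` to override.
#'
#' @param fits list of `"tunefit"` objects.
#' @param seed integer seed (one stream across all cells).
#' @param allow_any allow families other than `wG`/`F3`.
#' @param clip clip negative rates at zero (default `TRUE`).
#' @return list of [tuning_curve()] objects, one surrogate per input fit.
#' @export
surrogate_from_fits <- function(fits, seed = NULL, allow_any = FALSE,
                                clip = TRUE) {
  fam <- unique(vapply(fits, function(f) f$family, ""))
  if (!allow_any && !all(fam %in% c("wG", "F3"))) {
    stop("surrogate ensembles are built from wG or F3 fits; ",
         "use allow_any = TRUE to override")
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(fits, function(f) simulate.tunefit(f, nsim = 1, clip = clip)[[1]])
}

#' Generate a synthetic direction-tuning experiment
#'
#' Builds a trial-level [tuning_trials()] dataset emulating the structure of
#' a direction tuning experiment: 12 directions 30 degrees apart, a
#' unidirectional condition (`uni`, one moving stimulus, unimodal response
#' with a random preferred direction), and two composite-stimulus conditions
#' (`afix`, `ain`) whose responses are bimodal with components 120 degrees
#' apart.  `ain` differs from `afix` by a multiplicative attentional gain on
#' the component at the preferred direction (the "right" peak after
#' alignment).  Trial noise is heteroscedastic Gaussian: each trial rate is
#' drawn with standard deviation `cv * mean` (`noise = "gaussian_cv"`) or
#' `scale * sqrt(mean)` (`"poisson_like"`), and negative draws are clipped
#' at zero.
#'
#' Defaults emulate the spatially separate paradigm's response regime:
#' peak amplitude 25 1/s over a 5 1/s baseline, wrapped-Gaussian width 40
#' degrees, 10 trials per stimulus, and a trial coefficient of variation of
#' 0.38 (population median of that paradigm; use `cv = 0.72` to mimic the
#' transparent paradigm).
#'
#' @param n_cells number of cells.
#' @param conditions which conditions to generate.
#' @param family generating family for the tuning profiles (default `"wG"`).
#' @param a peak amplitude (1/s); `b` width parameter; `d` baseline (1/s).
#' @param n_trials trials per (condition, direction); scalar or range to
#'   sample per cell uniformly (e.g. `c(2, 15)`).
#' @param cv trial coefficient of variation for `"gaussian_cv"` noise.
#' @param noise noise model.
#' @param scale scale for `"poisson_like"` noise.
#' @param gain attentional gain applied to the right-peak amplitude in `ain`
#'   (default 1.2).
#' @param paradigm paradigm label stamped on the records.
#' @param sigma_floor minimum per-trial noise SD (keeps baseline trials from
#'   collapsing to identical values).
#' @param seed integer seed; fixed seed gives a bit-identical dataset.
#' @return a [tuning_trials()] data frame, with the generating parameters
#'   attached as attribute `ground_truth` (per cell: preferred direction and
#'   model parameters per condition).
#' @examples
#' tr <- generate_tuning_trials(n_cells = 2, seed = 1)
#' head(tr)
#' @export
generate_tuning_trials <- function(n_cells = 20,
                                   conditions = c("uni", "afix", "ain"),
                                   family = "wG", a = 25, b = 40, d = 5,
                                   n_trials = 10, cv = 0.38,
                                   noise = c("gaussian_cv", "poisson_like"),
                                   scale = 1, gain = 1.2,
                                   paradigm = "spatially_separate",
                                   sigma_floor = 0.5, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  grid <- DIRECTION_GRID
  rows <- list()
  truth <- list()
  for (ci in seq_len(n_cells)) {
    cell <- sprintf("cell%03d", ci)
    pref <- sample(grid, 1)  # preferred direction before alignment
    nt <- if (length(n_trials) > 1) sample(n_trials[1]:n_trials[2], 1) else n_trials
    params <- list()
    for (cond in conditions) {
      if (cond %in% c("uni", "uni1", "uni2")) {
        p <- c(a, b, pref, d)
        mu <- eval_tuning(family, p, grid, "unimodal")
      } else {
        a_right <- if (cond == "ain") gain * a else a
        p <- c(a, b, (pref - 120) %% 360, a_right, b, pref, d)
        mu <- eval_tuning(family, p, grid, "bimodal")
      }
      params[[cond]] <- p
      s <- switch(noise, gaussian_cv = cv * mu, poisson_like = scale * sqrt(mu))
      s <- pmax(s, sigma_floor)
      for (k in seq_along(grid)) {
        r <- pmax(stats::rnorm(nt, mu[k], s[k]), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cell, paradigm = paradigm, condition = cond,
          direction = grid[k], trial_index = seq_len(nt) - 1L, rate = r,
          stringsAsFactors = FALSE)
      }
    }
    truth[[cell]] <- list(pref = pref, n_trials = nt, params = params)
  }
  out <- tuning_trials(do.call(rbind, rows))
  attr(out, "ground_truth") <- truth
  out
}
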