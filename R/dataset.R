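DIRECTION_GRID <- seq(0, 330, by = 30)

#' Validate a trial-level tuning dataset
#'
#' The canonical input is a tidy data frame with one trial per row and
#' columns `cell_id`, `paradigm` (`"spatially_separate"` or `"transparent"`),
#' `condition` (`"uni"`, `"uni1"`, `"uni2"`, `"afix"`, `"ain"`), `direction`
#' (degrees, a multiple of 30 in \[0, 330\]), `trial_index` and `rate`
#' (firing rate in 1/s, non-negative).  Validation enforces the inclusion
#' rule that every recorded (cell, condition, direction) has at least two
#' trials.
#'
#' @param x data frame of trials.
#' @param check_trials if `TRUE` (default) enforce the >= 2 trials rule.
#' @return `x`, classed `"tuning_trials"`, with an `alignment_offsets`
#'   attribute (empty until [align_trials()] is applied).
#' @export
tuning_trials <- function(x, check_trials = TRUE) {
  need <- c("cell_id", "paradigm", "condition", "direction", "trial_index", "rate")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(x$direction %in% DIRECTION_GRID)) {
    bad <- which(!x$direction %in% DIRECTION_GRID)
    stop(sprintf("off-grid direction %s in row %d (directions must be multiples of 30 in [0, 330])",
                 x$direction[bad[1]], bad[1]))
  }
  if (!is.numeric(x$rate) || anyNA(x$rate) || any(x$rate < 0)) {
    stop("rate must be numeric, non-missing and non-negative")
  }
  bad_cond <- setdiff(unique(x$condition), c("uni", "uni1", "uni2", "afix", "ain"))
  if (length(bad_cond)) stop("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  if (check_trials) {
    n <- stats::aggregate(rate ~ cell_id + paradigm + condition + direction,
                          data = x, FUN = length)
    short <- n[n$rate < 2, , drop = FALSE]
    if (nrow(short)) {
      o <- short[1, ]
      stop(sprintf("cell %s, condition %s, direction %s has %d trial(s); at least two are required",
                   o$cell_id, o$condition, format(o$direction), o$rate))
    }
  }
  x <- as.data.frame(x)
  if (is.null(attr(x, "alignment_offsets"))) {
    attr(x, "alignment_offsets") <- stats::setNames(numeric(0), character(0))
  }
  class(x) <- unique(c("tuning_trials", class(x)))
  x
}

#' Construct a single tuning curve
#'
#' @param y per-direction trial-mean firing rate (length 12).
#' @param sigma per-direction trial standard deviation (length 12).
#' @param n_trials per-direction trial counts (length 12).
#' @param theta direction grid, default `seq(0, 330, 30)`.
#' @param cell_id,paradigm,condition optional identifiers.
#' @return object of class `"tuning_curve"`.
#' @export
tuning_curve <- function(y, sigma = rep(1, length(y)),
                         n_trials = rep(2L, length(y)),
                         theta = DIRECTION_GRID,
                         cell_id = NA_character_, paradigm = NA_character_,
                         condition = NA_character_) {
  stopifnot(length(y) == length(theta), length(sigma) == length(y),
            length(n_trials) == length(y), all(sigma >= 0))
  structure(list(cell_id = cell_id, paradigm = paradigm, condition = condition,
                 theta = as.numeric(theta), y = as.numeric(y),
                 sigma = as.numeric(sigma), n_trials = as.integer(n_trials)),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("Tuning curve: cell %s, %s / %s\n", x$cell_id, x$paradigm, x$condition))
  m <- rbind(theta = x$theta, mean = round(x$y, 2), sd = round(x$sigma, 2),
             n = x$n_trials)
  print(m)
  invisible(x)
}

#' Build trial-averaged tuning curves
#'
#' Collapses a trial table to one [tuning_curve()] per (cell, paradigm,
#' condition): per-direction sample mean, sample standard deviation
#' (denominator `n - 1`) and trial count on the 12-direction grid.
#'
#' @param trials a [tuning_trials()] table.
#' @return named list of `"tuning_curve"` objects; names are
#'   `cell_id.paradigm.condition`.
#' @export
build_curves <- function(trials) {
  trials <- tuning_trials(trials)
  key <- interaction(trials$cell_id, trials$paradigm, trials$condition, drop = TRUE)
  out <- lapply(split(trials, key), function(g) {
    got <- sort(unique(g$direction))
    m <- s <- n <- rep(NA_real_, length(got))
    for (j in seq_along(got)) {
      r <- g$rate[g$direction == got[j]]
      m[j] <- mean(r); s[j] <- stats::sd(r); n[j] <- length(r)
    }
    tuning_curve(m, s, n, theta = got, cell_id = as.character(g$cell_id[1]),
                 paradigm = as.character(g$paradigm[1]),
                 condition = as.character(g$condition[1]))
  })
  out[order(names(out))]
}

#' Pick the unidirectional condition to analyse
#'
#' In the spatially separate paradigm two single-stimulus conditions may be
#' recorded; by convention `uni2` is analysed when both `uni1` and `uni2`
#' exist.  In the transparent paradigm the single `uni` condition is used.
#' Some cells lack any unidirectional recording; those return `NA`.
#'
#' @param conditions character vector of condition labels present for a cell.
#' @return the chosen condition label, or `NA_character_` if none.
#' @export
select_uni <- function(conditions) {
  uni <- intersect(c("uni2", "uni", "uni1"), conditions)
  if (length(uni) == 0) return(NA_character_)
  uni[1]
}

#' Align tuning curves so the preferred direction sits at 240 degrees
#'
#' Applies, per cell, a single circular relabelling of directions (a multiple
#' of 30 degrees) to all conditions of that cell, such that the direction of
#' the maximum trial-mean rate of the unidirectional condition becomes 240.
#' When no unidirectional condition was recorded, the right peak of the
#' `afix` condition (the maximum over directions in \[180, 360)) is placed at
#' 240 instead.  Argmax ties are broken toward the smallest original angle.
#'
#' @param trials a [tuning_trials()] table.
#' @return the trials table with `direction` relabelled; the per-cell offsets
#'   (degrees added to each original direction, mod 360) are stored in the
#'   `alignment_offsets` attribute.
#' @export
align_trials <- function(trials) {
  trials <- tuning_trials(trials)
  offsets <- stats::setNames(numeric(0), character(0))
  for (cell in unique(trials$cell_id)) {
    sel <- trials$cell_id == cell
    conds <- unique(trials$condition[sel])
    uni <- select_uni(conds)
    if (!is.na(uni)) {
      g <- trials[sel & trials$condition == uni, ]
      mu <- tapply(g$rate, g$direction, mean)
      peak <- as.numeric(names(mu))[which.max(mu)]  # which.max: first = smallest angle
    } else if ("afix" %in% conds) {
      g <- trials[sel & trials$condition == "afix", ]
      mu <- tapply(g$rate, g$direction, mean)
      ang <- as.numeric(names(mu))
      right <- ang >= 180 & ang < 360
      mu <- mu[right]; ang <- ang[right]
      peak <- ang[which.max(mu)]
    } else {
      stop(sprintf("cell %s has neither a unidirectional nor an afix condition; cannot align", cell))
    }
    off <- (240 - peak) %% 360
    trials$direction[sel] <- (trials$direction[sel] + off) %% 360
    offsets[as.character(cell)] <- off
  }
  attr(trials, "alignment_offsets") <- offsets
  trials
}
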