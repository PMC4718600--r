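#' Two-group Kruskal-Wallis comparison of feature values
#'
#' Compares the distributions of one feature between two groups of cells
#' (e.g. the same feature in two conditions, or two comparable features in
#' one condition) with a two-sample Kruskal-Wallis rank test (ties
#' corrected).  The direction of change is read from the group medians,
#' falling back to the means when the medians tie exactly.
#'
#' With small groups the chi-square approximation to the rank statistic is
#' poor, so the p-value is computed exactly by enumerating all assignments of
#' the pooled ranks to the two groups whenever that enumeration is feasible
#' (at most `exact_max_combos` assignments); otherwise the usual chi-square
#' tail with one degree of freedom is used.
#'
#' @param values_a,values_b numeric vectors of feature values (`NA` dropped).
#' @param alpha significance threshold on the p-value (default 0.05).
#' @param exact_max_combos enumerate the exact permutation null when
#'   `choose(n_a + n_b, n_a)` is at most this (default 1e5); set 0 to force
#'   the asymptotic p-value.
#' @return list with `statistic` (tie-corrected rank statistic `H`), `p`,
#'   `significant`, `direction` (+1 when group b exceeds group a, -1 the
#'   reverse, 0 on a complete tie), `exact`, and the group sizes.
#' @examples
#' compare_feature_pair(c(1, 2, 3, 4), c(4, 5, 6, 7))
#' @export
compare_feature_pair <- function(values_a, values_b, alpha = 0.05,
                                 exact_max_combos = 1e5) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two non-missing values")
  }
  na <- length(a); nb <- length(b); N <- na + nb
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = 0, p = 1, significant = FALSE, direction = 0,
                exact = TRUE, n_a = na, n_b = nb))
  }
  kw <- stats::kruskal.test(list(a, b))
  H <- unname(kw$statistic)
  exact <- is.finite(H) && choose(N, na) <= exact_max_combos
  if (exact) {
    r <- rank(c(a, b))
    ties <- table(r)
    C <- 1 - sum(ties^3 - ties) / (N^3 - N)
    hstat <- function(Ra) {
      h <- 12 / (N * (N + 1)) * (Ra^2 / na + (sum(r) - Ra)^2 / nb) - 3 * (N + 1)
      h / C
    }
    Ra_all <- utils::combn(r, na, sum)
    p <- mean(hstat(Ra_all) >= H - 1e-10)
  } else {
    p <- unname(kw$p.value)
  }
  ma <- stats::median(a); mb <- stats::median(b)
  direction <- if (mb != ma) sign(mb - ma) else sign(mean(b) - mean(a))
  list(statistic = H, p = p,
       significant = is.finite(p) && p < alpha,
       direction = direction, exact = exact, n_a = na, n_b = nb)
}

#' Cross-model agreement counts for feature-pair comparisons
#'
#' For each feature pair evaluated under several model-based methods, counts
#' how many methods judged the pair significantly different, optionally
#' stratified by the direct method's verdict on the same pair.
#'
#' @param significant_by_method logical matrix, pairs x methods (model-based
#'   methods only).
#' @param direct_significant optional logical vector per pair (the direct
#'   method's verdict).
#' @return list with `counts` (integer per pair), `histogram` (table over
#'   0..n_methods) and, when `direct_significant` is given, `histogram_direct_sig`
#'   and `histogram_direct_nonsig`.
#' @export
agreement_counts <- function(significant_by_method, direct_significant = NULL) {
  m <- as.matrix(significant_by_method)
  keep <- !apply(m, 1, anyNA)
  if (any(!keep)) {
    warning(sum(!keep), " pair(s) missing a method verdict; excluded")
    m <- m[keep, , drop = FALSE]
    if (!is.null(direct_significant)) direct_significant <- direct_significant[keep]
  }
  counts <- rowSums(m)
  lev <- 0:ncol(m)
  hist_all <- table(factor(counts, levels = lev))
  out <- list(counts = counts, histogram = hist_all)
  if (!is.null(direct_significant)) {
    out$histogram_direct_sig <- table(factor(counts[direct_significant], levels = lev))
    out$histogram_direct_nonsig <- table(factor(counts[!direct_significant], levels = lev))
  }
  out
}

#' Stimulus-specific trial-ensemble effects between two conditions
#'
#' For one cell, compares the trial firing-rate ensembles of two conditions
#' at each stimulus direction with a two-sample Kolmogorov-Smirnov test
#' (exact p-value for small samples).  A stimulus shows a *specific effect*
#' when `p < alpha`; its direction (enhancement/suppression in condition b
#' relative to a) is the sign of the median difference, falling back to the
#' mean difference on median ties.
#'
#' @param trials_a,trials_b named lists (or lists indexed like the direction
#'   grid) of numeric trial-rate vectors per stimulus direction.
#' @param alpha significance threshold (default 0.05).
#' @param exact_max use the exact KS p-value when the combined trial count is
#'   at most this (default 25); asymptotic otherwise.
#' @return data frame with one row per direction: `direction`, `n_a`, `n_b`,
#'   `D`, `p`, `significant`, `direction_of_change` (+1 enhancement, -1
#'   suppression, 0 tie), `testable`.
#' @examples
#' a <- list(`0` = c(10, 12, 9), `30` = c(5, 6, 7))
#' b <- list(`0` = c(20, 22, 19), `30` = c(5, 6, 8))
#' specific_effects(a, b)
#' @export
specific_effects <- function(trials_a, trials_b, alpha = 0.05, exact_max = 25) {
  dirs <- union(names(trials_a), names(trials_b))
  if (is.null(dirs)) {
    dirs <- as.character(seq_along(trials_a) * 30 - 30)
    names(trials_a) <- names(trials_b) <- dirs
  }
  out <- data.frame(direction = as.numeric(dirs), n_a = NA_integer_,
                    n_b = NA_integer_, D = NA_real_, p = NA_real_,
                    significant = FALSE, direction_of_change = NA_real_,
                    testable = FALSE)
  for (i in seq_along(dirs)) {
    a <- trials_a[[dirs[i]]]; b <- trials_b[[dirs[i]]]
    out$n_a[i] <- length(a); out$n_b[i] <- length(b)
    if (length(a) < 2 || length(b) < 2) next
    out$testable[i] <- TRUE
    exact <- (length(a) + length(b)) <= exact_max
    ks <- suppressWarnings(stats::ks.test(a, b, exact = exact))
    out$D[i] <- unname(ks$statistic)
    out$p[i] <- unname(ks$p.value)
    out$significant[i] <- ks$p.value < alpha
    md <- stats::median(b) - stats::median(a)
    out$direction_of_change[i] <- if (md != 0) sign(md) else sign(mean(b) - mean(a))
  }
  out[order(out$direction), ]
}

#' Population summary of specific effects
#'
#' Aggregates per-cell [specific_effects()] maps into (i) a histogram of the
#' number of significant stimuli per cell (0-12) and (ii) per-stimulus
#' fractions of cells with no significant modulation, a significant
#' enhancement, or a significant suppression.
#'
#' @param maps list of data frames from [specific_effects()], one per cell.
#' @return list with `per_cell_counts`, `count_histogram` (table over 0..12)
#'   and `per_stimulus` (data frame: direction, fraction_none,
#'   fraction_enhanced, fraction_suppressed).
#' @export
specific_effect_summary <- function(maps) {
  if (length(maps) == 0) stop("no specific-effect maps supplied")
  counts <- vapply(maps, function(m) sum(m$significant, na.rm = TRUE), 0L)
  hist <- table(factor(counts, levels = 0:12))
  dirs <- sort(unique(unlist(lapply(maps, function(m) m$direction))))
  per <- data.frame(direction = dirs, fraction_none = NA_real_,
                    fraction_enhanced = NA_real_, fraction_suppressed = NA_real_)
  for (i in seq_along(dirs)) {
    sig <- vapply(maps, function(m) {
      r <- m[m$direction == dirs[i], , drop = FALSE]
      if (nrow(r) == 0 || !r$testable) return(NA_real_)
      if (!r$significant) 0 else r$direction_of_change
    }, 0)
    sig <- sig[!is.na(sig)]
    per$fraction_none[i] <- mean(sig == 0)
    per$fraction_enhanced[i] <- mean(sig > 0)
    per$fraction_suppressed[i] <- mean(sig < 0)
  }
  list(per_cell_counts = counts, count_histogram = hist, per_stimulus = per)
}
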