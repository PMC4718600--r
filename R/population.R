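#' Fit every model family to every curve
#'
#' @param curves list of [tuning_curve()] objects (e.g. from
#'   [build_curves()]).
#' @param families families to fit (default all eight).
#' @param ... passed to [tunefit()].
#' @return named list (per curve) of named lists (per family) of
#'   `"tunefit"` objects.
#' @export
fit_population <- function(curves, families = tune_families()$family, ...) {
  lapply(curves, function(cur) {
    fits <- lapply(families, function(f) tunefit(cur, f, ...))
    stats::setNames(fits, families)
  })
}

#' Maximum unidirectional firing rate per cell
#'
#' Used to normalise rate-valued features; cells without a unidirectional
#' condition get `NA`.
#'
#' @param curves list of [tuning_curve()] objects for one population.
#' @return named numeric vector by `cell_id`.
#' @export
uni_max_by_cell <- function(curves) {
  cells <- unique(vapply(curves, function(c) c$cell_id, ""))
  out <- stats::setNames(rep(NA_real_, length(cells)), cells)
  for (cell in cells) {
    mine <- Filter(function(c) c$cell_id == cell, curves)
    conds <- vapply(mine, function(c) c$condition, "")
    uni <- select_uni(conds)
    if (!is.na(uni)) out[cell] <- max(mine[[match(uni, conds)]]$y)
  }
  out
}

#' Feature table for a population of curves
#'
#' Extracts the full feature set for every curve, either directly from the
#' 12 trial-mean points (`method = "direct"`), from one fitted family
#' sampled at `resolution` degrees, or from each cell's best model
#' (`method = "bM"`, requiring `selections`).
#'
#' @param curves named list of [tuning_curve()] objects.
#' @param method `"direct"`, a family name, or `"bM"`.
#' @param fits output of [fit_population()] (required unless direct).
#' @param selections per-curve [select_model()] results (required for bM).
#' @param uni_max named vector from [uni_max_by_cell()]; computed from
#'   `curves` when `NULL`.
#' @param resolution sampling step for fitted curves (default 1 degree).
#' @return numeric matrix, curves x features, with `NA` where undefined.
#' @export
feature_table <- function(curves, method = "direct", fits = NULL,
                          selections = NULL, uni_max = NULL, resolution = 1) {
  if (is.null(uni_max)) uni_max <- uni_max_by_cell(curves)
  keys <- names(curves)
  if (is.null(keys)) keys <- as.character(seq_along(curves))
  rows <- lapply(seq_along(curves), function(i) {
    cur <- curves[[i]]
    um <- uni_max[[cur$cell_id]]
    if (method == "direct") {
      return(extract_features(cur, uni_max = um))
    }
    if (is.null(fits)) stop("model-based feature tables need `fits`")
    fam <- method
    if (method == "bM") {
      if (is.null(selections)) stop("method 'bM' needs `selections`")
      fam <- selections[[keys[i]]]$best
    }
    extract_features(fits[[keys[i]]][[fam]], uni_max = um,
                     resolution = resolution)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- keys
  m
}
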