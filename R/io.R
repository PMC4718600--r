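#' Read a trial-level tuning dataset from CSV
#'
#' Reads a tidy CSV (one trial per row) into a validated [tuning_trials()]
#' table.  Source files with different headers are adapted through
#' `column_map`, a named character vector mapping the canonical fields to
#' source column names.  Spike-count files are supported by mapping
#' `spike_count` plus `window_seconds` instead of `rate`; rates are then
#' derived as `count / window`.
#'
#' @param path CSV file path.
#' @param column_map named character vector, e.g.
#'   `c(cell_id = "unit", rate = "fr")`; unmapped canonical names are taken
#'   verbatim.
#' @return a [tuning_trials()] table.
#' @export
read_tuning_trials <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canon <- c("cell_id", "paradigm", "condition", "direction", "trial_index",
             "rate", "spike_count", "window_seconds")
  map <- stats::setNames(canon, canon)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in canon) {
    if (map[[f]] %in% names(raw)) out[[f]] <- raw[[map[[f]]]]
  }
  if (is.null(out$rate)) {
    if (is.null(out$spike_count) || is.null(out$window_seconds)) {
      stop("need either a rate column or spike_count + window_seconds")
    }
    out$rate <- out$spike_count / out$window_seconds
  }
  out$spike_count <- NULL; out$window_seconds <- NULL
  tuning_trials(out)
}

#' Write a trial-level tuning dataset to CSV
#'
#' @param trials a [tuning_trials()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[, c("cell_id", "paradigm",
    "condition", "direction", "trial_index", "rate")], path,
    row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table with a reproducibility manifest
#'
#' Writes any results data frame as CSV and, alongside it, a small JSON
#' manifest recording the seed, thresholds and package version of the run so
#' that outputs can be reproduced byte-for-byte.
#'
#' @param results data frame.
#' @param path output CSV path; the manifest goes to `<path>.manifest.json`.
#' @param manifest named list of run metadata (seed, alpha, ...).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, manifest = list()) {
  utils::write.csv(results, path, row.names = FALSE)
  manifest <- c(manifest, list(
    package = "tuneshape",
    version = as.character(utils::packageVersion("tuneshape")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  json <- paste0("{\n", paste(sprintf('  "%s": %s', names(manifest),
    vapply(manifest, function(v) {
      if (is.numeric(v) && length(v) == 1) format(v, digits = 15)
      else paste0('"', as.character(v)[1], '"')
    }, "")), collapse = ",\n"), "\n}\n")
  writeLines(json, paste0(path, ".manifest.json"))
  invisible(path)
}
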