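# Plain-text interchange: survey frames as CSV with a YAML schema sidecar,
# population projections and completed sets as CSV, imputation specs as
# YAML, run metadata as JSON. Empty fields encode missing values.

frame_schema <- function(frame) {
  list(
    columns = lapply(stats::setNames(names(frame), names(frame)), function(cn) {
      v <- frame[[cn]]
      role <- if (cn %in% DEMOGRAPHIC_COLUMNS) "demographic"
      else if (cn %in% SURVEY_COLUMNS) "survey"
      else "meta"
      type <- if (is.factor(v)) "factor"
      else if (is.logical(v)) "logical"
      else if (is.integer(v)) "integer" else "numeric"
      out <- list(role = role, type = type)
      if (is.factor(v)) out$levels <- levels(v)
      out
    }),
    missing = ""
  )
}

#' Write a survey frame as CSV with a YAML schema sidecar
#'
#' One row per invited person; empty fields encode missing values; the
#' sidecar (`<path>.schema.yaml`) records each column's role (demographic /
#' survey / meta), storage type, and factor levels so the frame round-trips
#' exactly.
#'
#' @param frame a survey frame.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_survey_frame <- function(frame, path) {
  utils::write.csv(frame, path, row.names = FALSE, na = "")
  yaml::write_yaml(frame_schema(frame), paste0(path, ".schema.yaml"))
  invisible(path)
}

#' Read a survey frame written by [write_survey_frame()]
#'
#' @param path CSV path (the sidecar `<path>.schema.yaml` must exist).
#' @return the survey frame with factor levels and column types restored.
#' @export
read_survey_frame <- function(path) {
  schema <- yaml::read_yaml(paste0(path, ".schema.yaml"))
  raw <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         colClasses = "character")
  out <- raw
  for (cn in names(schema$columns)) {
    sc <- schema$columns[[cn]]
    v <- raw[[cn]]
    out[[cn]] <- switch(sc$type,
                        factor = factor(v, levels = sc$levels),
                        logical = as.logical(v),
                        integer = as.integer(v),
                        as.numeric(v))
  }
  out
}

#' Write / read a population projection table
#'
#' @param projection a `population_projection` data frame.
#' @param path CSV path.
#' @return `path` (write) or the projection table (read).
#' @export
write_population_projection <- function(projection, path) {
  utils::write.csv(projection, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_projection
#' @export
read_population_projection <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "sex", "age", "weight") %in% names(out)))
  class(out) <- c("population_projection", "data.frame")
  out
}

#' Write / read imputation specs as YAML
#'
#' @param specs list of [imputation_spec()]s.
#' @param path YAML path.
#' @return `path` (write) or the spec list (read).
#' @export
write_specs <- function(specs, path) {
  specs <- as_spec_list(specs)
  yaml::write_yaml(lapply(specs, unclass), path)
  invisible(path)
}

#' @rdname write_specs
#' @export
read_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    imputation_spec(s$target, s$sampler, unlist(s$predictors), s$year_form,
                    if (!is.null(s$knots)) unlist(s$knots))
  })
}

#' Serialise a completed set as CSVs plus JSON metadata
#'
#' Writes one CSV per imputation (`imp_001.csv`, ...), the chain-mean
#' diagnostics as `chain_means.csv` (columns: target, iteration, stream,
#' mean), and run metadata (config, specs) as `metadata.json` into `dir`.
#'
#' @param completed a `completed_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_completed_set <- function(completed, dir) {
  stopifnot(inherits(completed, "completed_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(completed$imputations)) {
    utils::write.csv(completed$imputations[[i]],
                     file.path(dir, sprintf("imp_%03d.csv", i)),
                     row.names = FALSE, na = "")
  }
  cm <- completed$chain_means
  long <- expand.grid(target = dimnames(cm)[[1]],
                      iteration = seq_len(dim(cm)[2]),
                      stream = seq_len(dim(cm)[3]),
                      KEEP.OUT.ATTRS = FALSE)
  long$mean <- as.vector(cm)
  utils::write.csv(long, file.path(dir, "chain_means.csv"), row.names = FALSE)
  meta <- list(config = unclass(completed$config),
               specs = lapply(completed$specs, unclass),
               n_missing = lapply(completed$miss, length))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
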