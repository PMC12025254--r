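#' Write metric tables as CSV and JSON with provenance
#'
#' Each table is written as `<name>.csv` and `<name>.json`; the JSON copy
#' embeds the configuration hash and seed so a run can be reproduced and
#' verified bit-for-bit.
#'
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @param config Configuration object hashed into the output.
#' @param seed Seed recorded in the output.
#' @return Invisibly, the vector of files written.
#' @export
write_metrics <- function(tables, dir, config = NULL, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(tables)) {
    csv <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], csv, row.names = FALSE)
    js <- file.path(dir, paste0(nm, ".json"))
    jsonlite::write_json(
      list(table = tables[[nm]],
           config_hash = if (is.null(config)) NA else config_hash(config),
           seed = seed),
      js, dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    written <- c(written, csv, js)
  }
  invisible(written)
}

#' Save a segment set to disk
#'
#' Compressed array container plus a JSON metadata sidecar (band, shape,
#' window provenance).
#'
#' @param segments A `segment_set`.
#' @param path Output path (`.rds`); a `.json` sidecar is written next to
#'   it.
#' @return `path`, invisibly.
#' @export
save_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_set"))
  saveRDS(segments, path, compress = "gzip")
  jsonlite::write_json(
    list(band = segments$band, n = dim(segments$segments)[1],
         n_channels = dim(segments$segments)[2],
         window_samples = dim(segments$segments)[3],
         sample_rate = segments$sample_rate,
         class_counts = as.list(table(segments$labels))),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname save_segments
#' @export
load_segments <- function(path) {
  s <- readRDS(path)
  stopifnot(inherits(s, "segment_set"))
  s
}

#' Save / load a trained model
#'
#' Checkpoints carry the full parameter set, batch-norm buffers, model
#' configuration, input scale and training history.
#'
#' @param model A `duformer_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the model (load), invisibly for save.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "duformer_model"))
  saveRDS(model, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "duformer_model"))
  m
}
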