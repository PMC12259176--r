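## Plain-text serialization: images/trials as CSV, spike-count tensors as
## long-format CSV, reports as JSON, configurations as YAML.

#' Write and read generator tables
#'
#' Images are stored as `(image_id, memorability)` CSV; trials as one row
#' per trial with novelty, n-back, on-target flag and (when present)
#' behavioral choice columns.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `path`, invisibly (writers); a tibble (readers).
#' @export
write_images_csv <- function(x, path) {
  readr::write_csv(x[, c("image_id", "memorability")], path)
  invisible(path)
}

#' @rdname write_images_csv
#' @export
read_images_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(), memorability = readr::col_double()))
}

#' @rdname write_images_csv
#' @export
write_trials_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_images_csv
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trial_index = readr::col_integer(), image_id = readr::col_character(),
    novelty = readr::col_character(), n_back = readr::col_integer(),
    on_target = readr::col_logical(), .default = readr::col_guess()))
}

#' Serialize a session's spike-count tensor as long CSV
#'
#' One row per (unit, trial, bin) with a nonzero-count filter disabled so
#' the round trip is exact. Bin edges travel in a JSON sidecar written next
#' to the CSV.
#'
#' @param session A `session_recording`.
#' @param path CSV path; `<path>.meta.json` holds bin edges and ids.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(session, path) {
  d <- dim(session$counts)
  long <- tibble::tibble(
    unit = rep(seq_len(d[1]), times = d[2] * d[3]),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    bin = rep(seq_len(d[3]), each = d[1] * d[2]),
    count = as.integer(session$counts)
  )
  readr::write_csv(long[long$count != 0, ], path)
  jsonlite::write_json(
    list(dim = d, bin_edges = session$bin_edges,
         unit_ids = session$units$unit_id),
    paste0(path, ".meta.json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_counts_csv
#' @param trials,images Tables re-attached to the restored session.
#' @export
read_counts_csv <- function(path, trials, images) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  long <- readr::read_csv(path, col_types = "iiii")
  counts <- array(0L, dim = meta$dim)
  counts[cbind(long$unit, long$trial, long$bin)] <- long$count
  structure(
    list(counts = counts, trials = trials, images = images,
         units = tibble::tibble(unit_id = meta$unit_ids),
         bin_edges = meta$bin_edges, config_name = "restored"),
    class = "session_recording"
  )
}

#' Write a screen report as JSON
#' @param report Tibble from [responsiveness_filter()] or
#'   [stability_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_json <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read or write a run configuration as YAML
#' @param config A [run_config()] list.
#' @param path YAML path.
#' @return `path` invisibly (writer) or the config list (reader).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass_config(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

unclass_config <- function(x) {
  x <- unclass(x)
  lapply(x, function(e) if (is.list(e)) unclass_config(e) else e)
}
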