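# Delimited-text I/O for recordings and flat key-value results files.

#' Write a recording as CSV with a provenance sidecar
#'
#' Writes `time,<channel1>,...,<channelN>,force` rows and, when the
#' recording carries a generator config, a `<path>.yml` sidecar storing it.
#'
#' @param recording A `semg_recording`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_recording <- function(recording, path) {
  readr::write_csv(as_tibble(as.data.frame(recording)), path)
  truth <- attr(recording, "truth")
  meta <- list(
    fs = rec_fs(recording),
    channel_labels = as.list(rec_labels(recording))
  )
  if (!is.null(truth)) {
    meta$synth_config <- lapply(unclass(truth), function(v)
      if (length(v) > 1) as.list(v) else v)
  }
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path; the `<path>.yml` sidecar is read when present,
#'   otherwise `fs` is inferred from the time column.
#' @return A `semg_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    fs <- meta$fs
    labels <- unlist(meta$channel_labels)
  } else {
    fs <- 1 / median(diff(df$time))
    labels <- setdiff(names(df), c("time", "force"))
  }
  new_recording(as.matrix(df[, labels, drop = FALSE]), df$force, fs, labels)
}

#' Write a flat key-value results file
#'
#' One `key: value` line per entry with deterministic formatting, so a
#' rerun under the same config and seed reproduces the file byte-for-byte.
#'
#' @param values Named list of scalars.
#' @param path Output path.
#' @export
write_results_kv <- function(values, path) {
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.12g", v) else as.character(v)
  }
  lines <- vapply(seq_along(values),
                  function(i) sprintf("%s: %s", names(values)[i],
                                      fmt(values[[i]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}
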