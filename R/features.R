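# Classical per-window time-domain EMG features: mean absolute value,
# variance, zero crossings, Willison amplitude.

#' Mean absolute value of a window
#' @param window Non-empty numeric vector.
#' @return `(1/L) * sum(|x_i|)`.
#' @export
mav <- function(window) {
  if (length(window) == 0) abort("window is empty.")
  mean(abs(window))
}

#' Sample variance of a window (denominator L - 1)
#' @inheritParams mav
#' @export
emg_var <- function(window) {
  if (length(window) == 0) abort("window is empty.")
  if (length(window) == 1) return(0)
  var(window)
}

#' Zero-crossing count of a window
#'
#' Counts sign changes between consecutive samples whose amplitude step
#' exceeds the threshold (a small threshold suppresses noise-induced
#' crossings around zero).
#'
#' @inheritParams mav
#' @param threshold Minimum `|x_i - x_{i+1}|` for a crossing to count.
#' @return Integer in `[0, L - 1]`.
#' @export
zero_crossings <- function(window, threshold = 0) {
  if (length(window) < 2) return(0L)
  a <- window[-length(window)]
  b <- window[-1]
  sum(a * b < 0 & abs(a - b) > threshold)
}

#' Willison amplitude of a window
#'
#' Counts consecutive-sample amplitude steps exceeding the threshold.
#'
#' @inheritParams zero_crossings
#' @export
willison_amplitude <- function(window, threshold) {
  if (length(window) < 2) return(0L)
  sum(abs(diff(window)) > threshold)
}

#' Feature extraction settings
#'
#' @param features Subset of `c("MAV", "VAR", "ZC", "WA")`.
#' @param zc_threshold Zero-crossing amplitude threshold (default 0).
#' @param wa_threshold Willison-amplitude threshold; `NULL` (default) uses
#'   `0.05 *` the RMS of each window.
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(features = c("MAV", "VAR", "ZC", "WA"),
                         zc_threshold = 0, wa_threshold = NULL) {
  features <- match.arg(features, several.ok = TRUE)
  stopifnot(is.finite(zc_threshold), zc_threshold >= 0,
            is.null(wa_threshold) ||
              (is.finite(wa_threshold) && wa_threshold >= 0))
  structure(list(features = features, zc_threshold = zc_threshold,
                 wa_threshold = wa_threshold), class = "feature_spec")
}

window_feature <- function(window, feature, spec) {
  window <- as.numeric(window)
  switch(feature,
    MAV = mav(window),
    VAR = emg_var(window),
    ZC = zero_crossings(window, spec$zc_threshold),
    WA = willison_amplitude(
      window,
      spec$wa_threshold %||% (0.05 * sqrt(mean(window^2)))
    ),
    abort(sprintf("unknown feature '%s'", feature))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute time-domain features for every window
#'
#' Replaces each window's raw samples with the requested features, keeping
#' row order. Column order is feature-major: for each feature in spec
#' order, one column per channel, named `<feature>_<channel>`.
#'
#' @param windows A `semg_windows` from [build_windows()].
#' @param spec A [feature_spec()].
#' @return A `semg_windows`-like object whose `x` holds feature columns
#'   (one row per window) and whose `channel_mode` is `"stacked"`.
#' @export
featurize <- function(windows, spec = feature_spec()) {
  arr <- windows_array(windows)
  n_win <- dim(arr)[1]
  labels <- windows$labels
  cols <- list()
  for (f in spec$features) {
    for (c in seq_along(labels)) {
      cols[[paste0(f, "_", labels[c])]] <-
        apply(arr[, c, , drop = FALSE], 1, window_feature, feature = f,
              spec = spec)
    }
  }
  x <- do.call(cbind, cols)
  out <- windows
  out$x <- x
  out$y <- windows_targets(windows)
  out$window_id <- seq_len(n_win)
  out$channel <- rep(NA_character_, n_win)
  out$t_start <- unique_window_field(windows, "t_start")
  out$channel_mode <- "stacked"
  out$feature_names <- colnames(x)
  out$feature_spec <- spec
  out
}

unique_window_field <- function(windows, field) {
  if (windows$channel_mode == "stacked") windows[[field]]
  else windows[[field]][windows$channel == windows$labels[1]]
}

#' Write a feature table as delimited text
#'
#' @param windows A featurized `semg_windows` (see [featurize()]).
#' @param path Output CSV path.
#' @export
write_features <- function(windows, path) {
  df <- bind_cols(
    tibble(window_id = windows$window_id, t_start = windows$t_start),
    as_tibble(windows$x),
    tibble(force = windows$y)
  )
  readr::write_csv(df, path)
  invisible(path)
}
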