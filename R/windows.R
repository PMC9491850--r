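# Sliding-window dataset construction.

#' Slice a recording into per-window samples with force targets
#'
#' Slides a window of `window_len` samples with the given stride over the
#' recording and pairs every window with its mean force. In `per_channel`
#' mode each channel contributes its own row per window (rows are
#' window-major: all channels of window 1, then window 2, ...); in
#' `stacked` mode each row concatenates all channels of one window.
#'
#' @param recording A `semg_recording` (see [generate_recording()]).
#' @param window_len Window length in samples.
#' @param stride Hop between consecutive windows in samples
#'   (`0 < stride <= window_len` for a covering; any positive stride is
#'   accepted).
#' @param channel_mode `"per_channel"` (default) or `"stacked"`.
#' @param channels Optional subset of channel names or indices.
#' @return A `semg_windows` object: matrix `x` of per-window vectors,
#'   targets `y` (N), and per-row `window_id`, `channel`, `t_start` (s).
#' @export
build_windows <- function(recording, window_len = 200, stride = 100,
                          channel_mode = c("per_channel", "stacked"),
                          channels = NULL) {
  channel_mode <- match.arg(channel_mode)
  if (nrow(recording) == 0) abort("recording is empty.")
  if (stride <= 0) abort("stride must be positive.")
  n <- nrow(recording)
  if (window_len > n) abort("window_len exceeds the recording length.")
  labels <- rec_labels(recording)
  if (!is.null(channels)) {
    if (is.numeric(channels)) channels <- labels[channels]
    stopifnot(all(channels %in% labels))
    labels <- channels
  }
  sig <- as.matrix(recording[, labels, drop = FALSE])
  force <- rec_force(recording)

  n_win <- (n - window_len) %/% stride + 1L
  starts <- (seq_len(n_win) - 1L) * stride + 1L
  idx <- outer(starts, 0:(window_len - 1L), `+`)  # n_win x window_len
  y <- rowMeans(matrix(force[idx], n_win, window_len))
  t_start <- (starts - 1L) / rec_fs(recording)

  per_channel <- lapply(seq_along(labels), function(c) {
    matrix(sig[, c][idx], n_win, window_len)
  })

  if (channel_mode == "stacked") {
    x <- do.call(cbind, per_channel)
    win_id <- seq_len(n_win)
    channel <- rep(NA_character_, n_win)
    row_y <- y
    row_t <- t_start
  } else {
    # window-major interleave so rows of one window are contiguous
    x <- matrix(0, n_win * length(labels), window_len)
    for (c in seq_along(labels)) {
      x[seq(c, by = length(labels), length.out = n_win), ] <- per_channel[[c]]
    }
    win_id <- rep(seq_len(n_win), each = length(labels))
    channel <- rep(labels, times = n_win)
    row_y <- rep(y, each = length(labels))
    row_t <- rep(t_start, each = length(labels))
  }

  structure(list(
    x = x, y = row_y, window_id = win_id, channel = channel,
    t_start = row_t, window_len = window_len, stride = stride,
    channel_mode = channel_mode, labels = labels, fs = rec_fs(recording),
    n_windows = n_win
  ), class = "semg_windows")
}

#' @export
print.semg_windows <- function(x, ...) {
  cat(sprintf(
    "<semg_windows> %d windows x %d channels (%s), window %d, stride %d\n",
    x$n_windows, length(x$labels), x$channel_mode, x$window_len, x$stride
  ))
  invisible(x)
}

#' @export
as_tibble.semg_windows <- function(x, ...) {
  tibble(
    window_id = x$window_id, channel = x$channel, t_start = x$t_start,
    force = x$y, sample = asplit(x$x, 1)
  )
}

#' Rows of a windowed dataset for one channel
#'
#' @param windows A `semg_windows` in `per_channel` mode.
#' @param channel Channel name or index.
#' @return A `semg_windows`-like list restricted to that channel, with one
#'   row per window.
#' @export
channel_windows <- function(windows, channel) {
  stopifnot(windows$channel_mode == "per_channel")
  if (is.numeric(channel)) channel <- windows$labels[channel]
  keep <- windows$channel == channel
  out <- windows
  out$x <- windows$x[keep, , drop = FALSE]
  out$y <- windows$y[keep]
  out$window_id <- windows$window_id[keep]
  out$channel <- windows$channel[keep]
  out$t_start <- windows$t_start[keep]
  out$labels <- channel
  out
}

# 3-D [batch, channel, length] array view of a windowed dataset, the input
# layout the DRSN consumes.
windows_array <- function(windows) {
  n_win <- windows$n_windows
  n_ch <- length(windows$labels)
  L <- ncol(windows$x) %/% if (windows$channel_mode == "stacked") n_ch else 1L
  arr <- array(0, c(n_win, n_ch, L))
  if (!is.null(windows$feature_names)) {
    # featurized datasets are feature-major: column (f-1)*C + c
    for (c in seq_len(n_ch)) {
      arr[, c, ] <- windows$x[, (seq_len(L) - 1L) * n_ch + c, drop = FALSE]
    }
  } else if (windows$channel_mode == "stacked") {
    for (c in seq_len(n_ch)) {
      arr[, c, ] <- windows$x[, ((c - 1L) * L + 1L):(c * L)]
    }
  } else {
    for (c in seq_len(n_ch)) {
      arr[, c, ] <- windows$x[windows$channel == windows$labels[c], ,
                              drop = FALSE]
    }
  }
  dimnames(arr) <- list(NULL, windows$labels, NULL)
  arr
}

# Per-window targets (one per window regardless of channel_mode).
windows_targets <- function(windows) {
  if (windows$channel_mode == "stacked") windows$y
  else windows$y[windows$channel == windows$labels[1]]
}
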