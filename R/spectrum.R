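# Welch-style averaged modified periodogram and interference detection.

#' Power spectral density of a signal (averaged modified periodogram)
#'
#' Splits the signal into overlapping segments, applies a Hann taper,
#' averages the per-segment periodograms, and normalizes to a one-sided
#' power spectral density so that the integral over frequency approximates
#' the signal's variance (Parseval).
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency in Hz.
#' @param segment_s Segment length in seconds (default 1 s).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A `semg_spectrum` object: tibble with columns `frequency` (Hz)
#'   and `power` (density), plus `fs` attribute.
#' @export
power_spectrum <- function(x, fs, segment_s = 1, overlap = 0.5) {
  x <- as.numeric(x) - mean(x)
  nseg <- min(length(x), max(8L, round(segment_s * fs)))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1)))  # Hann
  u <- sum(w^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    p <- abs(fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  inner <- 2:(nf - if (nseg %% 2L == 0L) 1L else 0L)
  psd[inner] <- 2 * psd[inner]
  out <- tibble(
    frequency = (seq_len(nf) - 1) * fs / nseg,
    power = psd
  )
  attr(out, "fs") <- fs
  class(out) <- c("semg_spectrum", class(out))
  out
}

#' Detect a narrowband interference peak near a target frequency
#'
#' Looks for a local maximum of the power spectral density within
#' `tol_hz` of `target_hz` that exceeds the median density of the
#' surrounding band by at least `factor`.
#'
#' @param spectrum A [power_spectrum()] result.
#' @param target_hz Frequency to probe (e.g. 50 for powerline pickup).
#' @param tol_hz Search half-width around the target (Hz).
#' @param factor Required peak-to-local-median power ratio.
#' @param band_hz Half-width (Hz) of the band used for the local median.
#' @return One-row tibble: `detected`, `peak_hz`, `peak_power`, `ratio`.
#' @export
detect_interference <- function(spectrum, target_hz, tol_hz = 1,
                                factor = 3, band_hz = 25) {
  f <- spectrum$frequency
  p <- spectrum$power
  in_tol <- which(abs(f - target_hz) <= tol_hz)
  if (length(in_tol) == 0) abort("no frequency bins within tol_hz of target_hz.")
  i_peak <- in_tol[which.max(p[in_tol])]
  in_band <- abs(f - target_hz) <= band_hz &
    abs(f - f[i_peak]) > 2 * tol_hz & f > 0
  ref <- median(p[in_band])
  ratio <- p[i_peak] / ref
  # a genuine peak must also top its immediate neighbourhood
  nb <- which(abs(f - f[i_peak]) <= 2 * (f[2] - f[1]))
  is_local_max <- p[i_peak] >= max(p[nb])
  tibble(
    detected = is_local_max && ratio >= factor,
    peak_hz = f[i_peak],
    peak_power = p[i_peak],
    ratio = ratio
  )
}

#' Fraction of total band power below a cutoff frequency
#'
#' @param spectrum A [power_spectrum()] result.
#' @param cutoff_hz Cutoff in Hz.
#' @return Fraction in `[0, 1]` of integrated power at or below the cutoff.
#' @export
band_power_fraction <- function(spectrum, cutoff_hz) {
  sum(spectrum$power[spectrum$frequency <= cutoff_hz]) / sum(spectrum$power)
}
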