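# Performance indices and SNR-controlled noise injection.

#' Mean squared error between measured and predicted force
#'
#' @param measured,predicted Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @examples
#' mse(c(1, 2), c(0, 0)) # 2.5
#' @export
mse <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 1) {
    abort("measured and predicted must be non-empty and of equal length.")
  }
  mean((measured - predicted)^2)
}

#' Force-prediction performance indices
#'
#' Computes the package's standard regression indices: mean squared error,
#' root-mean-square error (N), mean absolute error (N), and the Pearson
#' correlation between measured and predicted force in percent.
#'
#' @inheritParams mse
#' @return One-row tibble with columns `mse`, `rms`, `mave`, `rho`. `rho`
#'   is `NA` (with a warning) when the measured trace is constant.
#' @export
metrics_suite <- function(measured, predicted) {
  m <- mse(measured, predicted)
  rho <- if (sd(measured) == 0 || sd(predicted) == 0) {
    warning("correlation undefined for a constant trace; rho reported as NA")
    NA_real_
  } else {
    100 * cor(measured, predicted)
  }
  tibble(
    mse = m,
    rms = sqrt(m),
    mave = mean(abs(measured - predicted)),
    rho = rho
  )
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Scales the noise so that `10 * log10(P_signal / P_noise)` equals
#' `snr_db` exactly for the realized noise vector.
#'
#' @param signal Numeric vector.
#' @param snr_db Target signal-to-noise ratio in dB; `Inf` returns the
#'   signal unchanged.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return Noisy signal of the same length.
#' @export
add_noise_snr <- function(signal, snr_db, seed = 1) {
  if (is.infinite(snr_db)) return(signal)
  noise <- if (is.null(seed)) rnorm(length(signal)) else
    with_seed(seed, rnorm(length(signal)))
  p_signal <- mean(signal^2)
  p_target <- p_signal / 10^(snr_db / 10)
  signal + noise * sqrt(p_target / mean(noise^2))
}

#' Measure the SNR between a clean and a noisy signal
#'
#' @param clean,noisy Equal-length numeric vectors; the noise is their
#'   difference.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy) {
  10 * log10(mean(clean^2) / mean((noisy - clean)^2))
}
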