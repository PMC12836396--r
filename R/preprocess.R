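#' Fourier-method resampling of a haemoglobin series
#'
#' Rate conversion by spectral truncation/zero-padding (the Fourier method):
#' the series is transformed, its spectrum cut or padded to the new length
#' `round(n * target / source)`, and transformed back. Exact for band-limited
#' signals; the two-site pipeline uses it to bring the 12.34 Hz recordings to
#' the common 8.13 Hz analysis rate.
#'
#' @param hb an [hb_series()].
#' @param target_rate target rate in Hz.
#' @return An [hb_series()] at `target_rate`.
#' @export
resample_series <- function(hb, target_rate) {
  stopifnot(inherits(hb, "hb_series"))
  if (target_rate <= 0) abort("`target_rate` must be positive.")
  if (any(!is.finite(hb$hbo2)) || any(!is.finite(hb$hhb))) {
    abort("non-finite values in input series.")
  }
  if (abs(target_rate - hb$sampling_rate) < 1e-12) return(hb)
  n_in <- ncol(hb$hbo2)
  n_out <- as.integer(round(n_in * target_rate / hb$sampling_rate))
  map_chromophores(hb, function(m) {
    t(apply(m, 1, fft_resample, n_out = n_out))
  }, new_rate = target_rate)
}

# scipy-style Fourier resampling of one real series to n_out samples
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(length.out = n_out)
  nyq_in <- floor(n / 2); nyq_out <- floor(n_out / 2)
  m <- min(nyq_in, nyq_out)
  Y[1] <- X[1]
  if (m >= 1) {
    Y[2:(m + 1)] <- X[2:(m + 1)]
    Y[n_out - (1:m) + 1] <- X[n - (1:m) + 1]
  }
  # split a shared Nyquist bin symmetrically when downsampling onto it
  if (n_out < n && n_out %% 2 == 0) {
    Y[nyq_out + 1] <- X[nyq_out + 1] + X[n - nyq_out + 1]
    Y[nyq_out + 1] <- Re(Y[nyq_out + 1]) / 2
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth design applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and the squared
#' magnitude response. Default cut-offs 0.01-0.2 Hz isolate the haemodynamic
#' band, excluding cardiac and very-low-frequency drift.
#'
#' @param hb an [hb_series()].
#' @param low,high cut-off frequencies in Hz.
#' @param order filter order (of the one-pass design).
#' @return A filtered [hb_series()].
#' @export
bandpass <- function(hb, low = 0.01, high = 0.2, order = 4) {
  stopifnot(inherits(hb, "hb_series"))
  ny <- hb$sampling_rate / 2
  if (!(low > 0 && low < high && high < ny)) {
    abort("cut-offs must satisfy 0 < low < high < Nyquist.")
  }
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  map_chromophores(hb, function(m) {
    t(apply(m, 1, function(x) signal::filtfilt(bf, x)))
  })
}

#' Global mean removal (PCA spatial filter)
#'
#' Removes the channel-common systemic component per chromophore: the
#' channels x samples matrix is decomposed by SVD and the leading
#' `n_components` spatial component(s) subtracted. With one component this
#' removes the dominant global signal (scalp haemodynamics, systemic
#' physiology) shared across channels while preserving channel count and run
#' length.
#'
#' @param hb an [hb_series()] (at least 2 included channels).
#' @param n_components number of leading spatial components to remove.
#' @return The filtered [hb_series()].
#' @export
global_mean_removal <- function(hb, n_components = 1) {
  stopifnot(inherits(hb, "hb_series"))
  if (nrow(hb$hbo2) < 2) abort("global mean removal needs at least 2 channels.")
  strip <- function(m) {
    s <- svd(m, nu = n_components, nv = n_components)
    m - s$u %*% (diag(s$d[seq_len(n_components)], n_components) %*% t(s$v))
  }
  map_chromophores(hb, strip)
}
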