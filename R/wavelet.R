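#' Build the analysis scale grid
#'
#' Default logarithmic grid: `octaves * voices` periods
#' `p_k = base_period * 2^(k / voices)`, k = 0 ... octaves*voices - 1, which
#' for 4 octaves x 4 voices from 2.5 s spans 2.5 to ~33.6 s (0.4 down to
#' ~0.03 Hz) in 16 scales. A linear grid in fixed `base_period` increments
#' (2.5, 5, ..., 40 s under defaults) is selectable; both constructions
#' yield 16 scales under defaults.
#'
#' @param octaves number of octaves (log spacing) .
#' @param voices voices per octave.
#' @param base_period shortest period in s.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return A list of class `scale_grid`: `periods` (s, ascending),
#'   `octaves`, `voices`, `base_period`, `spacing`.
#' @export
#' @examples
#' build_scale_grid()$periods  # 16 periods from 2.5 s
build_scale_grid <- function(octaves = 4, voices = 4, base_period = 2.5,
                             spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (octaves < 1 || voices < 1) abort("octaves and voices must be >= 1.")
  if (base_period <= 0) abort("`base_period` must be positive.")
  n <- octaves * voices
  periods <- switch(spacing,
    log = base_period * 2^((seq_len(n) - 1) / voices),
    linear = base_period * seq_len(n)
  )
  structure(list(periods = periods, octaves = octaves, voices = voices,
                 base_period = base_period, spacing = spacing),
            class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf("<scale_grid> %d periods (%s): %.2f .. %.2f s\n",
              length(x$periods), x$spacing, min(x$periods), max(x$periods)))
  invisible(x)
}

# Fourier transform of the analytic complex-Gaussian (derivative-of-Gaussian)
# wavelet of order n, evaluated at angular frequency w (vectorised):
# psi_hat(w) = w^n * exp(-(w - 1)^2 / 4) for w > 0, 0 otherwise.
# Its modulus peaks at w_peak = (1 + sqrt(1 + 8 n)) / 2 (= 3 for n = 3),
# which fixes the scale <-> period mapping.
cgau_hat <- function(w, order) {
  out <- numeric(length(w))
  pos <- w > 0
  out[pos] <- w[pos]^order * exp(-(w[pos] - 1)^2 / 4)
  out
}

cgau_peak <- function(order) (1 + sqrt(1 + 8 * order)) / 2

#' Continuous wavelet transform with a complex-Gaussian wavelet
#'
#' FFT-based CWT: the signal spectrum is multiplied per scale by the
#' conjugate wavelet spectrum and inverse-transformed. The wavelet is the
#' analytic complex-Gaussian (derivative-of-Gaussian) family of configurable
#' order (default 3); scales are mapped from the grid periods through the
#' wavelet's spectral peak so a sinusoid of period p maximises the modulus
#' at the grid period nearest p.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param grid a [build_scale_grid()].
#' @param order wavelet order (1-8).
#' @return Complex matrix, periods x samples, with the grid attached as an
#'   attribute.
#' @export
cwt_cgau <- function(x, rate, grid = build_scale_grid(), order = 3) {
  stopifnot(inherits(grid, "scale_grid"))
  if (any(!is.finite(x))) abort("signal must be finite.")
  if (!order %in% 1:8) abort("wavelet order must be an integer in 1..8.")
  n <- length(x)
  if (min(grid$periods) * rate < 2) {
    abort("shortest grid period is below 2 samples at this rate.")
  }
  wk <- 2 * pi * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n  # rad/sample
  xh <- fft(x)
  wpk <- cgau_peak(order)
  out <- matrix(0 + 0i, length(grid$periods), n)
  for (k in seq_along(grid$periods)) {
    s <- wpk * grid$periods[k] * rate / (2 * pi)   # scale in samples
    psi <- cgau_hat(s * wk, order) * sqrt(s)
    out[k, ] <- fft(xh * psi, inverse = TRUE) / n
  }
  attr(out, "grid") <- grid
  attr(out, "rate") <- rate
  out
}

#' Magnitude-squared wavelet coherence of two series
#'
#' `MSC = |S(Wx conj(Wy))|^2 / (S(|Wx|^2) S(|Wy|^2))`, where S is a
#' scale-proportional moving-average smoother in time whose window spans
#' `smooth_periods` wavelet periods at each scale (no cross-scale
#' smoothing). Without smoothing the ratio is identically 1 for any pair,
#' so the smoother is essential and applied by default; the default window
#' of 3 periods keeps the window longer than the decorrelation time of
#' signals whose bandwidth is of the order of the analysed frequency, which
#' a 1-period window cannot resolve (independent narrowband signals would
#' look perfectly coherent). Values are clipped to \[0, 1\].
#'
#' @param x,y equal-length numeric series at the same rate.
#' @param rate sampling rate in Hz.
#' @param grid a [build_scale_grid()].
#' @param order complex-Gaussian wavelet order.
#' @param smooth_periods smoothing window length in wavelet periods.
#' @return A list of class `wtc`: `msc` (periods x samples in \[0, 1\], all
#'   NA when either input has zero variance), `periods`, `rate`,
#'   `undefined` flag.
#' @export
wavelet_coherence <- function(x, y, rate, grid = build_scale_grid(),
                              order = 3, smooth_periods = 3) {
  if (length(x) != length(y)) abort("series must have equal length.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(list(
      msc = matrix(NA_real_, length(grid$periods), length(x)),
      periods = grid$periods, rate = rate, undefined = TRUE
    ), class = "wtc"))
  }
  wx <- cwt_cgau(x, rate, grid, order)
  wy <- cwt_cgau(y, rate, grid, order)
  msc <- matrix(0, length(grid$periods), length(x))
  for (k in seq_along(grid$periods)) {
    w <- max(1L, round(smooth_periods * grid$periods[k] * rate))
    cross <- wx[k, ] * Conj(wy[k, ])
    sxy <- complex(real = moving_average(Re(cross), w),
                   imaginary = moving_average(Im(cross), w))
    sxx <- moving_average(Mod(wx[k, ])^2, w)
    syy <- moving_average(Mod(wy[k, ])^2, w)
    msc[k, ] <- pmin(pmax(Mod(sxy)^2 / (sxx * syy), 0), 1)
  }
  structure(list(msc = msc, periods = grid$periods, rate = rate,
                 undefined = FALSE),
            class = "wtc")
}

#' @export
print.wtc <- function(x, ...) {
  if (x$undefined) {
    cat("<wtc> undefined (zero-variance input)\n")
  } else {
    cat(sprintf("<wtc> %d periods x %d samples; mean MSC %.3f\n",
                nrow(x$msc), ncol(x$msc), mean(x$msc)))
  }
  invisible(x)
}

#' @export
tidy.wtc <- function(x, ...) {
  tibble(
    period_s = rep(x$periods, times = ncol(x$msc)),
    time_s = rep((seq_len(ncol(x$msc)) - 1) / x$rate, each = nrow(x$msc)),
    msc = as.vector(x$msc)
  )
}
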