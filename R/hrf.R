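#' Canonical double-gamma haemodynamic response function
#'
#' The standard canonical HRF: a gamma-density response peaking near 6 s
#' minus a scaled gamma-density undershoot peaking near 16 s, sampled at
#' `sampling_rate` over `length_s` seconds and normalised to unit peak.
#' Defaults are the conventional values: peak delay 6 s, undershoot delay
#' 16 s, dispersions 1 s, peak:undershoot ratio 6, kernel length 32 s.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param peak_delay,undershoot_delay gamma means in s.
#' @param peak_disp,undershoot_disp gamma dispersions in s.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length_s kernel support in s.
#'
#' @return Numeric vector of kernel samples starting at t = 0.
#' @export
#' @examples
#' h <- canonical_hrf(8.13)
#' (which.max(h) - 1) / 8.13  # peak near 6 s
canonical_hrf <- function(sampling_rate, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, ratio = 6, length_s = 32) {
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  t <- seq(0, length_s, by = 1 / sampling_rate)
  # gamma densities with mode = delay: shape = 1 + delay/disp, scale = disp
  h <- stats::dgamma(t, shape = 1 + peak_delay / peak_disp,
                     scale = peak_disp) -
    stats::dgamma(t, shape = 1 + undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / ratio
  h / max(h)
}

#' Build a GLM design matrix from a paradigm
#'
#' One regressor per task condition: the indicator of that condition's task
#' blocks convolved with the canonical HRF and truncated to the run length,
#' plus an intercept column. Rest is modelled implicitly.
#'
#' @param paradigm a paradigm/event tibble (see [generate_paradigm()]).
#' @param rate sampling rate of the data in Hz.
#' @param hrf HRF kernel sampled at `rate`; defaults to [canonical_hrf()].
#' @param n_samples number of data samples; defaults to the paradigm
#'   duration times `rate`.
#'
#' @return A numeric matrix (samples x regressors) with named columns, the
#'   last one `"(Intercept)"`; class `fnirs_design` with the rate attached.
#' @export
build_design <- function(paradigm, rate, hrf = canonical_hrf(rate),
                         n_samples = NULL) {
  if (nrow(paradigm) == 0) abort("empty paradigm.")
  if (is.null(n_samples)) {
    n_samples <- as.integer(round(paradigm_duration(paradigm) * rate))
  }
  conditions <- setdiff(unique(paradigm$condition), "rest")
  cols <- lapply(conditions, function(cond) {
    box <- condition_boxcar(paradigm, cond, n_samples, rate)
    # divide by rate so the discrete convolution approximates the
    # continuous-time integral: regressors are then rate-invariant and the
    # two sites' betas share a scale
    convolve(box, rev(hrf), type = "open")[seq_len(n_samples)] / rate
  })
  X <- cbind(
    if (length(cols)) do.call(cbind, cols) else NULL,
    rep(1, n_samples)
  )
  colnames(X) <- c(conditions, "(Intercept)")
  structure(X, sampling_rate = rate, class = c("fnirs_design", "matrix", "array"))
}
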