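#' Channel quality control
#'
#' Flags channels with poor scalp coupling by four rules and reports the
#' union as excluded:
#' * `mirrored` — HbO2 and HHb perfectly anticorrelated
#'   (corr < `mirror_threshold`, default -0.98);
#' * `saturated` — raw intensity pinned at the dynamic-range ceiling for
#'   more than `saturation_frac` of samples;
#' * `no_heartbeat` — raw-intensity spectral power in the cardiac band
#'   (0.8-1.2 Hz) below `heartbeat_ratio` times the neighbouring-band power;
#' * `high_rms` — raw-intensity RMS (about the channel mean) more than
#'   `rms_factor` (default 10) times the RMS of the across-channel average
#'   signal.
#'
#' @param raw the [fnirs_raw()] recording.
#' @param hb the matching [hb_series()] (same channels).
#' @param mirror_threshold HbO2/HHb correlation below which a channel is
#'   mirrored.
#' @param saturation_frac tolerated fraction of ceiling-valued samples.
#' @param heartbeat_band cardiac band in Hz.
#' @param heartbeat_ratio minimum cardiac-to-neighbour band power ratio.
#' @param rms_factor multiple of the average-signal RMS above which a
#'   channel is rejected.
#'
#' @return A list of class `qc_report`: `flags` (tibble with one row per
#'   channel and logical columns `mirrored`, `saturated`, `no_heartbeat`,
#'   `high_rms`, `excluded`) and `fraction_excluded`.
#' @export
qc_exclude_channels <- function(raw, hb, mirror_threshold = -0.98,
                                saturation_frac = 0.01,
                                heartbeat_band = c(0.8, 1.2),
                                heartbeat_ratio = 0.25, rms_factor = 10) {
  stopifnot(inherits(raw, "fnirs_raw"), inherits(hb, "hb_series"))
  n_ch <- dim(raw$data)[1]
  if (nrow(hb$hbo2) != n_ch) abort("raw and hb channel counts differ.")
  rate <- raw$sampling_rate
  # work from the middle wavelength (isosbestic) for intensity-based rules
  inten <- raw$data[, , 2]
  if (n_ch == 1) inten <- matrix(inten, nrow = 1)

  mirrored <- vapply(seq_len(n_ch), function(ch) {
    if (sd(hb$hbo2[ch, ]) == 0 || sd(hb$hhb[ch, ]) == 0) return(FALSE)
    stats::cor(hb$hbo2[ch, ], hb$hhb[ch, ]) < mirror_threshold
  }, logical(1))

  ceiling_val <- max(raw$data)
  saturated <- vapply(seq_len(n_ch), function(ch) {
    mean(raw$data[ch, , ] >= ceiling_val * (1 - 1e-9)) > saturation_frac
  }, logical(1))

  no_heartbeat <- vapply(seq_len(n_ch), function(ch) {
    !has_heartbeat(inten[ch, ], rate, heartbeat_band, heartbeat_ratio)
  }, logical(1))

  avg_sig <- colMeans(inten)
  rms <- function(x) sqrt(mean((x - mean(x))^2))
  avg_rms <- rms(avg_sig)
  high_rms <- vapply(seq_len(n_ch), function(ch) {
    rms(inten[ch, ]) > rms_factor * avg_rms
  }, logical(1))

  flags <- tibble(
    channel = seq_len(n_ch),
    mirrored = mirrored, saturated = saturated,
    no_heartbeat = no_heartbeat, high_rms = high_rms
  ) %>%
    mutate(excluded = .data$mirrored | .data$saturated |
             .data$no_heartbeat | .data$high_rms)
  structure(list(flags = flags,
                 fraction_excluded = mean(flags$excluded)),
            class = "qc_report")
}

# cardiac-band power vs neighbouring bands on the raw periodogram
has_heartbeat <- function(x, rate, band = c(0.8, 1.2), ratio = 0.25) {
  if (rate / 2 <= band[2]) return(TRUE)   # cardiac band unresolvable: pass
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) / n * rate
  keep <- f <= rate / 2
  p <- p[keep]; f <- f[keep]
  inband <- f >= band[1] & f <= band[2]
  width <- band[2] - band[1]
  neigh <- (f >= band[1] - width & f < band[1]) |
    (f > band[2] & f <= min(band[2] + width, rate / 2))
  if (!any(inband) || !any(neigh)) return(TRUE)
  mean(p[inband]) > ratio * mean(p[neigh])
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d channels excluded (%.1f%%)\n",
              sum(x$flags$excluded), nrow(x$flags),
              100 * x$fraction_excluded))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) x$flags

#' @export
glance.qc_report <- function(x, ...) {
  tibble(n_channels = nrow(x$flags),
         n_excluded = sum(x$flags$excluded),
         fraction_excluded = x$fraction_excluded)
}

#' Apply a QC report to a haemoglobin series
#'
#' Marks excluded channels in the series' channel mask.
#'
#' @param hb an [hb_series()].
#' @param qc a `qc_report`.
#' @return The series with its `channel_mask` updated.
#' @export
apply_qc <- function(hb, qc) {
  stopifnot(inherits(hb, "hb_series"), inherits(qc, "qc_report"))
  hb$channel_mask <- hb$channel_mask & !qc$flags$excluded
  hb
}
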