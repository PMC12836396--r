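#' Raw optical intensity container
#'
#' Bundles a channels x samples x wavelength intensity array with its
#' acquisition metadata. Intensities are strictly positive arbitrary units;
#' exactly three wavelengths (780, 805, 830 nm) are carried, matching
#' continuous-wave systems that resolve oxy- and deoxyhaemoglobin by
#' multi-wavelength attenuation.
#'
#' @param data numeric array, channels x samples x 3, all values > 0.
#' @param sampling_rate sampling rate in Hz.
#' @param site_id site label, e.g. `"UK"` or `"US"`.
#' @param wavelengths wavelengths in nm, length 3.
#'
#' @return An object of class `fnirs_raw`.
#' @export
fnirs_raw <- function(data, sampling_rate, site_id = "unknown",
                      wavelengths = c(780, 805, 830)) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3-d array (channels x samples x wavelengths).")
  }
  if (dim(data)[3] != 3L || length(wavelengths) != 3L) {
    abort("exactly 3 wavelengths are required.")
  }
  if (any(!is.finite(data)) || any(data <= 0)) {
    abort("intensities must be finite and strictly positive.")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a positive number.")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate, site_id = site_id,
         wavelengths = wavelengths),
    class = "fnirs_raw"
  )
}

#' @export
print.fnirs_raw <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fnirs_raw> site %s: %d channels x %d samples x %d wavelengths @ %.2f Hz\n",
              x$site_id, d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}

#' @export
dim.fnirs_raw <- function(x) dim(x$data)

#' Haemoglobin concentration series container
#'
#' Holds oxyhaemoglobin (HbO2) and deoxyhaemoglobin (HHb) concentration-change
#' series as channels x samples matrices, plus a per-channel inclusion mask.
#' The difference signal HbDiff = HbO2 - HHb is always available through
#' [hbdiff()] and is recomputed on demand so the identity holds after every
#' operation.
#'
#' @param hbo2,hhb numeric matrices, channels x samples, equal dimensions.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_mask logical vector, `TRUE` = channel included. Defaults to
#'   all included.
#' @param site_id site label carried through from the raw recording.
#'
#' @return An object of class `hb_series`.
#' @export
hb_series <- function(hbo2, hhb, sampling_rate, channel_mask = NULL,
                      site_id = "unknown") {
  hbo2 <- as.matrix(hbo2); hhb <- as.matrix(hhb)
  if (!identical(dim(hbo2), dim(hhb))) {
    abort("`hbo2` and `hhb` must have identical dimensions.")
  }
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, nrow(hbo2))
  if (length(channel_mask) != nrow(hbo2)) {
    abort("`channel_mask` length must equal the channel count.")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a positive number.")
  }
  structure(
    list(hbo2 = hbo2, hhb = hhb, sampling_rate = sampling_rate,
         channel_mask = as.logical(channel_mask), site_id = site_id),
    class = "hb_series"
  )
}

#' Difference signal HbDiff = HbO2 - HHb
#'
#' @param hb an [hb_series()].
#' @return channels x samples matrix of HbDiff.
#' @export
hbdiff <- function(hb) {
  stopifnot(inherits(hb, "hb_series"))
  hb$hbo2 - hb$hhb
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("<hb_series> site %s: %d channels x %d samples @ %.2f Hz (%d excluded)\n",
              x$site_id, nrow(x$hbo2), ncol(x$hbo2), x$sampling_rate,
              sum(!x$channel_mask)))
  invisible(x)
}

#' @export
dim.hb_series <- function(x) dim(x$hbo2)

#' Tidy a haemoglobin series into long format
#'
#' @param x an [hb_series()].
#' @param ... unused.
#' @return A tibble with columns `channel`, `time_s`, `hbo2`, `hhb`, `hbdiff`.
#' @export
tidy.hb_series <- function(x, ...) {
  n_ch <- nrow(x$hbo2); n_t <- ncol(x$hbo2)
  tibble(
    channel = rep(seq_len(n_ch), times = n_t),
    time_s = rep((seq_len(n_t) - 1) / x$sampling_rate, each = n_ch),
    hbo2 = as.vector(x$hbo2),
    hhb = as.vector(x$hhb)
  ) %>% mutate(hbdiff = .data$hbo2 - .data$hhb)
}

# internal: apply a samples-dimension transform to both chromophores
map_chromophores <- function(hb, f, new_rate = hb$sampling_rate) {
  hb_series(
    hbo2 = f(hb$hbo2), hhb = f(hb$hhb),
    sampling_rate = new_rate, channel_mask = hb$channel_mask,
    site_id = hb$site_id
  )
}
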