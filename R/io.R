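#' Run configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the analysis conventions used throughout the package: 0.01-0.2 Hz
#' 4th-order band-pass, co-localisation `sigma = 0.01` (mm^-2,
#' `exp(-sigma d^2)` form), one global component removed, canonical HRF,
#' complex-Gaussian wavelet order 3, 4 octaves x 4 voices from 2.5 s
#' (logarithmic), three-period coherence smoothing window, 20 shuffled
#' pairs, FDR q = 0.05, common analysis rate 8.13 Hz.
#'
#' @param ... named overrides of any default.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    filter_low = 0.01, filter_high = 0.2, filter_order = 4,
    target_rate = 8.13,
    sigma = 0.01, kernel_form = "sigma_times_d2",
    gmr_components = 1,
    dpf = c(6, 6, 6),
    hrf = list(peak_delay = 6, undershoot_delay = 16, peak_disp = 1,
               undershoot_disp = 1, ratio = 6, length_s = 32),
    wavelet_order = 3,
    grid = list(octaves = 4, voices = 4, base_period = 2.5, spacing = "log"),
    smooth_periods = 3,
    n_shuffled = 20,
    fdr_q = 0.05,
    coherence_roi = "angular_gyrus",
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, dots)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (cfg$filter_high <= cfg$filter_low) {
    abort("`filter_high` must exceed `filter_low`.")
  }
  if (cfg$filter_low <= 0 || cfg$filter_high >= cfg$target_rate / 2) {
    abort("filter cut-offs must lie inside (0, Nyquist).")
  }
  if (cfg$sigma <= 0) abort("`sigma` must be positive.")
  invisible(cfg)
}

#' Write / read a run configuration (lossless JSON round trip)
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `write_config` the path invisibly; `read_config` the config.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Write a recording to a directory
#'
#' Primary on-disk format: one delimited channels x samples matrix per
#' wavelength (raw intensities) or per chromophore (concentration series),
#' plus a JSON metadata sidecar (`meta.json`) carrying type, site, rate and
#' wavelengths.
#'
#' @param x an [fnirs_raw()] or [hb_series()].
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, f) {
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(path, f), sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  if (inherits(x, "fnirs_raw")) {
    for (w in 1:3) {
      write_mat(x$data[, , w], sprintf("intensity_%d.csv", x$wavelengths[w]))
    }
    meta <- list(type = "raw_intensity", site_id = x$site_id,
                 sampling_rate = x$sampling_rate,
                 wavelengths = x$wavelengths,
                 n_channels = dim(x$data)[1], n_samples = dim(x$data)[2])
  } else if (inherits(x, "hb_series")) {
    write_mat(x$hbo2, "hbo2.csv")
    write_mat(x$hhb, "hhb.csv")
    meta <- list(type = "hb_series", site_id = x$site_id,
                 sampling_rate = x$sampling_rate,
                 n_channels = nrow(x$hbo2), n_samples = ncol(x$hbo2),
                 channel_mask = x$channel_mask)
  } else {
    abort("`x` must be an fnirs_raw or hb_series object.")
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path recording directory.
#' @return An [fnirs_raw()] or [hb_series()], per the sidecar type.
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) abort(sprintf("no meta.json under '%s'.", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  read_mat <- function(f) {
    m <- as.matrix(utils::read.table(file.path(path, f), sep = ",",
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    if (any(is.na(m))) abort(sprintf("NaN/NA cells in %s.", f))
    m
  }
  if (identical(meta$type, "raw_intensity")) {
    if (length(meta$wavelengths) != 3) {
      abort(sprintf("wavelength count is %d, expected 3.",
                    length(meta$wavelengths)))
    }
    mats <- lapply(meta$wavelengths, function(wl) {
      read_mat(sprintf("intensity_%d.csv", wl))
    })
    data <- array(0, dim = c(meta$n_channels, meta$n_samples, 3))
    for (w in 1:3) data[, , w] <- mats[[w]]
    fnirs_raw(data, meta$sampling_rate, meta$site_id, meta$wavelengths)
  } else if (identical(meta$type, "hb_series")) {
    hb_series(read_mat("hbo2.csv"), read_mat("hhb.csv"),
              meta$sampling_rate, channel_mask = meta$channel_mask,
              site_id = meta$site_id)
  } else {
    abort(sprintf("unknown recording type '%s'.", meta$type))
  }
}

#' Write / read an events table (TSV)
#'
#' Columns `onset`, `duration`, `condition` (and `run` when present).
#' Reading validates ordering and non-overlap, naming offending rows.
#'
#' @param events event tibble.
#' @param path file path.
#' @return `write_events` the path; `read_events` the validated tibble.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(as_tibble(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  validate_paradigm(ev)
  ev
}

#' Write / read channel geometry (CSV)
#'
#' Columns `channel`, `x`, `y`, `z` (MNI mm), `separation_cm`, `site_id`.
#'
#' @param geometry geometry tibble.
#' @param path file path.
#' @return `write_geometry` the path; `read_geometry` the tibble.
#' @export
write_geometry <- function(geometry, path) {
  readr::write_csv(geometry, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE)
  if (any(!is.finite(g$x + g$y + g$z))) abort("non-finite coordinates.")
  g
}

#' Export a co-localisation kernel for audit
#'
#' @param kernel a `coloc_kernel`.
#' @param path file path (delimited matrix, input x mask).
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  utils::write.table(kernel$weights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
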