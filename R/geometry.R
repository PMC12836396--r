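#' Site acquisition configuration
#'
#' Describes one laboratory's recording setup. The two packaged montages
#' mirror a dual-site LABNIRS arrangement: a US site with 134 channels
#' covering the whole head sampled at 8.13 Hz, and a UK site with 88 channels
#' over bilateral temporal, parietal and occipital cortex sampled at
#' 12.34 Hz. Source-detector separation defaults to 3 cm.
#'
#' @param site_id `"UK"` or `"US"` for the packaged montages; any label is
#'   accepted when the remaining fields are given explicitly.
#' @param n_channels number of measurement channels.
#' @param sampling_rate acquisition rate in Hz.
#' @param sd_separation source-detector separation in cm.
#'
#' @return A list of class `site_config`.
#' @export
#' @examples
#' site_config("UK")
#' site_config("US")
site_config <- function(site_id, n_channels = NULL, sampling_rate = NULL,
                        sd_separation = NULL) {
  defaults <- list(
    UK = list(n_channels = 88L, sampling_rate = 12.34, sd_separation = 3),
    US = list(n_channels = 134L, sampling_rate = 8.13, sd_separation = 3)
  )
  if (is.null(n_channels) || is.null(sampling_rate) || is.null(sd_separation)) {
    if (!site_id %in% names(defaults)) {
      abort(sprintf("unknown site label '%s'; supply n_channels, sampling_rate and sd_separation explicitly.", site_id))
    }
    d <- defaults[[site_id]]
    n_channels <- n_channels %||% d$n_channels
    sampling_rate <- sampling_rate %||% d$sampling_rate
    sd_separation <- sd_separation %||% d$sd_separation
  }
  if (n_channels < 1 || sampling_rate <= 0 || sd_separation <= 0) {
    abort("n_channels, sampling_rate and sd_separation must be positive.")
  }
  structure(list(site_id = site_id, n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, sd_separation = sd_separation),
            class = "site_config")
}

#' Generate a scalp-shell channel geometry for a site
#'
#' Places `n_channels` channel positions on a scalp-like spherical shell of
#' radius 90 mm in MNI-style coordinates (x right, y anterior, z superior,
#' origin near the centre of the head). The US montage covers the whole upper
#' head; the UK montage covers bilateral temporal, parietal and occipital
#' regions (posterior/lateral cap, sparing the frontal pole). Positions are
#' quasi-uniform (Fibonacci lattice over the covered cap) with a small seeded
#' jitter, and are deterministic for a given seed.
#'
#' @param site a [site_config()].
#' @param seed integer seed controlling the jitter.
#' @param radius_mm shell radius in mm.
#' @param jitter_mm standard deviation of the tangential jitter in mm.
#'
#' @return A tibble with columns `channel`, `x`, `y`, `z` (MNI mm),
#'   `separation_cm`, `site_id`.
#' @export
#' @examples
#' geom <- generate_geometry(site_config("UK"), seed = 1)
#' nrow(geom)  # 88
generate_geometry <- function(site, seed = 1L, radius_mm = 90,
                              jitter_mm = 1.5) {
  stopifnot(inherits(site, "site_config"))
  n <- site$n_channels
  # Fibonacci lattice over a spherical cap. Whole-head coverage uses the cap
  # above z/r = -0.15; the posterior montage drops anterior-superior points.
  golden <- (1 + sqrt(5)) / 2
  if (identical(site$site_id, "UK")) {
    # oversample the cap, then keep the posterior/lateral subset
    m <- ceiling(n * 2.2)
    k <- seq_len(m) - 0.5
    zfrac <- 1 - (k / m) * 1.15            # z/r in (-0.15, 1)
    theta <- 2 * pi * k / golden
    pts <- cbind(
      x = sqrt(pmax(0, 1 - zfrac^2)) * cos(theta),
      y = sqrt(pmax(0, 1 - zfrac^2)) * sin(theta),
      z = zfrac
    )
    keep <- which(pts[, "y"] < 0.35 & !(pts[, "z"] > 0.85 & pts[, "y"] > 0))
    if (length(keep) < n) keep <- order(pts[, "y"])[seq_len(n)]
    pts <- pts[keep[seq_len(n)], , drop = FALSE]
  } else {
    k <- seq_len(n) - 0.5
    zfrac <- 1 - (k / n) * 1.15
    theta <- 2 * pi * k / golden
    pts <- cbind(
      x = sqrt(pmax(0, 1 - zfrac^2)) * cos(theta),
      y = sqrt(pmax(0, 1 - zfrac^2)) * sin(theta),
      z = zfrac
    )
  }
  pts <- pts * radius_mm
  with_seed(seed, {
    jit <- matrix(rnorm(3 * n, sd = jitter_mm), ncol = 3)
    pts <- pts + jit
    # re-project onto the shell so every channel sits on the scalp surface
    r <- sqrt(rowSums(pts^2))
    pts <- pts / r * radius_mm
  })
  tibble(
    channel = seq_len(n),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    separation_cm = site$sd_separation,
    site_id = site$site_id
  )
}
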