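#' Ground-truth parameter set for the dyad simulator
#'
#' Collects every generative parameter so downstream recovery can be checked
#' against known values. Defaults describe a realistic clean recording:
#' task amplitude 1 concentration a.u., heartbeat near 1 Hz, a channel-common
#' low-frequency systemic component, white channel noise, and (optionally) a
#' band-limited coupling component shared between partners during live
#' blocks.
#'
#' @param task_amplitude task response amplitude per condition; a named
#'   vector (e.g. `c(live = 1, static = 1)`) or a single number applied to
#'   all task conditions (HbO2 units; HHb responds with `-hhb_ratio` times
#'   the HbO2 response).
#' @param coupling_amplitude amplitude (a.u.) of the shared band-limited
#'   component added to both partners during live blocks; 0 disables it.
#' @param coupling_period centre period of the coupling component in s.
#' @param heartbeat_freq cardiac frequency in Hz (~1 Hz physiologically).
#' @param heartbeat_amplitude cardiac amplitude in concentration a.u.
#' @param systemic_amplitude amplitude of the channel-common systemic drift.
#' @param noise_sd standard deviation of white channel noise.
#' @param hhb_ratio magnitude of the HHb task response relative to HbO2
#'   (HHb decreases while HbO2 increases).
#' @param seed integer seed; every random component derives from it.
#'
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(task_amplitude = 1, coupling_amplitude = 0,
                         coupling_period = 20, heartbeat_freq = 1.0,
                         heartbeat_amplitude = 0.02,
                         systemic_amplitude = 0.5, noise_sd = 0.1,
                         hhb_ratio = 1 / 3, seed = 1L) {
  stopifnot(all(task_amplitude >= 0), coupling_amplitude >= 0,
            coupling_period > 0, heartbeat_freq > 0, noise_sd >= 0)
  structure(
    list(task_amplitude = task_amplitude,
         coupling_amplitude = coupling_amplitude,
         coupling_period = coupling_period,
         heartbeat_freq = heartbeat_freq,
         heartbeat_amplitude = heartbeat_amplitude,
         systemic_amplitude = systemic_amplitude,
         noise_sd = noise_sd, hhb_ratio = hhb_ratio,
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Band-limited unit-variance Gaussian process
#'
#' White Gaussian noise band-pass filtered around `1/period` (passband
#' `(1 +/- band_halfwidth)` times the centre frequency, 2nd-order
#' Butterworth applied zero-phase) and rescaled to unit standard deviation.
#' This is the shared "coupling" component injected into both partners of a
#' simulated dyad. The default half-width of 0.5 gives a bandwidth equal to
#' the centre frequency, so the process decorrelates over about one period
#' — a coupling signal the scale-matched coherence smoother can resolve.
#'
#' @param n_samples length of the series.
#' @param rate sampling rate in Hz.
#' @param period centre period in s.
#' @param seed integer seed.
#' @param band_halfwidth passband half-width as a fraction of the centre
#'   frequency.
#' @return Numeric vector of length `n_samples`, sd 1, mean ~0.
#' @export
simulate_coupled_series <- function(n_samples, rate, period, seed,
                                    band_halfwidth = 0.5) {
  f0 <- 1 / period
  ny <- rate / 2
  lo <- max((1 - band_halfwidth) * f0 / ny, 1e-6)
  hi <- min((1 + band_halfwidth) * f0 / ny, 0.999)
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  with_seed(seed, {
    w <- rnorm(n_samples + 4 * round(rate * period))
    x <- signal::filtfilt(bf, w)
    x <- x[seq.int(2 * round(rate * period) + 1, length.out = n_samples)]
    x <- x - mean(x)
    x / sd(x)
  })
}

#' Coupling amplitude that yields a target true coherence
#'
#' For residual series `a * c + noise`, with `c` the unit-variance coupling
#' process spread over a passband of width `2 * band_halfwidth / period` Hz
#' and white noise of standard deviation `noise_sd`, the magnitude-squared
#' coherence at the coupling band is `(Sc / (Sc + Sn))^2` with band power
#' densities `Sc = a^2 / bw` and `Sn = 2 * noise_sd^2 / rate` (one-sided).
#' Solving for `a` gives the closed-form amplitude for a target coherence.
#'
#' @param target_msc target magnitude-squared coherence in (0, 1).
#' @param noise_sd white-noise standard deviation of the residual series.
#' @param rate sampling rate in Hz.
#' @param period coupling centre period in s.
#' @param band_halfwidth passband half-width fraction, matching
#'   [simulate_coupled_series()].
#' @return amplitude `a` (same units as the series).
#' @export
coupling_amplitude_for_msc <- function(target_msc, noise_sd, rate, period,
                                       band_halfwidth = 0.5) {
  stopifnot(target_msc > 0, target_msc < 1)
  r <- sqrt(target_msc)                   # Sc / (Sc + Sn)
  bw <- 2 * band_halfwidth / period       # passband width in Hz
  sn <- 2 * noise_sd^2 / rate             # one-sided white-noise PSD
  sc <- sn * r / (1 - r)
  sqrt(sc * bw)
}

#' Simulate one dyad's ROI residual series
#'
#' Generates the pair of residual-like ROI series the coherence stage
#' consumes, without the full optical forward model: white noise per
#' partner plus, when `coupling_amplitude > 0`, a shared band-limited
#' coupling component gated to the runs of `coupling_condition`. This is
#' the lightweight generator used for calibration studies of the
#' coherence/ANOVA stage (null rejection rate, power), where hundreds of
#' replicates are needed.
#'
#' @param paradigm a [generate_paradigm()] table.
#' @param rate sampling rate in Hz.
#' @param coupling_amplitude shared-component amplitude (a.u.).
#' @param coupling_period centre period in s.
#' @param noise_sd white-noise standard deviation.
#' @param seed integer seed.
#' @param coupling_condition condition whose runs carry the coupling.
#' @return A list with numeric vectors `a` and `b`.
#' @export
simulate_residual_pair <- function(paradigm, rate, coupling_amplitude = 0,
                                   coupling_period = 20, noise_sd = 1,
                                   seed = 1L,
                                   coupling_condition = "live") {
  n <- as.integer(round(paradigm_duration(paradigm) * rate))
  out <- with_seed(child_seed(seed, 11L), {
    list(a = rnorm(n, sd = noise_sd), b = rnorm(n, sd = noise_sd))
  })
  if (coupling_amplitude > 0) {
    cpl <- simulate_coupled_series(n, rate, coupling_period,
                                   seed = child_seed(seed, 12L))
    gate <- condition_run_gate(paradigm, coupling_condition, n, rate)
    shared <- coupling_amplitude * cpl * gate
    out$a <- out$a + shared
    out$b <- out$b + shared
  }
  out
}

# condition-run gate: 0/1 indicator of samples inside the runs of one
# condition (the whole 2 min run, not just its task blocks — spontaneous
# coupling is not task-locked), with short raised-cosine ramps so the gated
# coupling stays near-band-limited.
condition_run_gate <- function(paradigm, condition, n_samples, rate,
                               ramp_s = 2) {
  t <- (seq_len(n_samples) - 1) / rate
  g <- numeric(n_samples)
  runs <- paradigm %>%
    group_by(.data$run) %>%
    summarise(start = min(.data$onset),
              end = max(.data$onset + .data$duration),
              condition = setdiff(unique(.data$condition), "rest")[1],
              .groups = "drop")
  for (i in which(runs$condition == condition)) {
    g[t >= runs$start[i] & t < runs$end[i]] <- 1
  }
  w <- max(1L, round(ramp_s * rate))
  k <- (1 - cos(pi * seq_len(w) / w)) / 2
  kern <- c(k, rev(k)); kern <- kern / sum(kern)
  as.numeric(stats::filter(c(rep(g[1], length(kern)), g,
                             rep(g[length(g)], length(kern))),
                           kern, sides = 2))[seq_along(g) + length(kern)]
}

# concentration field for one participant (channels x samples matrices)
simulate_concentrations <- function(geometry, paradigm, truth, rate,
                                    coupling, participant_seed,
                                    coupling_channels = NULL) {
  n_ch <- nrow(geometry)
  n_t <- as.integer(round(paradigm_duration(paradigm) * rate))
  t <- (seq_len(n_t) - 1) / rate
  hrf <- canonical_hrf(rate)

  conditions <- setdiff(unique(paradigm$condition), "rest")
  amp <- truth$task_amplitude
  if (is.null(names(amp))) amp <- setNames(rep(amp[1], length(conditions)), conditions)

  task <- numeric(n_t)
  for (cond in conditions) {
    box <- condition_boxcar(paradigm, cond, n_t, rate)
    # rate-normalised convolution, matching build_design(), so the generated
    # amplitude is the beta the GLM recovers
    task <- task + amp[[cond]] *
      convolve(box, rev(hrf), type = "open")[seq_len(n_t)] / rate
  }

  with_seed(participant_seed, {
    ch_gain <- pmax(0.25, rnorm(n_ch, mean = 1, sd = 0.2))   # per-channel amplitude
    phase <- stats::runif(n_ch, 0, 2 * pi)
    # channel-common systemic drift: slow random walk, smoothed
    drift <- cumsum(rnorm(n_t, sd = 1))
    drift <- moving_average(drift, max(3L, round(10 * rate)))
    drift <- truth$systemic_amplitude * (drift - mean(drift)) / max(sd(drift), 1e-12)
    noise_o <- matrix(rnorm(n_ch * n_t, sd = truth$noise_sd), n_ch, n_t)
    noise_h <- matrix(rnorm(n_ch * n_t, sd = truth$noise_sd), n_ch, n_t)
  })

  heart <- truth$heartbeat_amplitude *
    outer(phase, t, function(p, tt) sin(2 * pi * truth$heartbeat_freq * tt + p))

  hbo2 <- outer(ch_gain, task) + heart +
    matrix(drift, n_ch, n_t, byrow = TRUE) + noise_o
  hhb <- -truth$hhb_ratio * outer(ch_gain, task) - 0.5 * heart +
    0.5 * matrix(drift, n_ch, n_t, byrow = TRUE) + noise_h

  if (!is.null(coupling)) {
    idx <- coupling_channels %||% seq_len(n_ch)
    add <- matrix(coupling, length(idx), n_t, byrow = TRUE)
    hbo2[idx, ] <- hbo2[idx, ] + add
    hhb[idx, ] <- hhb[idx, ] + add
  }
  list(hbo2 = hbo2, hhb = hhb, ch_gain = ch_gain)
}

#' Simulate a two-site dyad recording
#'
#' Generates both partners' raw three-wavelength intensity recordings from a
#' known concentration-space forward model: HRF-convolved task boxcars with
#' per-channel amplitudes, a ~1 Hz heartbeat, a channel-common systemic
#' drift, white channel noise and, when `truth$coupling_amplitude > 0`, a
#' band-limited coupling component identical in both partners (gated to live
#' blocks). Concentrations are mapped to intensities by inverting the
#' modified Beer-Lambert law, so [mbll_convert()] recovers them.
#'
#' @param geom_a,geom_b channel geometries of the two partners (see
#'   [generate_geometry()]).
#' @param paradigm a shared paradigm (see [generate_paradigm()]).
#' @param truth a [ground_truth()] parameter set.
#' @param rate_a,rate_b per-partner sampling rates in Hz; defaults 12.34 (UK)
#'   and 8.13 (US) keyed on the geometry's `site_id`.
#' @param coupling_condition task condition carrying the coupling component.
#' @param coupling_channels_a,coupling_channels_b channel indices receiving
#'   the coupling component; default all channels.
#' @param dpf,extinction forward-model optics passed to [mbll_intensity()].
#'
#' @return A list with elements `raw_a`, `raw_b` ([fnirs_raw()] objects),
#'   `truth`, and `conc_a`, `conc_b` (the generated concentration fields).
#' @export
simulate_dyad <- function(geom_a, geom_b, paradigm, truth,
                          rate_a = NULL, rate_b = NULL,
                          coupling_condition = "live",
                          coupling_channels_a = NULL,
                          coupling_channels_b = NULL,
                          dpf = rep(6, 3), extinction = default_extinction()) {
  default_rate <- function(g) {
    switch(g$site_id[1], UK = 12.34, US = 8.13,
           abort(sprintf("no default sampling rate for site '%s'; pass it explicitly.", g$site_id[1])))
  }
  rate_a <- rate_a %||% default_rate(geom_a)
  rate_b <- rate_b %||% default_rate(geom_b)
  dur <- paradigm_duration(paradigm)
  if (dur <= 0) abort("paradigm has zero duration.")

  make_coupling <- function(rate) {
    if (truth$coupling_amplitude <= 0) return(NULL)
    n_t <- as.integer(round(dur * rate))
    c_raw <- simulate_coupled_series(n_t, rate, truth$coupling_period,
                                     seed = child_seed(truth$seed, 1L))
    gate <- condition_run_gate(paradigm, coupling_condition, n_t, rate)
    truth$coupling_amplitude * c_raw * gate
  }

  conc_a <- simulate_concentrations(geom_a, paradigm, truth, rate_a,
                                    make_coupling(rate_a),
                                    child_seed(truth$seed, 2L),
                                    coupling_channels_a)
  conc_b <- simulate_concentrations(geom_b, paradigm, truth, rate_b,
                                    make_coupling(rate_b),
                                    child_seed(truth$seed, 3L),
                                    coupling_channels_b)

  raw_a <- mbll_intensity(conc_a$hbo2, conc_a$hhb, geom_a, rate_a,
                          site_id = geom_a$site_id[1], dpf = dpf,
                          extinction = extinction)
  raw_b <- mbll_intensity(conc_b$hbo2, conc_b$hhb, geom_b, rate_b,
                          site_id = geom_b$site_id[1], dpf = dpf,
                          extinction = extinction)
  list(raw_a = raw_a, raw_b = raw_b, truth = truth,
       conc_a = conc_a, conc_b = conc_b)
}

#' Inject channel artefacts into a raw recording
#'
#' Modifies the selected channels to exhibit a named artefact so the quality
#' control stage has something to find; all other channels are untouched.
#' Kinds: `"mirrored"` (HbO2 and HHb perfectly anticorrelated, rebuilt
#' through the forward optics), `"saturated"` (intensity pinned at the
#' dynamic-range ceiling for a fraction of samples), `"no_heartbeat"`
#' (cardiac band excised from the intensity spectrum), `"high_rms"`
#' (intensity fluctuations amplified `scale`-fold).
#'
#' @param raw an [fnirs_raw()] recording.
#' @param kind artefact kind (single string).
#' @param channels integer channel indices; empty returns the input
#'   unchanged.
#' @param scale amplification for `"high_rms"`.
#' @param ceiling_frac fraction of samples pinned for `"saturated"`.
#' @param geometry geometry (needed to rebuild `"mirrored"` channels through
#'   the forward model).
#' @param heartbeat_band band (Hz) removed for `"no_heartbeat"`.
#' @return The modified [fnirs_raw()].
#' @export
inject_bad_channels <- function(raw, kind, channels, scale = 12,
                                ceiling_frac = 0.05, geometry = NULL,
                                heartbeat_band = c(0.7, 1.3)) {
  stopifnot(inherits(raw, "fnirs_raw"))
  if (length(channels) == 0) return(raw)
  n_ch <- dim(raw$data)[1]
  if (any(channels < 1 | channels > n_ch)) abort("channel index out of range.")
  kinds <- c("mirrored", "saturated", "no_heartbeat", "high_rms")
  if (!kind %in% kinds) {
    abort(sprintf("unknown artefact kind '%s' (use one of: %s).",
                  kind, paste(kinds, collapse = ", ")))
  }
  x <- raw$data
  n_t <- dim(x)[2]
  for (ch in channels) {
    if (kind == "high_rms") {
      for (w in 1:3) {
        m <- mean(x[ch, , w])
        x[ch, , w] <- pmax(m + scale * (x[ch, , w] - m), m * 1e-3)
      }
    } else if (kind == "saturated") {
      ceiling_val <- max(x[ch, , ]) * 1.2
      idx <- seq_len(max(1L, round(ceiling_frac * n_t)))
      for (w in 1:3) x[ch, idx, w] <- ceiling_val
    } else if (kind == "no_heartbeat") {
      for (w in 1:3) {
        x[ch, , w] <- fft_bandstop(x[ch, , w], raw$sampling_rate,
                                   heartbeat_band[1], heartbeat_band[2])
      }
      x[ch, , ] <- pmax(x[ch, , ], 1e-6)
    } else if (kind == "mirrored") {
      if (is.null(geometry)) abort("`geometry` is required for kind = 'mirrored'.")
      s <- sin(2 * pi * 0.05 * (seq_len(n_t) - 1) / raw$sampling_rate)
      od <- mbll_forward_od(matrix(s, 1), matrix(-s, 1),
                            default_extinction(),
                            geometry$separation_cm[ch], rep(6, 3))
      for (w in 1:3) x[ch, , w] <- 10^(-od[1, , w])
    }
  }
  fnirs_raw(x, raw$sampling_rate, raw$site_id, raw$wavelengths)
}

# zero out an FFT band (two-sided) of a real series
fft_bandstop <- function(x, rate, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)                 # two-sided frequency magnitude
  X <- fft(x)
  X[f >= lo & f <= hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}
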