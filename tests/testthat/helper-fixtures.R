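# Small shared fixtures, built in code at test time.

# short two-condition paradigm: one 120 s run per condition
tiny_paradigm <- function(n_repeats = 1) {
  generate_paradigm(c("live", "static"), n_repeats = n_repeats)
}

# reduced-channel geometries for fast simulation (full montages where the
# channel count itself is under test)
tiny_geoms <- function(n_a = 6, n_b = 8, seed = 11) {
  list(
    a = generate_geometry(site_config("UK"), seed = seed)[seq_len(n_a), ],
    b = generate_geometry(site_config("US"), seed = seed + 1)[seq_len(n_b), ]
  )
}

# clean noiseless dyad for exact-recovery checks
noiseless_dyad <- function(paradigm = tiny_paradigm(), seed = 5,
                           n_a = 4, n_b = 5) {
  g <- tiny_geoms(n_a, n_b)
  truth <- ground_truth(noise_sd = 0, heartbeat_amplitude = 0,
                        systemic_amplitude = 0, seed = seed)
  sim <- simulate_dyad(g$a, g$b, paradigm, truth)
  c(sim, list(geom_a = g$a, geom_b = g$b, paradigm = paradigm))
}

demean_rows <- function(m) m - rowMeans(m)

# direct cross-spectral oracle: squared correlation of two series after
# band-passing both around 1/period (independent of the wavelet path)
bandpass_corr2 <- function(x, y, rate, period, halfwidth = 0.25) {
  f0 <- 1 / period
  ny <- rate / 2
  bf <- signal::butter(2, c((1 - halfwidth) * f0, (1 + halfwidth) * f0) / ny,
                       type = "pass")
  xf <- signal::filtfilt(bf, x)
  yf <- signal::filtfilt(bf, y)
  stats::cor(xf, yf)^2
}

# exhaustive Benjamini-Hochberg step-up oracle: largest k with
# p_(k) <= k q / m, reject the k smallest p-values
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}
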