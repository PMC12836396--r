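test_that("MBLL conversion solves the 3-wavelength system exactly", {
  # constant intensity -> zero concentration change
  const <- fnirs_raw(array(0.8, dim = c(2, 50, 3)), 8.13)
  geom <- tibble::tibble(channel = 1:2, x = 0, y = 0, z = 0,
                         separation_cm = 3, site_id = "US")
  hb <- mbll_convert(const, geom)
  expect_equal(max(abs(hb$hbo2)), 0)
  expect_equal(max(abs(hb$hhb)), 0)

  # OD synthesised from known concentrations: normal-equation oracle
  set.seed(42)
  ext <- default_extinction()
  dpf <- c(6, 6, 6)
  n <- 40
  c_true <- rbind(hbo2 = rnorm(n, sd = 0.5), hhb = rnorm(n, sd = 0.5))
  od <- ext %*% c_true * 3 * 6 * 1e-3          # wavelengths x samples
  arr <- array(0, dim = c(1, n, 3))
  for (w in 1:3) arr[1, , w] <- 10^(-od[w, ])
  raw <- fnirs_raw(arr, 8.13)
  hb2 <- mbll_convert(raw, geom[1, ], dpf = dpf,
                      i0 = matrix(1, 1, 3))
  # oracle: least squares through the explicit normal equations
  oracle <- solve(crossprod(ext), t(ext) %*% od) / (3 * 6 * 1e-3)
  expect_lt(max(abs(hb2$hbo2[1, ] - oracle[1, ])), 1e-9)
  expect_lt(max(abs(hb2$hhb[1, ] - oracle[2, ])), 1e-9)
  expect_lt(max(abs(hb2$hbo2[1, ] - c_true[1, ])), 1e-9)

  # contract: exactly three wavelengths
  expect_error(fnirs_raw(array(1, dim = c(2, 10, 2)), 8), "3")
  expect_error(mbll_convert(raw, geom[1, ], extinction = ext[1:2, ]),
               "3 x 2")
})

test_that("Fourier resampling preserves in-band sinusoids and lengths", {
  t12 <- (0:1233) / 12.34
  x <- sin(2 * pi * 0.1 * t12)
  h <- hb_series(rbind(x), rbind(x), 12.34)
  h2 <- resample_series(h, 8.13)
  expect_equal(ncol(h2$hbo2), round(1234 * 8.13 / 12.34))  # 813
  t8 <- (0:(ncol(h2$hbo2) - 1)) / 8.13
  ref <- sin(2 * pi * 0.1 * t8)
  interior <- 30:780
  expect_lt(max(abs(h2$hbo2[1, interior] - ref[interior])) / 1, 0.01)
  # identity when target equals source
  expect_identical(resample_series(h, 12.34), h)
  h$hbo2[1, 5] <- NaN
  expect_error(resample_series(h, 8.13), "finite")
})

test_that("zero-phase Butterworth band-pass has the designed response", {
  rate <- 8.13
  n <- 4096
  t <- (0:(n - 1)) / rate
  zero <- hb_series(rbind(numeric(n)), rbind(numeric(n)), rate)
  expect_equal(max(abs(bandpass(zero)$hbo2)), 0)

  gain_at <- function(f) {
    x <- sin(2 * pi * f * t)
    h <- hb_series(rbind(x), rbind(x), rate)
    y <- bandpass(h)$hbo2[1, ]
    interior <- seq.int(n %/% 4, 3 * n %/% 4)
    max(abs(y[interior])) / 1
  }
  expect_lt(abs(gain_at(0.1) - 1), 0.05)       # passband centre
  expect_lt(gain_at(1.0), 0.1)                 # cardiac band attenuated >90%
  expect_lt(gain_at(0.002), 0.1)               # drift attenuated

  # zero-phase: impulse response symmetric about the impulse
  imp <- numeric(n); imp[n / 2] <- 1
  y <- bandpass(hb_series(rbind(imp), rbind(imp), rate))$hbo2[1, ]
  win <- 200
  left <- y[(n / 2 - win):(n / 2 - 1)]
  right <- y[(n / 2 + 1):(n / 2 + win)]
  expect_lt(max(abs(left - rev(right))), 1e-6)

  # idempotency within 1% RMS on haemodynamic-band content (repeated
  # filtering only re-attenuates the transition bands)
  set.seed(1)
  inband <- signal::filtfilt(signal::butter(4, c(0.04, 0.12) / (rate / 2),
                                            "pass"), rnorm(n))
  h1 <- bandpass(hb_series(rbind(inband), rbind(inband), rate))
  h2 <- bandpass(h1)
  rel <- sqrt(mean((h2$hbo2 - h1$hbo2)^2)) / sqrt(mean(h1$hbo2^2))
  expect_lt(rel, 0.01)

  expect_error(bandpass(zero, low = 0.01, high = 5), "Nyquist")
})

test_that("global mean removal strips the channel-common component", {
  set.seed(7)
  n_ch <- 10; n_t <- 600
  drift <- cumsum(rnorm(n_t)); drift <- drift / sd(drift) * 3
  base <- matrix(rnorm(n_ch * n_t, sd = 0.3), n_ch, n_t)
  x <- base + matrix(drift, n_ch, n_t, byrow = TRUE)
  h <- hb_series(x, x, 8.13)
  out <- global_mean_removal(h)
  expect_equal(dim(out$hbo2), dim(h$hbo2))
  # variance of the injected common component reduced by >= 99%
  common_before <- var(colMeans(x))
  common_after <- var(colMeans(out$hbo2))
  expect_lt(common_after / common_before, 0.01)

  # residual structure orthogonal to the removed component is untouched:
  # X = w g' + R with R spatially+temporally orthogonal to the component
  w <- c(3, rep(1, 5)); w <- w / sqrt(sum(w^2))
  g <- sin(2 * pi * (1:300) / 40) * 10
  v2 <- cos(2 * pi * (1:300) / 23)
  v2 <- v2 - sum(v2 * g) / sum(g * g) * g       # exact temporal orthogonality
  w2 <- c(1, -1, 1, -1, 1, -1) - sum(w * c(1, -1, 1, -1, 1, -1)) * w
  R <- outer(w2, v2)
  X <- outer(w, g) + R
  h2 <- hb_series(X, X, 8.13)
  out2 <- global_mean_removal(h2)
  expect_lt(max(abs(out2$hbo2 - R)), 1e-10)

  expect_error(global_mean_removal(hb_series(rbind(1:5), rbind(1:5), 8)),
               "2 channels")
})

test_that("HbDiff identity holds after every preprocessing operation", {
  sim <- noiseless_dyad()
  hb <- mbll_convert(sim$raw_b, sim$geom_b)
  for (op in list(function(h) resample_series(h, 8.13),
                  function(h) bandpass(h),
                  function(h) global_mean_removal(h))) {
    hb <- op(hb)
    expect_equal(hbdiff(hb), hb$hbo2 - hb$hhb)
  }
})

test_that("QC flags channels by the 10x RMS rule and artefact signatures", {
  g <- tiny_geoms(8, 8)
  truth <- ground_truth(noise_sd = 0.05, seed = 6)
  sim <- simulate_dyad(g$a, g$b, tiny_paradigm(), truth)

  # clean recording: nothing excluded
  hb <- mbll_convert(sim$raw_b, g$b)
  qc0 <- qc_exclude_channels(sim$raw_b, hb)
  expect_equal(qc0$fraction_excluded, 0)

  # rule arithmetic on a montage-sized common-mode recording: with n
  # channels sharing one signal and channel 2 amplified k-fold, the
  # channel-to-average RMS ratio is k * n / (n - 1 + k), so k = 12 crosses
  # the 10x threshold (10.99 at n = 120) and k = 9 stays under (8.44)
  n_ch <- 120; n_t <- 600
  common <- 1 + 0.05 * sin(2 * pi * (1:n_t) / 37) +
    0.02 * sin(2 * pi * 1.0 * (1:n_t) / 8.13)
  for (k in c(12, 9)) {
    arr <- array(rep(common, each = n_ch), dim = c(n_ch, n_t, 3))
    arr[2, , ] <- mean(common) + k * (arr[2, , ] - mean(common))
    raw_k <- fnirs_raw(arr, 8.13)
    hb_k <- hb_series(matrix(common, n_ch, n_t, byrow = TRUE),
                      matrix(common, n_ch, n_t, byrow = TRUE) / 2, 8.13)
    qc_k <- qc_exclude_channels(raw_k, hb_k)
    if (k == 12) expect_true(qc_k$flags$high_rms[2])
    else expect_false(qc_k$flags$high_rms[2])
    expect_false(any(qc_k$flags$high_rms[-2]))
  }

  # mirrored and saturated artefacts are caught
  raw_m <- inject_bad_channels(sim$raw_b, "mirrored", 3, geometry = g$b)
  qc_m <- qc_exclude_channels(raw_m, mbll_convert(raw_m, g$b))
  expect_true(qc_m$flags$mirrored[3])
  raw_s <- inject_bad_channels(sim$raw_b, "saturated", 4)
  qc_s <- qc_exclude_channels(raw_s, mbll_convert(raw_s, g$b))
  expect_true(qc_s$flags$saturated[4])

  # identical channels: no high_rms flags (each RMS equals the average RMS)
  same <- fnirs_raw(array(rep(1 + 0.1 * sin(1:200), each = 4),
                          dim = c(4, 200, 3)), 8.13)
  hb_same <- hb_series(matrix(sin(1:200), 4, 200, byrow = TRUE),
                       matrix(cos(1:200), 4, 200, byrow = TRUE), 8.13)
  expect_false(any(qc_exclude_channels(same, hb_same)$flags$high_rms))
})

test_that("QC flags are invariant to channel ordering", {
  g <- tiny_geoms(6, 6)
  truth <- ground_truth(noise_sd = 0.05, seed = 8)
  sim <- simulate_dyad(g$a, g$b, tiny_paradigm(), truth)
  raw <- inject_bad_channels(sim$raw_b, "high_rms", channels = 2, scale = 15)
  hb <- mbll_convert(raw, g$b)
  qc <- qc_exclude_channels(raw, hb)

  perm <- c(4, 1, 6, 2, 3, 5)
  raw_p <- fnirs_raw(raw$data[perm, , , drop = FALSE], raw$sampling_rate,
                     raw$site_id)
  hb_p <- hb_series(hb$hbo2[perm, ], hb$hhb[perm, ], hb$sampling_rate)
  qc_p <- qc_exclude_channels(raw_p, hb_p)
  expect_equal(qc_p$flags$excluded, qc$flags$excluded[perm])
})
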