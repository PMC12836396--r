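test_that("the scale grid spans 2.5 to ~34 s in 16 scales", {
  g <- build_scale_grid()
  expect_length(g$periods, 16)
  expect_equal(min(g$periods), 2.5)
  expect_equal(g$periods[5] / g$periods[1], 2)   # one octave after 4 voices
  expect_lt(max(g$periods), 34)

  lin <- build_scale_grid(spacing = "linear")
  expect_equal(lin$periods, seq(2.5, 40, by = 2.5))

  expect_equal(build_scale_grid(1, 1, 7)$periods, 7)
  expect_error(build_scale_grid(base_period = 0), "positive")
})

test_that("the complex-Gaussian CWT localises sinusoids at their period", {
  rate <- 8.13
  grid <- build_scale_grid()
  n <- 2048
  t <- (0:(n - 1)) / rate

  expect_equal(max(Mod(cwt_cgau(numeric(n), rate, grid))), 0)

  for (p0 in c(5, 10, 20)) {
    W <- cwt_cgau(sin(2 * pi * t / p0), rate, grid)
    ridge <- grid$periods[which.max(rowMeans(Mod(W)^2))]
    expect_equal(ridge, grid$periods[which.min(abs(grid$periods - p0))])
  }

  # linearity
  x <- rnorm(n)
  expect_equal(cwt_cgau(2.5 * x, rate, grid), 2.5 * cwt_cgau(x, rate, grid),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(cwt_cgau(x, rate = 0.5, grid), "2 samples")
  expect_error(cwt_cgau(c(x[-1], NA), rate, grid), "finite")
})

test_that("wavelet coherence is a symmetric, bounded self-normalised measure", {
  rate <- 8.13
  grid <- build_scale_grid()
  set.seed(21)
  n <- 976
  x <- rnorm(n); y <- rnorm(n)

  # self-coherence is exactly 1 at every scale and time
  ws <- wavelet_coherence(x, x, rate, grid)
  expect_lt(max(abs(ws$msc - 1)), 1e-10)

  # bounded in [0, 1]
  w <- wavelet_coherence(x, y, rate, grid)
  expect_true(all(w$msc >= 0 & w$msc <= 1))

  # symmetry to 1e-12
  w2 <- wavelet_coherence(y, x, rate, grid)
  expect_lt(max(abs(w$msc - w2$msc)), 1e-12)

  # zero-variance input yields the undefined flag, not numbers
  wz <- wavelet_coherence(numeric(n), y, rate, grid)
  expect_true(wz$undefined)
  expect_true(all(is.na(wz$msc)))
})

test_that("without smoothing the estimator degenerates to 1 (guard)", {
  # the moving-average smoother is what makes MSC informative: with a
  # one-sample window the ratio collapses to 1 for ANY pair of signals
  rate <- 8.13
  grid <- build_scale_grid()
  set.seed(4)
  x <- rnorm(488); y <- rnorm(488)
  w0 <- wavelet_coherence(x, y, rate, grid, smooth_periods = 1e-9)
  expect_lt(max(abs(w0$msc - 1)), 1e-9)
  # while the default (smoothed) estimator is far from 1 for noise
  w3 <- wavelet_coherence(x, y, rate, grid)
  expect_lt(mean(w3$msc), 0.9)
})

test_that("independent noise falls below the permutation-oracle 95% band", {
  rate <- 8.13
  grid <- build_scale_grid(octaves = 3)   # periods 2.5..14 fit the series
  set.seed(31)
  n <- 976
  x <- rnorm(n); y <- rnorm(n)
  observed <- mean(wavelet_coherence(x, y, rate, grid)$msc)
  # permutation oracle: circular shifts of y destroy any alignment while
  # preserving the spectrum; 100 draws give the null band
  draws <- vapply(1:100, function(i) {
    ys <- y[c((i * 7 + 1):n, 1:(i * 7))]
    mean(wavelet_coherence(x, ys, rate, grid)$msc)
  }, numeric(1))
  expect_lt(observed, quantile(draws, 0.95))
})

test_that("per-dyad coherence averages runs into one value per period and condition", {
  rate <- 8.13
  p <- tiny_paradigm(n_repeats = 2)
  grid <- build_scale_grid()
  set.seed(5)
  n <- round(paradigm_duration(p) * rate)

  # identical residual series: MSC = 1 at every period
  x <- rnorm(n)
  dc1 <- dyad_coherence(x, x, p, rate, grid)
  expect_equal(nrow(dc1), 2 * 16)                 # condition x period
  expect_lt(max(abs(dc1$msc - 1)), 1e-10)

  # live-only coupling at 20 s: live profile exceeds static near 20 s
  amp <- coupling_amplitude_for_msc(0.6, 1, rate, 20)
  rp <- simulate_residual_pair(p, rate, coupling_amplitude = amp,
                               coupling_period = 20, seed = 17)
  dc <- dyad_coherence(rp$a, rp$b, p, rate, grid)
  k20 <- which.min(abs(grid$periods - 20))
  live <- dc$msc[dc$condition == "live"]
  static <- dc$msc[dc$condition == "static"]
  expect_gt(live[k20], static[k20])

  expect_error(dyad_coherence(x, x, p, rate, grid, conditions = "poke"),
               "absent")
})

test_that("shuffled pairs form a seeded cross-site derangement", {
  real <- tibble::tibble(uk = sprintf("uk%02d", 1:20),
                         us = sprintf("us%02d", 1:20))
  sh <- make_shuffled_pairs(real, seed = 3)
  expect_equal(nrow(sh), 20)
  # no shuffled pair equals a real pair
  expect_false(any(paste(sh$uk, sh$us) %in% paste(real$uk, real$us)))
  # each side drawn from its own laboratory
  expect_setequal(sh$uk, real$uk)
  expect_true(all(sh$us %in% real$us))
  # deterministic per seed
  expect_identical(sh, make_shuffled_pairs(real, seed = 3))
  expect_false(identical(sh, make_shuffled_pairs(real, seed = 4)))

  # n = 2: the unique swap
  two <- make_shuffled_pairs(real[1:2, ], seed = 1)
  expect_equal(two$us, c("us02", "us01"))
  expect_error(make_shuffled_pairs(real[1, ]), "2 real dyads")

  # oversampling draws further derangements
  many <- make_shuffled_pairs(real, n_pairs = 35, seed = 5)
  expect_equal(nrow(many), 35)
  expect_false(any(paste(many$uk, many$us) %in% paste(real$uk, real$us)))
})

test_that("coherence profiles summarise dyads with mean within the dyad range", {
  grid <- build_scale_grid()
  set.seed(6)
  one <- tibble::tibble(dyad = "d1", kind = "real", condition = "live",
                        period_s = grid$periods, msc = runif(16))
  pr1 <- coherence_profile(one)
  expect_equal(pr1$mean, one$msc)
  expect_true(all(pr1$sd == 0))

  many <- dplyr::bind_rows(lapply(1:20, function(i) {
    dplyr::mutate(one, dyad = paste0("d", i), msc = runif(16))
  }))
  pr <- coherence_profile(many)
  rng <- many %>% dplyr::group_by(period_s) %>%
    dplyr::summarise(lo = min(msc), hi = max(msc))
  expect_true(all(pr$mean >= rng$lo & pr$mean <= rng$hi))
})
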