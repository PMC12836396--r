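test_that("canonical HRF has the standard double-gamma shape", {
  for (rate in c(8.13, 16.26)) {
    h <- canonical_hrf(rate)
    t <- (seq_along(h) - 1) / rate
    peak <- t[which.max(h)]
    expect_gte(peak, 5); expect_lte(peak, 7)
    expect_equal(h[1], 0)                 # gamma density at the origin
    expect_equal(max(h), 1)               # peak-normalised
    # undershoot present and smaller than the peak
    expect_lt(min(h), 0)
    expect_gt(min(h), -0.5)
  }
  # peak location is rate-invariant within one sample
  p1 <- which.max(canonical_hrf(8.13)) / 8.13
  p2 <- which.max(canonical_hrf(16.26)) / 16.26
  expect_lte(abs(p1 - p2), 1 / 8.13 + 1e-9)
  expect_error(canonical_hrf(0), "positive")
})

test_that("design matrices carry one HRF-convolved regressor per condition", {
  rate <- 8.13
  p <- tiny_paradigm()
  X <- build_design(p, rate)
  expect_equal(ncol(X), 3)                       # live, static, intercept
  expect_equal(colnames(X), c("live", "static", "(Intercept)"))

  # a single 15 s block: regressor peaks after the block onset (HRF lag)
  single <- generate_paradigm("live", n_repeats = 1)
  single <- single[1:2, ]                        # one task + one rest block
  X1 <- build_design(single, rate, n_samples = round(60 * rate))
  peak_t <- (which.max(X1[, "live"]) - 1) / rate
  expect_gt(peak_t, single$onset[1])

  # all-rest paradigm: no condition regressors, intercept only
  rest_only <- tibble::tibble(onset = c(0, 15), duration = c(15, 15),
                              condition = "rest", run = 1L)
  X0 <- build_design(rest_only, rate, n_samples = 100)
  expect_equal(colnames(X0), "(Intercept)")

  expect_error(build_design(p[0, ], rate), "empty")
})

test_that("OLS fits match the normal-equation oracle to 1e-10", {
  set.seed(3)
  rate <- 8.13
  X <- build_design(tiny_paradigm(), rate)
  n <- nrow(X)
  y <- matrix(rnorm(4 * n), 4, n)
  fit <- fit_glm(y, X)
  oracle <- t(solve(crossprod(X), t(X) %*% t(y)))    # explicit (X'X)^-1 X'y
  expect_lt(max(abs(fit$betas - oracle)), 1e-10)
  expect_equal(fit$dof, n - 3)

  # residuals orthogonal to every design column
  expect_lt(max(abs(fit$residuals %*% X)), 1e-8)

  # y equal to a design column recovers beta = 1, zero residuals
  fit1 <- fit_glm(X[, "live"], X)
  expect_equal(unname(fit1$betas[1, ]), c(1, 0, 0), tolerance = 1e-10)
  expect_lt(max(abs(fit1$residuals)), 1e-10)

  # linearity: fitting a*y scales the betas by a
  fit_a <- fit_glm(3.5 * y, X)
  expect_equal(fit_a$betas, 3.5 * fit$betas, tolerance = 1e-10)

  # rank-deficient design rejected
  Xbad <- cbind(X, X[, 1])
  expect_error(fit_glm(y, Xbad), "rank-deficient")
})

test_that("noiseless simulated amplitudes are recovered as betas", {
  sim <- noiseless_dyad()
  hb <- mbll_convert(sim$raw_b, sim$geom_b)
  X <- build_design(sim$paradigm, 8.13, n_samples = ncol(hb$hbo2))
  fit <- fit_glm(hb$hbo2, X)
  expect_lt(max(abs(fit$betas[, "live"] - sim$conc_b$ch_gain)), 1e-6)
  expect_lt(max(abs(fit$betas[, "static"] - sim$conc_b$ch_gain)), 1e-6)
})

test_that("the group contrast is a paired one-sample t-test with n-1 dof", {
  set.seed(9)
  live <- matrix(rnorm(40 * 3, mean = 0.3), 40, 3)
  static <- matrix(rnorm(40 * 3), 40, 3)
  res <- group_contrast_test(live, static)
  expect_equal(unique(res$dof), 39)              # 40 participants

  # textbook oracle on a printed toy vector of 5 contrasts
  d <- c(0.12, -0.05, 0.31, 0.02, 0.15)
  res5 <- group_contrast_test(matrix(d, 5, 1), matrix(0, 5, 1))
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res5$t, t_hand, tolerance = 1e-12)
  expect_equal(res5$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)

  # identical condition betas: t = 0, p = 1
  same <- group_contrast_test(live, live)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))

  expect_error(group_contrast_test(live[1, , drop = FALSE],
                                   static[1, , drop = FALSE]), "2 participants")
})

test_that("FDR correction reproduces the exhaustive BH step-up rule", {
  p <- c(0.001, 0.02, 0.03, 0.5)
  expect_equal(sum(fdr_correct(p, 0.05)), 3)
  expect_equal(fdr_correct(p, 0.05), bh_stepup_oracle(p, 0.05))

  expect_false(any(fdr_correct(rep(1, 10), 0.05)))
  expect_equal(fdr_correct(numeric(0)), logical(0))

  # random panels, including permutation invariance
  set.seed(11)
  for (i in 1:25) {
    pv <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(fdr_correct(pv, q), bh_stepup_oracle(pv, q))
    perm <- sample(length(pv))
    expect_equal(fdr_correct(pv[perm], q), fdr_correct(pv, q)[perm])
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})
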