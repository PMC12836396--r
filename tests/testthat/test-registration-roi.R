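test_that("pairwise distances are Euclidean with the documented shape", {
  a <- tibble::tibble(channel = 1, x = 0, y = 0, z = 0)
  b <- tibble::tibble(channel = 1, x = 3, y = 4, z = 0)
  expect_equal(pairwise_distances(a, a)[1, 1], 0)
  expect_equal(pairwise_distances(b, a)[1, 1], 5)

  input <- generate_geometry(site_config("UK"), 1)
  mask <- generate_geometry(site_config("US"), 2)
  d <- pairwise_distances(input, mask)
  expect_equal(dim(d), c(134, 88))
  expect_error(pairwise_distances(input[0, ], mask), "empty")
})

test_that("kernel weights are Gaussian in distance and column-normalised", {
  input <- generate_geometry(site_config("UK"), 3)
  mask <- generate_geometry(site_config("US"), 4)
  d <- pairwise_distances(input, mask)
  for (form in c("sigma_times_d2", "d2_over_sigma")) {
    sigma <- if (form == "sigma_times_d2") 0.01 else 100
    k <- build_kernel(d, sigma = sigma, form = form)
    expect_lt(max(abs(colSums(k$weights) - 1)), 1e-10)
    expect_true(all(k$weights >= 0))
  }
  k <- build_kernel(d, sigma = 0.01)
  # zero distance carries raw weight exp(0) = 1: the nearest input channel
  # always holds the largest weight in its mask column, monotone in distance
  dt <- t(d)
  for (j in sample(ncol(k$weights), 10)) {
    ord <- order(dt[, j])
    expect_equal(k$weights[ord, j], sort(k$weights[, j], decreasing = TRUE))
  }
  expect_error(build_kernel(d, sigma = -1), "positive")
})

test_that("colocalise maps any montage onto the 134-channel mask", {
  mask <- generate_geometry(site_config("US"), 4)
  sim <- noiseless_dyad(n_a = 4, n_b = 5)

  # 88-channel montage -> 134 mask channels
  g_uk <- generate_geometry(site_config("UK"), 3)
  hb_uk <- hb_series(matrix(rnorm(88 * 40), 88), matrix(rnorm(88 * 40), 88),
                     8.13)
  k <- build_kernel(pairwise_distances(g_uk, mask), 0.01)
  out <- colocalise(hb_uk, k)
  expect_equal(nrow(out$hbo2), 134)

  # mask-equal geometry in the strong-decay limit: kernel ~ identity
  k_id <- build_kernel(pairwise_distances(mask, mask), sigma = 10)
  hb_m <- hb_series(matrix(rnorm(134 * 30), 134),
                    matrix(rnorm(134 * 30), 134), 8.13)
  out_id <- colocalise(hb_m, k_id)
  expect_lt(max(abs(out_id$hbo2 - hb_m$hbo2)), 1e-8)

  # constants preserved (partition of unity over input channels)
  hb_c <- hb_series(matrix(3.7, 88, 20), matrix(-1.2, 88, 20), 8.13)
  out_c <- colocalise(hb_c, k)
  expect_lt(max(abs(out_c$hbo2 - 3.7)), 1e-12)
  expect_lt(max(abs(out_c$hhb + 1.2)), 1e-12)

  # linearity to 1e-10
  hb1 <- hb_series(matrix(rnorm(88 * 20), 88), matrix(rnorm(88 * 20), 88), 8.13)
  hb2 <- hb_series(matrix(rnorm(88 * 20), 88), matrix(rnorm(88 * 20), 88), 8.13)
  mix <- hb_series(2 * hb1$hbo2 - 5 * hb2$hbo2, 2 * hb1$hhb - 5 * hb2$hhb, 8.13)
  lhs <- colocalise(mix, k)$hbo2
  rhs <- 2 * colocalise(hb1, k)$hbo2 - 5 * colocalise(hb2, k)$hbo2
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  # dimension mismatch is an error
  expect_error(colocalise(hb_m, k), "input channels")

  # QC-excluded channels are dropped and columns renormalised
  hb_excl <- hb_c
  hb_excl$channel_mask[1:10] <- FALSE
  out_e <- colocalise(hb_excl, k)
  expect_lt(max(abs(out_e$hbo2 - 3.7)), 1e-12)
})

test_that("the packaged ROI table defines 14 bilateral regions without BA overlap", {
  rt <- roi_table()
  expect_equal(length(unique(rt$region)), 14)
  expect_equal(nrow(rt), 28)
  expect_setequal(unique(rt$hemisphere), c("L", "R"))
  bas <- unlist(strsplit(rt$brodmann[rt$hemisphere == "L"], ";"))
  expect_equal(anyDuplicated(bas), 0)
})

test_that("ROI averaging pools member channels and flags empty regions", {
  mask <- generate_geometry(site_config("US"), 4)
  assignment <- assign_rois(mask)
  expect_equal(nrow(assignment), 134)
  expect_equal(length(unique(assignment$region)), 14)

  hb <- hb_series(matrix(rnorm(134 * 60), 134), matrix(rnorm(134 * 60), 134),
                  8.13)
  rs <- roi_average(hb, assignment)
  expect_equal(nrow(rs$hbo2), 14)

  # single-channel ROI equals that channel
  one <- assignment
  one$region <- "other"
  one$region[7] <- "solo"
  rs1 <- roi_average(hb, one, regions = "solo")
  expect_equal(rs1$hbo2[1, ], hb$hbo2[7, ])

  # antiphase unit sinusoids average to zero
  t <- (1:100) / 8.13
  two <- hb_series(rbind(sin(t), -sin(t)), rbind(sin(t), -sin(t)), 8.13)
  asg <- tibble::tibble(channel = 1:2, region = "pair", hemisphere = "L",
                        distance_mm = 0)
  expect_lt(max(abs(roi_average(two, asg)$hbo2)), 1e-12)

  # a region with no included channel is an error naming the region
  hb_masked <- hb
  hb_masked$channel_mask[assignment$region == "angular_gyrus"] <- FALSE
  expect_error(roi_average(hb_masked, assignment), "angular_gyrus")
})
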