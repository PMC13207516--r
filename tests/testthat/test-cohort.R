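test_that("cohort sampling is seeded, named, and strictly positive", {
  spec <- cohort_spec(n_samples = 50, seed = 7)
  a <- sample_feature_cohort(spec)
  b <- sample_feature_cohort(spec)
  expect_identical(a, b)
  expect_identical(names(a), c("sample_id", feature_names()))
  expect_true(all(as.matrix(a[feature_names()]) > 0))
  # a different seed changes the draw
  c2 <- sample_feature_cohort(cohort_spec(n_samples = 50, seed = 8))
  expect_false(identical(a$WSSG, c2$WSSG))
})

test_that("copula correlation is recovered empirically", {
  spec <- cohort_spec(n_samples = 5000, seed = 3)
  x <- sample_feature_cohort(spec)
  pairs <- list(c("WSS_trans", "WSSG"), c("TAWSS", "RRT"),
                c("E_eff", "E_loss"))
  for (pr in pairs) {
    target <- spec$feature_correlation[pr[1], pr[2]]
    got <- cor(x[[pr[1]]], x[[pr[2]]], method = "spearman")
    expect_lt(abs(got - target), 0.1)
  }
})

test_that("latent quality is monotone and saturating", {
  spec <- cohort_spec(n_samples = 20, seed = 1)
  x <- sample_feature_cohort(spec)
  cq <- flowgrade:::calibrated_quality(spec)
  s0 <- latent_quality(x, cq$coefficients, cq$intercept)
  x2 <- x
  x2$WSS_trans <- 2 * x2$WSS_trans
  s1 <- latent_quality(x2, cq$coefficients, cq$intercept)
  expect_true(all(s1 < s0))  # strictly decreasing in WSS_trans
  # all-zero coefficients: every sample at the scale midpoint
  z <- latent_quality(x, cq$coefficients * 0, 0, c(1, 10))
  expect_equal(z, rep(5.5, 20))
  # scores remain inside the scale
  expect_true(all(s0 > 1 & s0 < 10))
})

test_that("default cohort spans roughly the 3 to 9.5 score range", {
  co <- generate_cohort(cohort_spec(seed = 2))
  rng <- range(co$truth$quality)
  expect_gt(rng[1], 1.5)
  expect_lt(rng[1], 4.0)
  expect_gt(rng[2], 8.8)
  expect_lt(rng[2], 10)
})

test_that("ratings follow the bias + noise + clip model", {
  s <- c(4, 5, 6, 7)
  r0 <- simulate_ratings(s, n_raters = 3, rater_bias_sd = 0,
                         rater_noise_sd = 0, seed = 1)
  expect_equal(unname(as.matrix(r0[, -1])), cbind(s, s, s),
               ignore_attr = TRUE)
  # clipping at the scale bounds
  rc <- simulate_ratings(c(9.9, 1.05), n_raters = 2, rater_bias_sd = 2,
                         rater_noise_sd = 2, seed = 5)
  expect_true(all(as.matrix(rc[, -1]) >= 1 & as.matrix(rc[, -1]) <= 10))
  # seeded determinism
  expect_identical(simulate_ratings(s, seed = 9), simulate_ratings(s, seed = 9))
})

test_that("missing patterns must leave two ratings per sample", {
  s <- c(4, 5, 6)
  mp <- matrix(FALSE, 3, 3)
  mp[1, 1] <- TRUE
  r <- simulate_ratings(s, 3, missing_pattern = mp, seed = 1)
  expect_true(is.na(r$rater_1[1]))
  mp[1, 2] <- TRUE
  expect_error(simulate_ratings(s, 3, missing_pattern = mp, seed = 1),
               "fewer than 2")
})

test_that("rater-noise calibration hits the target ICC3k over seeds", {
  # Monte-Carlo check of the closed-form calibration at cohort scale
  iccs <- sapply(1:5, function(sd_) {
    co <- generate_cohort(cohort_spec(seed = sd_))
    icc3k(co$ratings)$icc3k
  })
  expect_lt(abs(mean(iccs) - 0.846), 0.05)
})

test_that("cohort spec validation rejects bad inputs", {
  expect_error(cohort_spec(score_range = c(5, 2)), "score_range")
  expect_error(cohort_spec(quality_weights = c(WSS_trans = 1)),
               "strictly negative")
  bad <- diag(19)
  bad[1, 2] <- bad[2, 1] <- 2  # not PSD
  expect_error(cohort_spec(feature_correlation = bad), "semidefinite")
})
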