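test_that("tensor primitives agree with naive summation", {
  tm <- asNamespace("threemode")
  set.seed(20)
  x <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  m <- matrix(rnorm(15), 5, 3)
  y <- tm$ttm(x, m, 2L)
  naive <- array(0, c(2, 5, 4))
  for (i in 1:2) for (j in 1:5) for (k in 1:4)
    naive[i, j, k] <- sum(m[j, ] * x[i, , k])
  expect_equal(y, naive, tolerance = 1e-12)
  for (mode in 1:3)
    expect_equal(tm$fold(tm$unfold(x, mode), mode, dim(x)), x)
})

test_that("rank admissibility is enforced", {
  expect_true(ranks_admissible(c(3, 2, 2)))
  expect_false(ranks_admissible(c(5, 2, 2)))
  x <- random_cube(c(6, 5, 4), 1)
  expect_error(tucker3_als(x, c(5, 2, 2)), "inadmissible")
  expect_error(tucker3_als(x, c(6, 5, 5)), "exceed")
  x[1] <- NA
  expect_error(tucker3_als(x, c(2, 2, 2)), "non-finite")
})

test_that("exact-rank and saturated fits reach 100%", {
  sy <- generate_tucker3_dataset(
    synthetic_spec(dims = c(12, 6, 5), ranks = c(2, 2, 2), noise_sd = 0,
                   missing_rate = 0, n_external = 0, seed = 31))
  pre <- preprocess_cube(sy$dataset$values)$data
  expect_equal(tucker3_als(pre, c(2, 2, 2))$fit_pct, 100, tolerance = 1e-9)

  x <- random_cube(c(4, 3, 3), 32)
  expect_equal(tucker3_als(x, c(4, 3, 3))$fit_pct, 100, tolerance = 1e-8)
})

test_that("ALS dominates the truncated HOSVD and its loss never increases", {
  for (s in 1:20) {
    x <- random_cube(c(5, 4, 3), 200 + s)
    fit <- tucker3_als(x, c(2, 2, 2))
    expect_gte(fit$fit_pct + 1e-10, hosvd_fit_oracle(x, c(2, 2, 2)))
    expect_true(all(diff(fit$loss_history) <= 1e-8 * fit$loss_history[1]))
  }
})

test_that("fitted models satisfy orthonormality and the core-SS identity", {
  for (s in 1:5) {
    x <- random_cube(c(8, 6, 5), 300 + s)
    fit <- tucker3_als(x, c(3, 2, 2))
    for (m in list(fit$A, fit$B, fit$C))
      expect_lt(max(abs(crossprod(m) - diag(ncol(m)))), 1e-10)
    expect_equal(sum(fit$G^2), sum(reconstruct(fit)^2),
                 tolerance = 1e-8)
    # sign convention: largest-magnitude entry of every column positive
    for (m in list(fit$A, fit$B, fit$C))
      for (j in seq_len(ncol(m)))
        expect_gt(m[which.max(abs(m[, j])), j], 0)
  }
})

test_that("fit is non-decreasing when any single rank grows", {
  # multi-start ALS: enough random restarts to escape the occasional local
  # optimum of the larger model
  for (s in 1:6) {
    x <- random_cube(c(7, 5, 4), 400 + s)
    base <- tucker3_als(x, c(2, 2, 2), n_starts = 15, seed = s)$fit_pct
    for (bump in list(c(3, 2, 2), c(2, 3, 2), c(2, 2, 3)))
      expect_gte(tucker3_als(x, bump, n_starts = 15, seed = s)$fit_pct,
                 base - 1e-6)
  }
})

test_that("reconstruction follows the model equation", {
  a <- c(1, -2, 0.5); b <- c(2, 1); cc <- c(0.3, -1, 2)
  model <- tucker3_model(matrix(a / sqrt(sum(a^2))),
                         matrix(b / sqrt(sum(b^2))),
                         matrix(cc / sqrt(sum(cc^2))),
                         array(4, c(1, 1, 1)))
  expect_equal(reconstruct(model),
               4 * outer(a / sqrt(sum(a^2)),
                         outer(b / sqrt(sum(b^2)), cc / sqrt(sum(cc^2)))),
               tolerance = 1e-12)

  x <- random_cube(c(5, 4, 3), 55)
  fit <- tucker3_als(x, c(5, 4, 3))
  expect_equal(reconstruct(fit), x, tolerance = 1e-8)
})

test_that("fit percentage behaves at its extremes and guards its domain", {
  x <- random_cube(c(5, 4, 3), 66)
  fit <- tucker3_als(x, c(5, 4, 3))
  expect_equal(fit_percentage(fit, x), 100, tolerance = 1e-8)

  zero_model <- tucker3_model(fit$A, fit$B, fit$C, array(0, c(5, 4, 3)))
  expect_equal(fit_percentage(zero_model, x), 0)
  expect_error(fit_percentage(fit, array(0, c(5, 4, 3))), "all-zero")
  expect_error(tucker3_als(array(0, c(4, 3, 2)), c(2, 2, 2)), "all-zero")
})

test_that("trend-inclusive fit accounting nests the heterogeneity fit", {
  sy <- generate_tucker3_dataset(
    synthetic_spec(dims = c(30, 8, 5), ranks = c(2, 2, 2), noise_sd = NULL,
                   target_share = 0.4, target_total_share = 0.7,
                   missing_rate = 0, n_external = 0, seed = 44))
  pre <- preprocess_cube(sy$dataset$values)
  fit <- tucker3_als(pre$data, c(2, 2, 2))
  fa <- total_fit_with_trend(fit, pre$state, sy$dataset$values)
  expect_equal(fa$heterogeneity_fit_pct, fit$fit_pct, tolerance = 1e-8)
  expect_gt(fa$total_fit_pct, fa$heterogeneity_fit_pct)  # trend SS > 0
  expect_true(all(c(fa$ss_trend, fa$ss_model, fa$ss_residual, fa$ss_total) >= 0))

  # perfect model on the preprocessed cube: total fit 100
  sat <- tucker3_als(pre$data, dim(pre$data))
  fa_sat <- total_fit_with_trend(sat, pre$state, sy$dataset$values)
  expect_equal(fa_sat$total_fit_pct, 100, tolerance = 1e-6)

  # zero model, zero trend: total fit 0
  x <- random_cube(c(6, 4, 3), 9)
  cen <- center_across_persons(x)$data   # trendless by construction
  pp <- preprocess_cube(cen)
  f0 <- tucker3_als(pp$data, c(2, 2, 2))
  zero <- tucker3_model(f0$A, f0$B, f0$C, array(0, c(2, 2, 2)))
  fa0 <- total_fit_with_trend(zero, pp$state, cen)
  expect_equal(fa0$total_fit_pct, 0, tolerance = 1e-10)
})
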