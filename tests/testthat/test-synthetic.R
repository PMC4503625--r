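test_that("generation is deterministic given spec and seed", {
  sp <- synthetic_spec(dims = c(10, 5, 4), ranks = c(2, 2, 2), noise_sd = 0.4,
                       missing_rate = 0.1, n_external = 2,
                       external_loadings = matrix(c(0.5, 0, 0, 0.3), 2, 2),
                       seed = 17)
  a <- generate_tucker3_dataset(sp)
  b <- generate_tucker3_dataset(sp)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$dataset$mask, b$dataset$mask)
  expect_identical(a$external_table, b$external_table)
  expect_identical(a$truth_model$G, b$truth_model$G)
})

test_that("spec validation rejects inadmissible inputs", {
  expect_error(synthetic_spec(ranks = c(4, 1, 1)), "inadmissible")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
  expect_error(synthetic_spec(dims = c(1, 5, 5)), "dims")
  expect_error(synthetic_spec(score_bounds = c(3, 0)), "score_bounds")
  expect_error(synthetic_spec(n_external = 1,
                              external_loadings = matrix(1.2, 1, 3)),
               "sums of squares")
  expect_error(synthetic_spec(target_share = 0.3, target_total_share = 0.2),
               "target_total_share")
})

test_that("planted components are orthonormal and the mask hits the target rate", {
  sp <- synthetic_spec(dims = c(219, 21, 9), ranks = c(3, 2, 2),
                       noise_sd = 1, missing_rate = 0.078, n_external = 0,
                       seed = 5)
  sy <- generate_tucker3_dataset(sp)
  for (m in list(sy$truth_model$A, sy$truth_model$B, sy$truth_model$C))
    expect_lt(max(abs(crossprod(m) - diag(ncol(m)))), 1e-10)
  expect_identical(sum(!sy$dataset$mask), as.integer(round(0.078 * 219 * 21 * 9)))
})

test_that("missingness injection: exact counts, rate 0 no-op, MAR-by-time gradient", {
  cube <- three_way_data(array(rnorm(219 * 21 * 9), c(219, 21, 9)))
  expect_identical(inject_missingness(cube, 0), cube)
  expect_error(inject_missingness(cube, 1), "rate")

  mcar <- inject_missingness(cube, 0.078, "MCAR", seed = 2)
  expect_identical(sum(!mcar$mask), 3228L)   # round(0.078 * 41391)

  mar <- inject_missingness(cube, 0.2, "MAR-by-time", seed = 2)
  by_time <- apply(!mar$mask, 3, mean)
  # geometric weighting concentrates missingness at later assessments
  expect_gt(mean(by_time[7:9]), 3 * mean(by_time[1:3]))
  expect_identical(sum(!mar$mask), as.integer(round(0.2 * 219 * 21 * 9)))
})

test_that("noiseless planted cube is recovered exactly at the true ranks", {
  sp <- synthetic_spec(dims = c(30, 8, 5), ranks = c(2, 2, 2), noise_sd = 0,
                       missing_rate = 0, n_external = 0, seed = 7)
  sy <- generate_tucker3_dataset(sp)
  pre <- preprocess_cube(sy$dataset$values)
  fit <- tucker3_als(pre$data, c(2, 2, 2))
  expect_equal(fit$fit_pct, 100, tolerance = 1e-9)
  truth <- truth_model_preprocessed(sy, pre$state)
  al <- align_solution(fit, truth, method = "procrustes")
  expect_true(all(abs(col_congruence(al$A, truth$A)) >= 0.999))
  expect_true(all(abs(col_congruence(al$B, truth$B)) >= 0.999))
  expect_true(all(abs(col_congruence(al$C, truth$C)) >= 0.999))
})

test_that("score bounds clip and round to the item range", {
  sp <- synthetic_spec(dims = c(40, 6, 5), ranks = c(2, 2, 2), noise_sd = 2,
                       missing_rate = 0, score_bounds = c(0, 3),
                       n_external = 0, seed = 9)
  v <- generate_tucker3_dataset(sp)$dataset$values
  expect_true(all(v >= 0 & v <= 3))
  expect_true(all(v == round(v)))
})

test_that("external covariates carry the planted correlations with person scores", {
  L <- rbind(c(0.6, 0), c(-0.4, 0.3))
  sp <- synthetic_spec(dims = c(500, 6, 5), ranks = c(2, 2, 2), noise_sd = 0.5,
                       missing_rate = 0, n_external = 2,
                       external_loadings = L, seed = 13)
  sy <- generate_tucker3_dataset(sp)
  z <- scale(sy$truth_model$A)
  for (e in 1:2)
    for (p in 1:2)
      expect_lt(abs(cor(sy$external_table[[e]], z[, p]) - L[e, p]), 0.1)
})

test_that("target_share calibration puts the planted share where requested", {
  fits <- vapply(1:6, function(s) {
    sy <- generate_tucker3_dataset(
      synthetic_spec(dims = c(120, 10, 6), ranks = c(2, 2, 2), noise_sd = NULL,
                     target_share = 0.5, n_external = 0, seed = s))
    tucker3_als(preprocess_cube(sy$dataset$values)$data, c(2, 2, 2))$fit_pct
  }, 0)
  expect_lt(abs(mean(fits) - 50), 3)
})

test_that("the study-shaped preset reproduces its calibration targets", {
  fits <- c(); tots <- c()
  for (s in 1:4) {
    sy <- generate_tucker3_dataset(study_like_spec(seed = s, missing_rate = 0,
                                                   n_external = 0))
    pre <- preprocess_cube(sy$dataset$values)
    f <- tucker3_als(pre$data, c(3, 2, 2))
    fits <- c(fits, f$fit_pct)
    tots <- c(tots,
              total_fit_with_trend(f, pre$state,
                                   sy$dataset$values)$total_fit_pct)
  }
  expect_lt(abs(mean(fits) - 28), 3)
  expect_lt(abs(mean(tots) - 65), 3)
})

test_that("synthetic datasets persist with a readable truth sidecar", {
  sy <- generate_tucker3_dataset(
    synthetic_spec(dims = c(8, 4, 3), ranks = c(2, 2, 2), noise_sd = 0.2,
                   missing_rate = 0.05, n_external = 0, seed = 23))
  path <- withr::local_tempfile(fileext = ".csv")
  write_synthetic_dataset(sy, path)
  back <- read_long_table(path, item_order = sy$dataset$item_labels)
  expect_equal(back$values, sy$dataset$values)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"), simplifyVector = TRUE)
  expect_equal(unlist(truth$ranks), c(2, 2, 2), ignore_attr = TRUE)
  expect_equal(truth$B, unclass(sy$truth_model$B), tolerance = 1e-12,
               ignore_attr = TRUE)
})
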