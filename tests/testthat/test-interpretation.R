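test_that("core explained variances add up to the model fit", {
  x <- random_cube(c(10, 6, 5), 1001)
  pre <- preprocess_cube(x)
  fit <- tucker3_als(pre$data, c(2, 2, 2))
  ss_pre <- sum(pre$data^2)
  ev <- core_explained_variance(fit, ss_pre)
  expect_equal(sum(ev$ev_pct), fit$fit_pct, tolerance = 1e-8)

  # saturated model: everything explained
  sat <- tucker3_als(pre$data, dim(pre$data))
  expect_equal(sum(core_explained_variance(sat, ss_pre)$ev_pct), 100,
               tolerance = 1e-8)
  expect_error(core_explained_variance(fit, 0), "positive")
})

test_that("a single planted core element carries all the model variance", {
  sy <- generate_tucker3_dataset(
    synthetic_spec(dims = c(20, 6, 5), ranks = c(2, 2, 2),
                   core_pattern = data.frame(p = 1, q = 2, r = 1,
                                             magnitude = 30),
                   noise_sd = 0, missing_rate = 0, n_external = 0, seed = 3))
  ev <- core_explained_variance(sy$truth_model, sum(sy$truth_model$G^2))
  expect_equal(ev$ev_pct[ev$p == 1 & ev$q == 2 & ev$r == 1], 100)
  expect_equal(sum(ev$ev_pct), 100)
})

test_that("pooled solutions keep the EV additivity with spread columns", {
  mp <- make_pooled(seed = 6)
  ss_pre <- sum(mp$pre$data^2)
  ev <- core_explained_variance(mp$pooled, ss_pre)
  expect_equal(sum(ev$ev_pct),
               100 * sum(mp$pooled$mean_model$G^2) / ss_pre,
               tolerance = 1e-10)
  expect_true(all(c("core_sd", "ev_sd") %in% names(ev)))
  expect_true(all(ev$core_sd >= 0))
})

test_that("trajectory curves follow the core-time contraction", {
  tm <- asNamespace("threemode")
  set.seed(55)
  model <- tucker3_model(tm$rorth(10, 2), tm$rorth(6, 2), tm$rorth(5, 2),
                         array(0, c(2, 2, 2)))
  flat <- component_trajectories(model)
  expect_true(all(flat$curves$value == 0))

  G <- array(0, c(2, 2, 2)); G[1, 2, 2] <- 5
  model$G <- G
  tr <- component_trajectories(model)
  curve <- tr$curves[tr$curves$person_component == 1 &
                       tr$curves$symptom_component == 2, "value"]
  expect_equal(curve, 5 * model$C[, 2], tolerance = 1e-12)

  # flipping a time component (compensated in the core) leaves curves intact
  flipped <- model
  flipped$C[, 2] <- -flipped$C[, 2]
  flipped$G[, , 2] <- -flipped$G[, , 2]
  tr2 <- component_trajectories(flipped)
  expect_equal(tr2$curves$value, tr$curves$value, tolerance = 1e-12)
})

test_that("trend projection contextualizes the curves", {
  sy <- generate_tucker3_dataset(study_like_spec(seed = 8, missing_rate = 0,
                                                 n_external = 0))
  pre <- preprocess_cube(sy$dataset$values)
  fit <- tucker3_als(pre$data, c(3, 2, 2))
  tr <- component_trajectories(fit, pre$state,
                               time_labels = sy$dataset$time_labels)
  expect_identical(nrow(tr$trend_projection), 2L * 9L)
  expect_identical(sort(unique(tr$curves$time)),
                   as.numeric(sy$dataset$time_labels))
})

test_that("external correlations: identity, pooling, and the null bound", {
  set.seed(91)
  A <- matrix(rnorm(219 * 2), 219, 2)
  # a component's own score column correlates perfectly with itself
  ct <- external_correlations(A, data.frame(self = A[, 1]),
                              method = "pearson")
  expect_equal(ct$r[ct$person_component == 1], 1, tolerance = 1e-10)

  # identical imputations reduce to the single-dataset coefficient
  ext <- data.frame(v = rnorm(219))
  single <- external_correlations(A, ext, method = "pearson")
  pooled <- external_correlations(rep(list(A), 5), ext, method = "pearson")
  expect_equal(pooled$r, single$r, tolerance = 1e-10)
  expect_equal(pooled$r_sd, rep(0, 2))

  # independent noise stays inside the n = 219 null band almost always
  inside <- 0
  for (s in 1:40) {
    set.seed(2000 + s)
    r <- cor(A[, 1], rnorm(219))
    if (abs(r) < 0.14) inside <- inside + 1
  }
  expect_gte(inside, 36)   # ~95% of replicates

  expect_error(external_correlations(A, data.frame(flat = rep(1, 219))),
               "constant")
})

test_that("the normality rule switches between Pearson and Spearman", {
  set.seed(92)
  A <- matrix(rnorm(200 * 2), 200, 2)
  ext <- data.frame(gaussian = rnorm(200), skewed = rexp(200)^2)
  ct <- external_correlations(A, ext, method = "auto")
  expect_identical(unique(ct$method[ct$variable == "gaussian"]), "pearson")
  expect_identical(unique(ct$method[ct$variable == "skewed"]), "spearman")
  # Benjamini-Hochberg adjustment never decreases p-values
  raw <- external_correlations(A, ext, method = "pearson")
  adj <- external_correlations(A, ext, method = "pearson", adjust = "BH")
  expect_true(all(adj$p_value >= raw$p_value - 1e-12))
})

test_that("planted covariate correlation is recovered through the full fit", {
  rs <- vapply(1:3, function(s) {
    sy <- generate_tucker3_dataset(
      study_like_spec(seed = 300 + s, structure_share = 0.7,
                      total_share = 0.85, missing_rate = 0))
    pre <- preprocess_cube(sy$dataset$values)
    fit <- joint_orthomax(tucker3_als(pre$data, c(3, 2, 2)))
    truth <- truth_model_preprocessed(sy, pre$state)
    al <- align_solution(fit, truth, method = "procrustes")
    ct <- external_correlations(al$A, sy$external_table, method = "pearson")
    ct$r[ct$variable == "covariate1" & ct$person_component == 1]
  }, 0)
  expect_lt(abs(mean(rs) - 0.6), 0.08)
})
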