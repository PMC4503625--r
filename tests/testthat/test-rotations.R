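test_that("congruence coefficient basics", {
  u <- c(1, 2, -3)
  expect_equal(congruence(u, u), 1)
  expect_equal(congruence(u, 2 * u), 1)
  expect_equal(congruence(c(1, 0), c(0, 1)), 0)
  expect_equal(congruence(u, -u), -1)
  expect_error(congruence(u, c(0, 0, 0)), "zero vector")
})

test_that("rotation weights: standard preset and validation", {
  w <- rotation_weights(c(219, 21, 9), c(3, 2, 2))
  expect_equal(w$w_mode[1], 0)                       # person mode unweighted
  expect_equal(w$w_mode[2], 12 / (21 * 2))           # core/matrix element ratio
  expect_equal(w$w_mode[3], 12 / (9 * 2))
  expect_error(rotation_weights(c(10, 5, 4), c(2, 2, 2), w_core = 0,
                                w_mode = c(0, 0, 0)), "at least one")
  expect_error(rotation_weights(c(10, 5, 4), c(2, 2, 2), w_mode = c(-1, 1, 1)),
               "nonnegative")
})

test_that("joint orthomax preserves the reconstruction and increases simplicity", {
  for (s in 1:5) {
    x <- random_cube(c(15, 7, 5), 500 + s)
    fit <- tucker3_als(x, c(3, 2, 2))
    rot <- joint_orthomax(fit)
    expect_lt(max(abs(reconstruct(rot) - reconstruct(fit))), 1e-10)
    expect_equal(fit_percentage(rot, x), fit_percentage(fit, x),
                 tolerance = 1e-12)
    hist <- attr(rot, "criterion_history")
    expect_true(all(diff(hist) >= -1e-9 * max(abs(hist))))
    for (m in list(rot$A, rot$B, rot$C))
      expect_lt(max(abs(crossprod(m) - diag(ncol(m)))), 1e-9)
  }
  bad <- tucker3_model(matrix(c(1, 1, 0, 1), 2) / 1.2, diag(2), diag(2),
                       array(1, c(2, 2, 2)))
  expect_error(joint_orthomax(bad), "orthonormal")
})

test_that("with only one component-matrix weight, joint orthomax is varimax", {
  tm <- asNamespace("threemode")
  set.seed(77)
  for (s in 1:3) {
    x <- random_cube(c(20, 8, 5), 600 + s)
    fit <- tucker3_als(x, c(2, 2, 2))
    w <- rotation_weights(c(20, 8, 5), c(2, 2, 2), w_core = 0,
                          w_mode = c(0, 1, 0))
    rot <- joint_orthomax(fit, w)
    vm <- stats::varimax(fit$B, normalize = FALSE, eps = 1e-12)
    expect_equal(tm$orthomax_crit(rot$B, 1),
                 tm$orthomax_crit(unclass(vm$loadings), 1),
                 tolerance = 1e-7)
  }
})

test_that("alignment undoes signed permutations and matches brute force", {
  tm <- asNamespace("threemode")
  set.seed(88)
  ref <- tucker3_model(tm$rorth(12, 3), tm$rorth(7, 2), tm$rorth(5, 2),
                       array(rnorm(12), c(3, 2, 2)))
  expect_equal(align_solution(ref, ref)$A, ref$A)

  perm <- c(3, 1, 2); sgn <- c(-1, 1, -1)
  Tm <- matrix(0, 3, 3)
  for (j in 1:3) Tm[perm[j], j] <- sgn[j]
  scrambled <- tucker3_model(ref$A %*% Tm, ref$B, ref$C,
                             tm$ttm(ref$G, t(Tm), 1L))
  undone <- align_solution(scrambled, ref)
  expect_equal(undone$A, ref$A, tolerance = 1e-12)
  expect_equal(undone$G, ref$G, tolerance = 1e-12)
  expect_lt(max(abs(reconstruct(scrambled) - reconstruct(ref))), 1e-12)

  # brute force over all 3! * 2^3 signed permutations of a random solution
  sol <- tucker3_model(tm$rorth(12, 3), ref$B, ref$C, array(rnorm(12), c(3, 2, 2)))
  phi <- tm$congruence_matrix(sol$A, ref$A)
  best <- -Inf
  perms <- tm$permutations_of(3L)
  for (r in seq_len(nrow(perms)))
    best <- max(best, sum(abs(phi[cbind(perms[r, ], 1:3)])))
  al <- align_solution(sol, ref, modes = 1L)
  expect_equal(sum(diag(tm$congruence_matrix(al$A, ref$A))), best,
               tolerance = 1e-12)

  expect_error(align_solution(tucker3_model(tm$rorth(12, 2), ref$B, ref$C,
                                            array(0, c(2, 2, 2))), ref),
               "rank mismatch")
})

test_that("generalized Procrustes recovers a common solution from rotated copies", {
  tm <- asNamespace("threemode")
  x <- random_cube(c(15, 6, 4), 99)
  fit <- tucker3_als(x, c(2, 2, 2))
  set.seed(99)
  copies <- lapply(1:8, function(i) {
    mats <- list(fit$A, fit$B, fit$C); G <- fit$G
    for (n in 1:3) {
      Tn <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
      mats[[n]] <- mats[[n]] %*% Tn
      G <- tm$ttm(G, t(Tn), n)
    }
    tucker3_model(mats[[1]], mats[[2]], mats[[3]], G, fit_pct = fit$fit_pct)
  })
  gp <- generalized_procrustes(copies)
  expect_lt(max(gp$element_sd$A, gp$element_sd$B, gp$element_sd$C), 1e-8)
  expect_true(all(unlist(gp$per_dataset_congruence) >= 0.999))
  expect_lt(max(abs(reconstruct(gp$mean_model) - reconstruct(fit))), 1e-8)
  for (m in list(gp$mean_model$A, gp$mean_model$B, gp$mean_model$C))
    expect_lt(max(abs(crossprod(m) - diag(ncol(m)))), 1e-6)
})

test_that("pooling identical solutions returns them with zero spread", {
  x <- random_cube(c(10, 5, 4), 101)
  fit <- tucker3_als(x, c(2, 2, 2))
  gp <- generalized_procrustes(rep(list(fit), 20))
  expect_equal(gp$mean_model$A, fit$A, tolerance = 1e-10)
  expect_equal(gp$mean_model$G, fit$G, tolerance = 1e-8)
  expect_equal(max(gp$element_sd$G), 0, tolerance = 1e-10)
  expect_error(generalized_procrustes(list(fit)), "at least two")
})
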