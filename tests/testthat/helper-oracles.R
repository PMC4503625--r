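# Independent oracles used across tests. These deliberately avoid the
# package's own tensor primitives.

# Three-way ANOVA sums of squares via a saturated fixed-effects linear model
# (sequential SS are orthogonal under the balanced complete design).
anova_oracle <- function(v) {
  d <- dim(v)
  df <- expand.grid(i = factor(seq_len(d[1])), j = factor(seq_len(d[2])),
                    k = factor(seq_len(d[3])))
  df$y <- as.vector(v)
  fit <- stats::aov(y ~ i + j + k + i:j + i:k + j:k, data = df,
                    contrasts = list(i = "contr.sum", j = "contr.sum",
                                     k = "contr.sum"))
  tab <- summary(fit)[[1]]
  ssq <- tab[["Sum Sq"]]
  names(ssq) <- trimws(rownames(tab))
  c(persons = ssq[["i"]], symptoms = ssq[["j"]], time = ssq[["k"]],
    `persons:symptoms` = ssq[["i:j"]], `persons:time` = ssq[["i:k"]],
    `symptoms:time` = ssq[["j:k"]], `three-way+error` = ssq[["Residuals"]],
    total = sum((v - mean(v))^2))
}

# Truncated higher-order SVD fit percentage, with the core projection done
# by explicit summation.
hosvd_fit_oracle <- function(x, ranks) {
  d <- dim(x)
  A <- svd(matrix(x, d[1]))$u[, seq_len(ranks[1]), drop = FALSE]
  B <- svd(matrix(aperm(x, c(2, 1, 3)), d[2]))$u[, seq_len(ranks[2]), drop = FALSE]
  C <- svd(matrix(aperm(x, c(3, 1, 2)), d[3]))$u[, seq_len(ranks[3]), drop = FALSE]
  G <- array(0, ranks)
  for (p in seq_len(ranks[1]))
    for (q in seq_len(ranks[2]))
      for (r in seq_len(ranks[3])) {
        acc <- 0
        for (i in seq_len(d[1]))
          for (j in seq_len(d[2]))
            for (k in seq_len(d[3]))
              acc <- acc + A[i, p] * B[j, q] * C[k, r] * x[i, j, k]
        G[p, q, r] <- acc
      }
  100 * sum(G^2) / sum(x^2)
}

# column-wise congruence between equally-shaped matrices
col_congruence <- function(m1, m2) {
  vapply(seq_len(ncol(m1)), function(j) congruence(m1[, j], m2[, j]), 0)
}

random_cube <- function(dims, seed) {
  set.seed(seed)
  array(rnorm(prod(dims)), dims)
}

# small fitted pooled solution on perturbed copies of one planted cube
make_pooled <- function(seed = 1, n_sol = 4, dims = c(30, 8, 5),
                        ranks = c(2, 2, 2)) {
  sy <- generate_tucker3_dataset(
    synthetic_spec(dims = dims, ranks = ranks, noise_sd = NULL,
                   target_share = 0.7, n_external = 0, seed = seed))
  pre <- preprocess_cube(sy$dataset$values)
  set.seed(seed + 100)
  models <- lapply(seq_len(n_sol), function(i) {
    pert <- pre$data + array(rnorm(prod(dims), sd = 0.05), dims)
    tucker3_als(pert, ranks)
  })
  list(pooled = generalized_procrustes(models), pre = pre, synth = sy)
}
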