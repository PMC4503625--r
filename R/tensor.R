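# Internal dense three-way tensor algebra (mode-n unfolding, folding,
# tensor-times-matrix). Mode order: 1 = persons, 2 = items, 3 = time.

#' Matricize a three-way array along one mode
#'
#' Mode-n unfolding: mode 1 gives an I x (J*K) matrix whose columns run over
#' (j, k) with j varying fastest; modes 2 and 3 analogously.
#'
#' @param x three-way numeric array.
#' @param mode integer in 1:3.
#' @return a matrix with `dim(x)[mode]` rows.
#' @keywords internal
#' @noRd
unfold <- function(x, mode) {
  d <- dim(x)
  stopifnot(length(d) == 3L, mode %in% 1:3)
  perm <- switch(mode, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  matrix(aperm(x, perm), nrow = d[mode])
}

#' @noRd
fold <- function(m, mode, dims) {
  stopifnot(mode %in% 1:3, nrow(m) == dims[mode])
  perm <- switch(mode, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  inv <- order(perm)
  aperm(array(m, dims[perm]), inv)
}

#' Multiply a three-way array by a matrix along one mode
#'
#' Computes `x` x_mode `m`, i.e. the array whose mode-`mode` unfolding is
#' `m %*% unfold(x, mode)`.
#'
#' @noRd
ttm <- function(x, m, mode) {
  d <- dim(x)
  d2 <- d
  d2[mode] <- nrow(m)
  fold(m %*% unfold(x, mode), mode, d2)
}

# x multiplied along all three modes by matrices in `mats` (list of 3)
#' @noRd
ttm3 <- function(x, mats) {
  ttm(ttm(ttm(x, mats[[1L]], 1L), mats[[2L]], 2L), mats[[3L]], 3L)
}

#' @noRd
ss <- function(x) sum(x * x)

# random orthonormal columns (n x k), via QR of a Gaussian matrix with a
# deterministic sign fix (R's qr() sign is implementation-defined)
#' @noRd
rorth <- function(n, k) {
  q <- qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
  sweep(q, 2L, sign_convention_signs(q), `*`)
}

# signs flipping each column so its largest-magnitude entry is positive
#' @noRd
sign_convention_signs <- function(m) {
  apply(m, 2L, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
}

# run `expr` under a temporary RNG state seeded with `seed`;
# restores the caller's RNG state afterwards
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
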