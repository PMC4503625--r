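# Tucker3 (three-mode PCA) model fitting by alternating least squares.

#' Construct a Tucker3 model object
#'
#' A Tucker3 (three-mode principal component) model represents a three-way
#' array `X` (persons x items x time) as `G x1 A x2 B x3 C`: orthonormal
#' component matrices `A` (I x P, person mode), `B` (J x Q, symptom mode),
#' `C` (K x R, time mode), and a core array `G` (P x Q x R) whose entry
#' `g[p,q,r]` weights the triple interaction of person component p, symptom
#' component q and time component r.
#'
#' @param A,B,C component score matrices with orthonormal columns.
#' @param G numeric core array of dimension `c(ncol(A), ncol(B), ncol(C))`.
#' @param fit_pct percentage of the fitted array's sum of squares explained.
#' @param converged logical; did ALS meet its tolerance.
#' @param n_iter iterations used.
#' @param loss_history residual sum of squares per ALS iteration.
#' @return an object of class `tucker3_model`.
#' @export
tucker3_model <- function(A, B, C, G, fit_pct = NA_real_, converged = NA,
                          n_iter = NA_integer_, loss_history = numeric(0)) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  if (!identical(dim(G), c(ncol(A), ncol(B), ncol(C))))
    stop("core dimensions must equal (ncol(A), ncol(B), ncol(C))")
  structure(
    list(A = A, B = B, C = C, G = G,
         ranks = c(P = ncol(A), Q = ncol(B), R = ncol(C)),
         fit_pct = fit_pct, converged = converged, n_iter = n_iter,
         loss_history = loss_history),
    class = "tucker3_model")
}

#' @export
print.tucker3_model <- function(x, ...) {
  cat(sprintf("Tucker3 model: %d x %d x %d data, ranks (%d,%d,%d)\n",
              nrow(x$A), nrow(x$B), nrow(x$C),
              x$ranks[1], x$ranks[2], x$ranks[3]))
  if (is.finite(x$fit_pct))
    cat(sprintf("  fit: %.2f%%  (converged: %s, %d iterations)\n",
                x$fit_pct, x$converged, x$n_iter))
  invisible(x)
}

#' Check Tucker3 rank admissibility
#'
#' A rank triple (P,Q,R) is admissible when each rank does not exceed the
#' product of the other two (otherwise the extra components are redundant).
#'
#' @param ranks integer vector (P, Q, R).
#' @return logical.
#' @export
ranks_admissible <- function(ranks) {
  p <- ranks[1]; q <- ranks[2]; r <- ranks[3]
  all(ranks >= 1) && p <= q * r && q <= p * r && r <= p * q
}

check_ranks <- function(ranks, dims) {
  ranks <- as.integer(ranks)
  if (length(ranks) != 3L || anyNA(ranks))
    stop("ranks must be three integers (P, Q, R)")
  if (!ranks_admissible(ranks))
    stop(sprintf("inadmissible ranks (%d,%d,%d): each rank must be <= product of the other two",
                 ranks[1], ranks[2], ranks[3]))
  if (any(ranks > dims))
    stop("ranks may not exceed the array dimensions")
  ranks
}

leading_lsv <- function(m, k) {
  svd(m, nu = k, nv = 0)$u
}

#' Fit a Tucker3 model by alternating least squares
#'
#' TUCKALS-type algorithm: each mode's component matrix is updated to the
#' leading left singular vectors of the data matricized against the other two
#' modes' current projections; the core is the data projected onto all three
#' component spaces. Iterates until the relative fit change drops below `tol`.
#' With `init = "hosvd"` the first start uses the truncated higher-order SVD;
#' additional random starts (orthonormalized Gaussian matrices) can be
#' requested with `n_starts`, and the best fit wins.
#'
#' @param x numeric three-way array (complete; typically preprocessed).
#' @param ranks integer (P, Q, R), admissible and at most `dim(x)`.
#' @param init `"hosvd"` (default) or `"random"` for the first start.
#' @param n_starts number of starts (starts beyond the first are random).
#' @param tol relative fit-change convergence threshold.
#' @param max_iter maximum ALS iterations per start.
#' @param seed optional seed for the random starts.
#' @return a [tucker3_model()] with fit diagnostics; columns follow the sign
#'   convention that each component's largest-magnitude entry is positive
#'   (compensated in the core).
#' @export
tucker3_als <- function(x, ranks, init = c("hosvd", "random"), n_starts = 1L,
                        tol = 1e-8, max_iter = 1000L, seed = NULL) {
  init <- match.arg(init)
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("x must be a three-way array")
  if (!all(is.finite(x))) stop("x contains non-finite values")
  d <- dim(x)
  ranks <- check_ranks(ranks, d)
  ssx <- ss(x)
  if (ssx == 0) stop("cannot fit a Tucker3 model to an all-zero array")

  fit_one <- function(A, B, C) {
    loss <- numeric(0)
    prev_fit <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      A <- leading_lsv(unfold(ttm(ttm(x, t(B), 2L), t(C), 3L), 1L), ranks[1])
      B <- leading_lsv(unfold(ttm(ttm(x, t(A), 1L), t(C), 3L), 2L), ranks[2])
      C <- leading_lsv(unfold(ttm(ttm(x, t(A), 1L), t(B), 2L), 3L), ranks[3])
      G <- ttm3(x, list(t(A), t(B), t(C)))
      fit <- ss(G) / ssx
      loss <- c(loss, ssx - ss(G))
      if (abs(fit - prev_fit) < tol * max(fit, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      prev_fit <- fit
      if (iter >= max_iter) break
    }
    list(A = A, B = B, C = C, G = G, fit = fit, iter = iter,
         loss = loss, converged = converged)
  }

  hosvd_start <- function() {
    list(A = leading_lsv(unfold(x, 1L), ranks[1]),
         B = leading_lsv(unfold(x, 2L), ranks[2]),
         C = leading_lsv(unfold(x, 3L), ranks[3]))
  }
  random_start <- function() {
    list(A = rorth(d[1], ranks[1]),
         B = rorth(d[2], ranks[2]),
         C = rorth(d[3], ranks[3]))
  }

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(max(1L, n_starts))) {
      st <- if (s == 1L && init == "hosvd") hosvd_start() else random_start()
      res <- fit_one(st$A, st$B, st$C)
      if (is.null(best) || res$fit > best$fit) best <- res
    }
  })

  # deterministic column signs, compensated in the core
  sa <- sign_convention_signs(best$A)
  sb <- sign_convention_signs(best$B)
  sc <- sign_convention_signs(best$C)
  A <- sweep(best$A, 2L, sa, `*`)
  B <- sweep(best$B, 2L, sb, `*`)
  C <- sweep(best$C, 2L, sc, `*`)
  G <- best$G * outer(sa, outer(sb, sc))

  tucker3_model(A, B, C, G,
                fit_pct = 100 * best$fit,
                converged = best$converged,
                n_iter = best$iter,
                loss_history = best$loss)
}

#' Reconstruct the fitted array from a Tucker3 model
#'
#' @param model a [tucker3_model()].
#' @return the I x J x K array `G x1 A x2 B x3 C`.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "tucker3_model"))
  ttm3(model$G, list(model$A, model$B, model$C))
}

#' Fit percentage of a Tucker3 model on a data array
#'
#' `100 * (1 - SS(x - reconstruction) / SS(x))`.
#'
#' @param model a [tucker3_model()].
#' @param x the array the model is evaluated against.
#' @return a percentage.
#' @export
fit_percentage <- function(model, x) {
  stopifnot(inherits(model, "tucker3_model"))
  if (!identical(dim(x), c(nrow(model$A), nrow(model$B), nrow(model$C))))
    stop("array dimensions do not match the model")
  ssx <- ss(x)
  if (ssx == 0) stop("fit percentage undefined for an all-zero array")
  100 * (1 - ss(x - reconstruct(model)) / ssx)
}

#' Fit accounting including the general trend
#'
#' The model is fitted to the preprocessed cube (centered across persons,
#' normalized within symptom mode), so its fit percentage describes only the
#' heterogeneity around the general trend. This function also accounts for
#' the trend itself: on the symptom-normalized scale the full prediction for
#' cell (i,j,k) is `trend[j,k]/s[j] + xhat[i,j,k]`, and the total fit
#' percentage compares it against the completed raw cube on that same scale.
#'
#' @param model Tucker3 model fitted to the preprocessed cube.
#' @param state the [preprocessing_state()] that produced that cube.
#' @param raw completed raw-scale cube (array or [three_way_data()]), the one
#'   that was preprocessed.
#' @return a `fit_account` list: `heterogeneity_fit_pct`, `total_fit_pct`,
#'   `ss_trend`, `ss_model`, `ss_residual`, `ss_total` (all on the
#'   symptom-normalized scale).
#' @export
total_fit_with_trend <- function(model, state, raw) {
  stopifnot(inherits(model, "tucker3_model"),
            inherits(state, "preprocessing_state"))
  x <- cube_values(raw)
  d <- dim(x)
  if (!identical(d, c(nrow(model$A), nrow(model$B), nrow(model$C))))
    stop("raw cube dimensions do not match the model")
  if (!identical(dim(state$trend), d[2:3]) || length(state$scales) != d[2])
    stop("preprocessing state does not match the cube dimensions")
  if (anyNA(x)) stop("raw cube must be complete (imputed)")

  xs <- sweep(x, 2L, state$scales, `/`)                      # x_ijk / s_j
  trend_s <- sweep(state$trend, 1L, state$scales, `/`)       # M_jk / s_j
  pred <- reconstruct(model) +
    aperm(array(trend_s, c(d[2], d[3], d[1])), c(3L, 1L, 2L))
  ss_total <- ss(xs)
  ss_residual <- ss(xs - pred)
  ss_trend <- d[1] * ss(trend_s)
  preproc <- sweep(xs, c(2L, 3L), trend_s, `-`)
  ss_pre <- ss(preproc)
  structure(list(
    heterogeneity_fit_pct = 100 * (1 - ss(preproc - reconstruct(model)) / ss_pre),
    total_fit_pct = 100 * (1 - ss_residual / ss_total),
    ss_trend = ss_trend,
    ss_model = ss(reconstruct(model)),
    ss_residual = ss_residual,
    ss_total = ss_total), class = "fit_account")
}
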