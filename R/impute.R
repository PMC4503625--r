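# Multiple imputation of missing cube entries with a bootstrap-EM
# multivariate-normal imputer. The cube is flattened to a persons x
# (items * time points [+ covariates]) matrix; for each of the m
# imputations, persons are bootstrap-resampled, EM estimates the normal
# (mean, ridge-regularized covariance) on the resample, and every person's
# missing block is drawn from its conditional normal given that person's
# observed entries.

#' Multiply impute a three-way cube (bootstrap EM, multivariate normal)
#'
#' @param dataset a [three_way_data()] with missing cells; every person must
#'   have at least one observed cell and every (item, time) column at least
#'   one observation.
#' @param covariates optional complete numeric person x variable matrix or
#'   data frame (rows in person order) appended to the flattening so that
#'   auxiliary information informs the imputation model.
#' @param m number of imputations (the study convention is 20).
#' @param ridge covariance shrinkage toward its diagonal, expressed as a
#'   fraction of the sample size added as prior observations (default 0.005,
#'   i.e. 0.5% of the persons); needed because the flattening has roughly as
#'   many columns as rows.
#' @param max_em_iter,tol EM iteration cap and relative-change threshold.
#' @param seed integer seed; the whole set of m imputations is deterministic
#'   given the seed.
#' @return an `imputation_set`: `completed` (list of m complete
#'   [three_way_data()]s), `m`, `seed`, `em_iterations_used`,
#'   `em_converged`, `ridge`.
#' @export
em_bootstrap_impute <- function(dataset, covariates = NULL, m = 20L,
                                ridge = 0.005, max_em_iter = 200L,
                                tol = 1e-3, seed = NULL) {
  stopifnot(inherits(dataset, "three_way_data"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1")
  d <- dim(dataset$values)
  I <- d[1]
  y_cube <- unfold(dataset$values, 1L)              # I x (J*K)
  p_cube <- ncol(y_cube)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != I)
      stop("covariates must have one row per person")
    if (anyNA(covariates)) stop("covariates must be complete")
    y <- cbind(y_cube, covariates)
  } else y <- y_cube
  obs <- !is.na(y)
  if (any(rowSums(obs) == 0)) stop("every person needs >= 1 observed cell")
  if (any(colSums(obs) == 0)) {
    j <- which(colSums(obs) == 0)[1]
    stop(sprintf("column %d has no observed entries; cannot impute", j))
  }

  completed <- vector("list", m)
  iters <- integer(m)
  convs <- logical(m)

  if (!any(!obs[, seq_len(p_cube)])) {
    # nothing missing in the cube: m identical copies
    full <- three_way_data(dataset$values, person_ids = dataset$person_ids,
                           item_labels = dataset$item_labels,
                           time_labels = dataset$time_labels,
                           time_unit = dataset$time_unit)
    return(structure(list(completed = rep(list(full), m), m = m, seed = seed,
                          em_iterations_used = rep(0L, m),
                          em_converged = rep(TRUE, m), ridge = ridge),
                     class = "imputation_set"))
  }

  with_seed(seed, {
    for (imp in seq_len(m)) {
      rows <- sample.int(I, I, replace = TRUE)
      est <- em_mvnorm(y[rows, , drop = FALSE], ridge = ridge,
                       max_iter = max_em_iter, tol = tol)
      iters[imp] <- est$iterations
      convs[imp] <- est$converged
      if (!est$converged)
        warning(sprintf("imputation %d: EM not converged after %d iterations; using last iterate",
                        imp, est$iterations))
      filled <- draw_conditional(y, obs, est$mu, est$sigma)
      vals <- fold(filled[, seq_len(p_cube), drop = FALSE], 1L, d)
      completed[[imp]] <- three_way_data(
        vals, person_ids = dataset$person_ids,
        item_labels = dataset$item_labels,
        time_labels = dataset$time_labels, time_unit = dataset$time_unit)
    }
  })

  structure(list(completed = completed, m = m, seed = seed,
                 em_iterations_used = iters, em_converged = convs,
                 ridge = ridge),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("imputation_set: m = %d completions (ridge %.4g; EM iterations %s)\n",
              x$m, x$ridge, paste(x$em_iterations_used, collapse = ",")))
  invisible(x)
}

# EM for a multivariate normal with missing entries; covariance shrunk
# toward its diagonal with prior weight h = ridge * n pseudo-observations.
#' @noRd
em_mvnorm <- function(y, ridge, max_iter, tol) {
  n <- nrow(y); p <- ncol(y)
  obs <- !is.na(y)
  mu <- colMeans(y, na.rm = TRUE)
  y0 <- y
  y0[!obs] <- matrix(mu, n, p, byrow = TRUE)[!obs]
  sigma <- stats::cov(y0) * (n - 1) / n
  sigma <- regularize_cov(sigma, ridge, n)
  patterns <- apply(obs, 1L, function(r) paste(which(!r), collapse = ","))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    K <- chol2inv(chol(sigma))
    yhat <- y
    cc <- matrix(0, p, p)   # accumulated conditional covariances
    for (pat in unique(patterns)) {
      if (pat == "") next
      rows <- which(patterns == pat)
      mis <- as.integer(strsplit(pat, ",", fixed = TRUE)[[1]])
      Kmm_inv <- chol2inv(chol(K[mis, mis, drop = FALSE]))
      for (r in rows) {
        o <- which(obs[r, ])
        dev <- y[r, o] - mu[o]
        yhat[r, mis] <- mu[mis] -
          Kmm_inv %*% (K[mis, o, drop = FALSE] %*% dev)
      }
      cc[mis, mis] <- cc[mis, mis] + length(rows) * Kmm_inv
    }
    mu_new <- colMeans(yhat)
    centered <- sweep(yhat, 2L, mu_new)
    sigma_new <- (crossprod(centered) + cc) / n
    sigma_new <- regularize_cov(sigma_new, ridge, n)
    delta <- max(max(abs(mu_new - mu)) / max(1, max(abs(mu))),
                 max(abs(sigma_new - sigma)) / max(1, max(abs(sigma))))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(mu = mu, sigma = sigma, iterations = it, converged = converged)
}

#' @noRd
regularize_cov <- function(sigma, ridge, n) {
  h <- ridge * n
  s <- (n * sigma + h * diag(diag(sigma), nrow(sigma))) / (n + h)
  # guard against numerically semi-definite diagonals
  eps <- 1e-10 * mean(diag(s))
  s + diag(eps, nrow(s))
}

# draw missing entries of y from N(mu, sigma) conditional on each person's
# observed entries (via the precision matrix, so only small solves per
# missingness pattern are needed)
#' @noRd
draw_conditional <- function(y, obs, mu, sigma) {
  n <- nrow(y)
  K <- chol2inv(chol(sigma))
  patterns <- apply(obs, 1L, function(r) paste(which(!r), collapse = ","))
  out <- y
  for (pat in unique(patterns)) {
    if (pat == "") next
    rows <- which(patterns == pat)
    mis <- as.integer(strsplit(pat, ",", fixed = TRUE)[[1]])
    cond_cov <- chol2inv(chol(K[mis, mis, drop = FALSE]))
    ch <- chol(cond_cov)
    for (r in rows) {
      o <- which(obs[r, ])
      dev <- y[r, o] - mu[o]
      cmean <- mu[mis] - cond_cov %*% (K[mis, o, drop = FALSE] %*% dev)
      out[r, mis] <- cmean + t(ch) %*% stats::rnorm(length(mis))
    }
  }
  out
}
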