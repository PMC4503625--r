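# Orthogonal rotations of Tucker3 solutions: Joint Orthomax for
# interpretability, congruence-based alignment, and generalized Procrustes
# pooling of per-imputation solutions. All operations are orthogonal and
# compensated in the core, so the reconstruction (and hence fit) never
# changes.

#' Tucker congruence coefficient
#'
#' Cosine similarity between two component vectors:
#' `phi = sum(u*v) / sqrt(sum(u^2) * sum(v^2))`. Values near 1 indicate
#' equivalent components; the coefficient is invariant to positive scaling.
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
congruence <- function(u, v) {
  su <- sum(u * u); sv <- sum(v * v)
  if (su == 0 || sv == 0) stop("congruence undefined for a zero vector")
  sum(u * v) / sqrt(su * sv)
}

# column-by-column congruence matrix (rows: columns of m1, cols: of m2)
#' @noRd
congruence_matrix <- function(m1, m2) {
  n1 <- sqrt(colSums(m1^2)); n2 <- sqrt(colSums(m2^2))
  (crossprod(m1, m2)) / outer(n1, n2)
}

#' Rotation weights for Joint Orthomax
#'
#' The criterion is a weighted sum of orthomax simplicity of the core (along
#' its three matricizations, weight `w_core` each) and of the three component
#' matrices. The standard (natural) preset weighs each mode matrix by the
#' ratio of core elements to matrix elements, `P*Q*R / (dim * rank)`, and —
#' following common practice for person-mode scores, which are not directly
#' interpreted — sets the person-mode weight to zero.
#'
#' @param dims data dimensions (I, J, K).
#' @param ranks component counts (P, Q, R).
#' @param gamma orthomax family parameter (1 = varimax).
#' @param w_core core-simplicity weight per matricization.
#' @param w_mode length-3 nonnegative weights for the person, symptom and
#'   time component matrices; `NULL` for the standard preset.
#' @return object of class `rotation_weights`.
#' @export
rotation_weights <- function(dims, ranks, gamma = 1, w_core = 1,
                             w_mode = NULL) {
  if (is.null(w_mode)) {
    w_mode <- prod(ranks) / (dims * ranks)
    w_mode[1] <- 0
  }
  if (length(w_mode) != 3L || any(w_mode < 0) || w_core < 0)
    stop("weights must be three nonnegative mode weights and w_core >= 0")
  if (w_core == 0 && all(w_mode == 0)) stop("at least one weight must be > 0")
  structure(list(gamma = gamma, w_core = w_core, w_mode = w_mode),
            class = "rotation_weights")
}

# orthomax simplicity of the columns of m: sum_j [ sum_i m_ij^4
#   - (gamma/n) (sum_i m_ij^2)^2 ]
#' @noRd
orthomax_crit <- function(m, gamma) {
  m2 <- m * m
  sum(m2 * m2) - (gamma / nrow(m)) * sum(colSums(m2)^2)
}

# the joint criterion for a current (G, A, B, C) configuration
#' @noRd
joint_crit <- function(G, mats, weights) {
  val <- 0
  if (weights$w_core > 0)
    for (n in 1:3)
      val <- val + weights$w_core * orthomax_crit(t(unfold(G, n)), weights$gamma)
  for (n in 1:3)
    if (weights$w_mode[n] > 0)
      val <- val + weights$w_mode[n] * orthomax_crit(mats[[n]], weights$gamma)
  val
}

# apply a plane rotation by theta to columns (c1, c2) of mode `n`:
# component columns post-multiplied, core rows (in the mode-n unfolding)
# counter-rotated.
#' @noRd
apply_plane <- function(G, mats, n, c1, c2, theta) {
  cs <- cos(theta); sn <- sin(theta)
  m <- mats[[n]]
  a <- m[, c1]; b <- m[, c2]
  m[, c1] <- cs * a + sn * b
  m[, c2] <- -sn * a + cs * b
  mats[[n]] <- m
  gu <- unfold(G, n)
  ga <- gu[c1, ]; gb <- gu[c2, ]
  gu[c1, ] <- cs * ga + sn * gb
  gu[c2, ] <- -sn * ga + cs * gb
  list(G = fold(gu, n, dim(G)), mats = mats)
}

#' Joint Orthomax rotation of a Tucker3 solution
#'
#' Orthogonally rotates the component matrices (post-multiplication) with the
#' core counter-rotated, maximizing a weighted sum of orthomax simplicity of
#' the core array (along all three matricizations) and of the component
#' matrices. Uses Jacobi plane rotations; for any plane rotation the joint
#' criterion is exactly `a + b*cos(4t) + c*sin(4t)`, so the optimal angle is
#' obtained analytically from four criterion evaluations. Sweeps over modes
#' (symptom, time, person order) until the criterion gain per sweep drops
#' below `tol`. The reconstruction is unchanged.
#'
#' @param model a [tucker3_model()] with orthonormal component matrices.
#' @param weights a [rotation_weights()]; default: standard preset for the
#'   model's shape.
#' @param tol minimal relative criterion gain per sweep.
#' @param max_sweeps sweep cap.
#' @return rotated [tucker3_model()] with attribute `"criterion_history"`.
#' @export
joint_orthomax <- function(model, weights = NULL, tol = 1e-10,
                           max_sweeps = 100L) {
  stopifnot(inherits(model, "tucker3_model"))
  for (m in list(model$A, model$B, model$C))
    if (max(abs(crossprod(m) - diag(ncol(m)))) > 1e-8)
      stop("model component matrices must have orthonormal columns")
  if (is.null(weights))
    weights <- rotation_weights(c(nrow(model$A), nrow(model$B), nrow(model$C)),
                                model$ranks)
  G <- model$G
  mats <- list(model$A, model$B, model$C)
  ranks <- model$ranks
  crit <- joint_crit(G, mats, weights)
  history <- crit
  scale_ref <- max(abs(crit), 1)

  for (sweep_i in seq_len(max_sweeps)) {
    crit_before <- crit
    for (n in c(2L, 3L, 1L)) {
      if (ranks[n] < 2L) next
      pairs <- utils::combn(ranks[n], 2L)
      for (pp in seq_len(ncol(pairs))) {
        c1 <- pairs[1, pp]; c2 <- pairs[2, pp]
        f <- function(theta) {
          st <- apply_plane(G, mats, n, c1, c2, theta)
          joint_crit(st$G, st$mats, weights)
        }
        # exact trig interpolation: f(t) = a + b cos 4t + c sin 4t
        f0 <- f(0); f1 <- f(pi / 8); f2 <- f(-pi / 8); f3 <- f(pi / 4)
        a <- (f0 + f3) / 2
        b <- (f0 - f3) / 2
        cc <- (f1 - f2) / 2
        if (b == 0 && cc == 0) next
        theta <- atan2(cc, b) / 4
        gain <- a + sqrt(b^2 + cc^2) - f0
        if (gain > 0) {
          st <- apply_plane(G, mats, n, c1, c2, theta)
          G <- st$G; mats <- st$mats
          crit <- joint_crit(G, mats, weights)
        }
      }
    }
    history <- c(history, crit)
    if (crit - crit_before < tol * scale_ref) break
  }

  out <- tucker3_model(mats[[1]], mats[[2]], mats[[3]], G,
                       fit_pct = model$fit_pct, converged = model$converged,
                       n_iter = model$n_iter,
                       loss_history = model$loss_history)
  attr(out, "criterion_history") <- history
  out
}

# signed permutation matrix maximizing total absolute congruence of
# sol columns with ref columns; brute force over permutations (ranks here
# are small). Returns the k x k orthogonal matrix T with sol %*% T aligned.
#' @noRd
best_signed_permutation <- function(phi) {
  k <- ncol(phi)
  perms <- permutations_of(k)
  best <- NULL; best_val <- -Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    val <- sum(abs(phi[cbind(p, seq_len(k))]))
    if (val > best_val) { best_val <- val; best <- p }
  }
  T <- matrix(0, k, k)
  for (j in seq_len(k)) {
    s <- sign(phi[best[j], j])
    if (s == 0) s <- 1
    T[best[j], j] <- s
  }
  T
}

#' @noRd
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- NULL
  for (pos in seq_len(k)) {
    ins <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                 sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

#' Align a Tucker3 solution with a reference
#'
#' Per mode, permutes and sign-flips the solution's columns to maximize the
#' total absolute congruence with the reference's columns (exhaustive
#' assignment over signed permutations); the core is counter-transformed, so
#' the reconstruction is unchanged.
#'
#' @param solution,reference [tucker3_model()]s with equal ranks.
#' @param modes which modes to align (default all three; use `c(2, 3)` when
#'   the person mode is not comparable, e.g. across split halves).
#' @param method `"permutation"` (default) restricts the alignment to signed
#'   column permutations; `"procrustes"` allows any orthogonal rotation
#'   toward the reference (appropriate when comparing a fitted subspace with
#'   a planted truth whose within-subspace orientation is arbitrary).
#' @return aligned [tucker3_model()].
#' @export
align_solution <- function(solution, reference, modes = 1:3,
                           method = c("permutation", "procrustes")) {
  stopifnot(inherits(solution, "tucker3_model"),
            inherits(reference, "tucker3_model"))
  method <- match.arg(method)
  if (!identical(unname(solution$ranks), unname(reference$ranks)))
    stop("rank mismatch between solution and reference")
  mats <- list(solution$A, solution$B, solution$C)
  refs <- list(reference$A, reference$B, reference$C)
  G <- solution$G
  for (n in modes) {
    if (method == "procrustes") {
      sv <- svd(crossprod(mats[[n]], refs[[n]]))
      Tn <- sv$u %*% t(sv$v)
      mats[[n]] <- mats[[n]] %*% Tn
      G <- ttm(G, t(Tn), n)
      next
    }
    if (solution$ranks[n] < 2L) {
      # only the sign can differ
      s <- sign(congruence(mats[[n]][, 1], refs[[n]][, 1]))
      if (s == 0) s <- 1
      Tn <- matrix(s, 1L, 1L)
    } else {
      Tn <- best_signed_permutation(congruence_matrix(mats[[n]], refs[[n]]))
    }
    mats[[n]] <- mats[[n]] %*% Tn
    G <- ttm(G, t(Tn), n)
  }
  tucker3_model(mats[[1]], mats[[2]], mats[[3]], G,
                fit_pct = solution$fit_pct, converged = solution$converged,
                n_iter = solution$n_iter,
                loss_history = solution$loss_history)
}

#' Generalized Procrustes pooling of Tucker3 solutions
#'
#' Iteratively rotates each solution's component matrices (orthogonal
#' Procrustes, cores counter-rotated) toward the running element-wise mean,
#' then averages. Yields a pooled mean model, element-wise standard
#' deviations across solutions, and per-solution, per-column congruences with
#' the mean — the device used to combine the per-imputation solutions into
#' one reportable solution.
#'
#' @param solutions list of >= 2 [tucker3_model()]s with equal dims/ranks
#'   (e.g. one per imputed dataset).
#' @param tol convergence threshold on the mean change.
#' @param max_iter iteration cap (warning on non-convergence).
#' @return object of class `pooled_solution`: `mean_model` (orthonormality
#'   restored by polar orthogonalization, absorbed into the core),
#'   `element_sd` (same-shaped arrays for A, B, C, G), `per_dataset_congruence`
#'   (list per mode: solutions x columns matrices), `rotated` (the rotated
#'   inputs), `n_iter`, `converged`.
#' @export
generalized_procrustes <- function(solutions, tol = 1e-10, max_iter = 200L) {
  if (length(solutions) < 2L) stop("need at least two solutions to pool")
  r0 <- unname(solutions[[1]]$ranks)
  d0 <- c(nrow(solutions[[1]]$A), nrow(solutions[[1]]$B), nrow(solutions[[1]]$C))
  for (s in solutions) {
    stopifnot(inherits(s, "tucker3_model"))
    if (!identical(unname(s$ranks), r0) ||
        !identical(c(nrow(s$A), nrow(s$B), nrow(s$C)), d0))
      stop("all solutions must share dimensions and ranks")
  }
  # align everything to the first solution so GPA starts near the optimum
  sols <- lapply(solutions, align_solution, reference = solutions[[1]])
  get_mats <- function(s) list(s$A, s$B, s$C)
  mats <- lapply(sols, get_mats)
  cores <- lapply(sols, `[[`, "G")

  mean_mats <- function() lapply(1:3, function(n)
    Reduce(`+`, lapply(mats, `[[`, n)) / length(mats))

  mm <- mean_mats()
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    for (s in seq_along(mats)) {
      for (n in 1:3) {
        sv <- svd(crossprod(mats[[s]][[n]], mm[[n]]))
        Tn <- sv$u %*% t(sv$v)
        mats[[s]][[n]] <- mats[[s]][[n]] %*% Tn
        cores[[s]] <- ttm(cores[[s]], t(Tn), n)
      }
    }
    mm_new <- mean_mats()
    delta <- max(vapply(1:3, function(n) max(abs(mm_new[[n]] - mm[[n]])), 0))
    mm <- mm_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized Procrustes did not converge; using last iterate")

  mean_core <- Reduce(`+`, cores) / length(cores)
  # restore orthonormality by polar decomposition, absorbed into the core
  G <- mean_core
  orth <- vector("list", 3L)
  for (n in 1:3) {
    sv <- svd(mm[[n]])
    orth[[n]] <- sv$u %*% t(sv$v)
    H <- sv$v %*% diag(sv$d, length(sv$d)) %*% t(sv$v)   # (M'M)^(1/2)
    G <- ttm(G, H, n)
  }
  mean_model <- tucker3_model(orth[[1]], orth[[2]], orth[[3]], G,
                              fit_pct = mean(vapply(solutions, `[[`, 0, "fit_pct")))

  sd_arr <- function(get) {
    vals <- lapply(seq_along(mats), function(s) get(s))
    m1 <- Reduce(`+`, vals) / length(vals)
    sqrt(Reduce(`+`, lapply(vals, function(v) (v - m1)^2)) / (length(vals) - 1))
  }
  element_sd <- list(
    A = sd_arr(function(s) mats[[s]][[1]]),
    B = sd_arr(function(s) mats[[s]][[2]]),
    C = sd_arr(function(s) mats[[s]][[3]]),
    G = sd_arr(function(s) cores[[s]]))

  congr <- lapply(1:3, function(n)
    t(vapply(seq_along(mats),
             function(s) diag(congruence_matrix(mats[[s]][[n]], orth[[n]])),
             numeric(r0[n]))))
  names(congr) <- c("person", "symptom", "time")

  rotated <- lapply(seq_along(mats), function(s)
    tucker3_model(mats[[s]][[1]], mats[[s]][[2]], mats[[s]][[3]], cores[[s]],
                  fit_pct = solutions[[s]]$fit_pct))

  structure(list(mean_model = mean_model, element_sd = element_sd,
                 per_dataset_congruence = congr, rotated = rotated,
                 n_iter = iters, converged = converged),
            class = "pooled_solution")
}

#' @export
print.pooled_solution <- function(x, ...) {
  cat(sprintf("pooled Tucker3 solution over %d datasets (GPA, %d iterations)\n",
              length(x$rotated), x$n_iter))
  cat(sprintf("  max element sd: A %.4f, B %.4f, C %.4f, core %.4f\n",
              max(x$element_sd$A), max(x$element_sd$B),
              max(x$element_sd$C), max(x$element_sd$G)))
  invisible(x)
}
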