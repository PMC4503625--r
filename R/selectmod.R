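# Model complexity selection (generalized scree over all admissible rank
# triples, convex hull on total component count vs. fit) and stability
# assessment (cross-imputation congruence, split-half congruence).

#' Fit all admissible rank triples on every imputed dataset
#'
#' Each imputed cube is preprocessed (its own centering and normalization)
#' and a Tucker3 model fitted at every admissible rank triple up to
#' `max_ranks`. Entries are flagged as convex-hull-optimal on the
#' (total components S = P+Q+R, mean fit) plane: for each S the best mean
#' fit is taken, and the upper convex hull of those points marks the
#' complexities with the best fit-per-component trade-off.
#'
#' @param imputations an `imputation_set`, or a list of complete
#'   [three_way_data()] / arrays.
#' @param max_ranks (Pmax, Qmax, Rmax), each at most the matching dimension.
#' @param keep_models if `TRUE`, the fitted models are retained per entry
#'   (needed by [select_complexity()]'s stability screen).
#' @param ... passed to [tucker3_als()] (e.g. `tol`, `n_starts`).
#' @return a `scree_grid`: data frame `entries` with columns `P`, `Q`, `R`,
#'   `S`, `mean_fit`, `sd_fit`, `hull`, plus per-imputation fit columns;
#'   `models` (list of lists, or `NULL`).
#' @export
scree_grid <- function(imputations, max_ranks, keep_models = TRUE, ...) {
  cubes <- imputation_cubes(imputations)
  d <- dim(cubes[[1]])
  max_ranks <- as.integer(max_ranks)
  if (any(max_ranks > d)) stop("max_ranks may not exceed the data dimensions")
  pre <- lapply(cubes, function(x) preprocess_cube(x)$data)

  triples <- expand.grid(P = seq_len(max_ranks[1]), Q = seq_len(max_ranks[2]),
                         R = seq_len(max_ranks[3]))
  adm <- apply(triples, 1L, function(r) ranks_admissible(as.integer(r)))
  triples <- triples[adm, , drop = FALSE]

  fits <- matrix(NA_real_, nrow(triples), length(pre))
  models <- if (keep_models) vector("list", nrow(triples)) else NULL
  for (e in seq_len(nrow(triples))) {
    rk <- as.integer(triples[e, ])
    row_models <- vector("list", length(pre))
    for (i in seq_along(pre)) {
      fit <- tryCatch(tucker3_als(pre[[i]], rk, ...),
                      error = function(err)
                        stop(sprintf("rank (%d,%d,%d), imputation %d: %s",
                                     rk[1], rk[2], rk[3], i,
                                     conditionMessage(err))))
      fits[e, i] <- fit$fit_pct
      row_models[[i]] <- fit
    }
    if (keep_models) models[[e]] <- row_models
  }

  entries <- data.frame(
    P = triples$P, Q = triples$Q, R = triples$R,
    S = triples$P + triples$Q + triples$R,
    mean_fit = rowMeans(fits),
    sd_fit = if (length(pre) > 1) apply(fits, 1L, stats::sd) else 0)
  colnames(fits) <- paste0("fit_imp", seq_along(pre))
  entries$hull <- hull_flags(entries$S, entries$mean_fit)
  entries <- cbind(entries, fits)
  structure(list(entries = entries, models = models,
                 max_ranks = max_ranks, dims = d, m = length(pre)),
            class = "scree_grid")
}

# upper-convex-hull flags on (S, fit): for each S keep the best fit; the
# hull is the concave majorant over S (increasing fit, decreasing slope)
#' @noRd
hull_flags <- function(S, fit) {
  flags <- logical(length(S))
  best_at_s <- tapply(seq_along(S), S, function(ix) ix[which.max(fit[ix])])
  s_vals <- as.numeric(names(best_at_s))
  ord <- order(s_vals)
  cand_idx <- as.integer(best_at_s)[ord]
  s_vals <- s_vals[ord]
  # keep only candidates strictly better than every smaller-S candidate
  keep <- rep(TRUE, length(cand_idx))
  running <- -Inf
  for (i in seq_along(cand_idx)) {
    if (fit[cand_idx[i]] <= running) keep[i] <- FALSE
    else running <- fit[cand_idx[i]]
  }
  cand_idx <- cand_idx[keep]; s_vals <- s_vals[keep]
  # Andrew-style scan enforcing decreasing slopes (concave upper hull)
  hull <- integer(0)
  for (i in seq_along(cand_idx)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      sl_ab <- (fit[b] - fit[a]) / (S[b] - S[a])
      sl_bc <- (fit[cand_idx[i]] - fit[b]) / (S[cand_idx[i]] - S[b])
      if (sl_bc >= sl_ab) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, cand_idx[i])
  }
  flags[hull] <- TRUE
  flags
}

#' @export
print.scree_grid <- function(x, ...) {
  cat(sprintf("scree grid: %d admissible rank triples x %d imputations (max ranks %s)\n",
              nrow(x$entries), x$m, paste(x$max_ranks, collapse = ",")))
  print(x$entries[x$entries$hull,
                  c("P", "Q", "R", "S", "mean_fit", "sd_fit")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

# smallest per-column cross-imputation congruence of the symptom and time
# component matrices, after aligning every model to the first
#' @noRd
cross_imputation_congruence <- function(models) {
  if (length(models) < 2L) return(1)
  ref <- models[[1]]
  vals <- c()
  for (i in seq_along(models)[-1]) {
    al <- align_solution(models[[i]], ref)
    vals <- c(vals,
              diag(congruence_matrix(al$B, ref$B)),
              diag(congruence_matrix(al$C, ref$C)))
  }
  min(vals)
}

#' Choose the model complexity from a scree grid
#'
#' Among convex-hull entries, computes each interior hull point's scree
#' salience (the ratio of the per-component fit gain up to that point to the
#' gain beyond it); higher salience marks the elbow. Candidates whose
#' solutions are unstable across imputations (smallest cross-imputation
#' symptom/time component congruence below `stability_threshold`) are
#' screened out first. Ties and near-ties resolve toward fewer total
#' components.
#'
#' @param grid a [scree_grid()] (fitted with `keep_models = TRUE`, unless
#'   `stability` is supplied).
#' @param stability optional named numeric vector of smallest
#'   cross-imputation congruences, named `"P,Q,R"`; computed from the grid's
#'   stored models when `NULL`.
#' @param stability_threshold smallest acceptable congruence (default 0.85).
#' @return list: `ranks` (named integer triple), `trace` (data frame of hull
#'   candidates with salience, stability and the decision).
#' @export
select_complexity <- function(grid, stability = NULL,
                              stability_threshold = 0.85) {
  stopifnot(inherits(grid, "scree_grid"))
  ent <- grid$entries
  hull <- ent[ent$hull, , drop = FALSE]
  if (nrow(hull) == 0L) stop("empty convex hull; cannot select complexity")
  hull <- hull[order(hull$S), , drop = FALSE]

  key <- function(p, q, r) paste(p, q, r, sep = ",")
  if (is.null(stability)) {
    if (is.null(grid$models) || grid$m < 2L) {
      stability <- stats::setNames(rep(1, nrow(hull)),
                                   key(hull$P, hull$Q, hull$R))
    } else {
      stability <- vapply(seq_len(nrow(hull)), function(i) {
        e <- which(ent$P == hull$P[i] & ent$Q == hull$Q[i] & ent$R == hull$R[i])
        cross_imputation_congruence(grid$models[[e]])
      }, 0)
      names(stability) <- key(hull$P, hull$Q, hull$R)
    }
  }
  hull$stability <- stability[key(hull$P, hull$Q, hull$R)]
  hull$stability[is.na(hull$stability)] <- 1

  n <- nrow(hull)
  sal <- rep(NA_real_, n)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      gain_in <- (hull$mean_fit[i] - hull$mean_fit[i - 1]) /
        (hull$S[i] - hull$S[i - 1])
      gain_out <- (hull$mean_fit[i + 1] - hull$mean_fit[i]) /
        (hull$S[i + 1] - hull$S[i])
      sal[i] <- if (gain_out <= 0) Inf else gain_in / gain_out
    }
  }
  hull$salience <- sal

  stable <- hull$stability >= stability_threshold
  cand <- which(!is.na(sal) & stable)
  if (length(cand) == 0L) cand <- which(stable)
  if (length(cand) == 0L) cand <- seq_len(n)
  # highest salience; ties (within 1e-8) toward fewer total components
  sal_c <- hull$salience[cand]
  sal_c[is.na(sal_c)] <- -Inf
  best_sal <- max(sal_c)
  tied <- cand[sal_c >= best_sal - 1e-8]
  pick <- tied[which.min(hull$S[tied])]

  hull$selected <- seq_len(n) == pick
  list(ranks = c(P = hull$P[pick], Q = hull$Q[pick], R = hull$R[pick]),
       trace = hull[, c("P", "Q", "R", "S", "mean_fit", "sd_fit",
                        "stability", "salience", "selected")])
}

#' Split-half stability of a Tucker3 solution
#'
#' Randomly halves the persons, preprocesses and fits each half
#' independently at the given ranks (rotation applied when `weights` given),
#' aligns the halves' symptom and time components, and records the
#' per-column congruence between halves. Person components are not compared
#' (the halves share no persons). Repeated `n_splits` times.
#'
#' @param x complete cube (array or [three_way_data()]).
#' @param ranks rank triple to fit.
#' @param n_splits number of random splits (default 10).
#' @param weights optional [rotation_weights()] applied to each half's fit.
#' @param seed integer seed.
#' @param ... passed to [tucker3_als()].
#' @return a `stability_report`: `per_split_congruence` (data frame: split,
#'   mode, component, phi), `min_congruence`, `n_splits`, `seed`.
#' @export
split_half_stability <- function(x, ranks, n_splits = 10L, weights = NULL,
                                 seed = NULL, ...) {
  v <- cube_values(x)
  if (anyNA(v)) stop("cube must be complete (impute first)")
  d <- dim(v)
  if (d[1] < 4L) stop("need at least 4 persons to split")
  ranks <- check_ranks(ranks, c(floor(d[1] / 2), d[2], d[3]))

  half_fit <- function(idx) {
    pre <- preprocess_cube(v[idx, , , drop = FALSE])$data
    fit <- tucker3_als(pre, ranks, ...)
    if (!is.null(weights)) fit <- joint_orthomax(fit, weights)
    fit
  }

  rows <- with_seed(seed, {
    out <- vector("list", n_splits)
    for (s in seq_len(n_splits)) {
      idx <- sample.int(d[1], floor(d[1] / 2))
      f1 <- half_fit(idx)
      f2 <- align_solution(half_fit(setdiff(seq_len(d[1]), idx)), f1,
                           modes = c(2L, 3L))
      phi_b <- diag(congruence_matrix(f2$B, f1$B))
      phi_c <- diag(congruence_matrix(f2$C, f1$C))
      out[[s]] <- data.frame(
        split = s,
        mode = c(rep("symptom", length(phi_b)), rep("time", length(phi_c))),
        component = c(seq_along(phi_b), seq_along(phi_c)),
        phi = c(phi_b, phi_c))
    }
    do.call(rbind, out)
  })

  structure(list(per_split_congruence = rows,
                 min_congruence = min(rows$phi),
                 n_splits = as.integer(n_splits), seed = seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("split-half stability: %d splits, min congruence %.3f\n",
              x$n_splits, x$min_congruence))
  invisible(x)
}

# list of complete value arrays from an imputation_set or a plain list
#' @noRd
imputation_cubes <- function(imputations) {
  cubes <- if (inherits(imputations, "imputation_set")) imputations$completed
           else imputations
  lapply(cubes, function(x) {
    v <- cube_values(x)
    if (anyNA(v)) stop("imputed cubes must be complete")
    v
  })
}
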