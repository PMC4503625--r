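# Synthetic longitudinal symptom cubes with a planted Tucker3 structure,
# a shared declining general trend, Gaussian noise, missingness and
# external covariates tied to the person components. Every downstream
# stage of the pipeline is testable against the recorded truth.

#' Specification for a synthetic Tucker3 symptom cube
#'
#' @param dims (I, J, K): persons, items, time points. Default emulates the
#'   depression cohort shape: 219 persons x 21 questionnaire items x 9
#'   three-monthly assessments.
#' @param ranks planted component counts (P, Q, R); must be admissible.
#' @param core_pattern data frame / matrix with columns `p, q, r, magnitude`
#'   giving the nonzero planted core entries (on the preprocessed scale).
#' @param trend J x K matrix of mean item trajectories added to every person
#'   (score units); `NULL` for the default declining-trajectory family
#'   ([default_trend()]).
#' @param noise_sd standard deviation of i.i.d. additive Gaussian noise. Use
#'   [calibrate_noise_sd()] to target a structural share of the
#'   post-preprocessing sum of squares.
#' @param target_share optional fraction in (0, 1); when set, `noise_sd` is
#'   ignored and the noise level is solved per realization so that the
#'   planted structure carries exactly this expected share of the
#'   post-preprocessing sum of squares (accounts for the per-item
#'   renormalization, which a global calibration cannot).
#' @param missing_rate fraction of cells masked, in \[0, 1).
#' @param missing_mechanism `"MCAR"` or `"MAR-by-time"` (missingness odds
#'   multiplied by 1.5 per later time point, dropout-like).
#' @param score_bounds `NULL` for unbounded continuous scores, or
#'   `c(min, max)` for rounding and clipping to an integer item range
#'   (e.g. `c(0, 3)`); clipping breaks exact recovery and is meant for
#'   realism tests only.
#' @param n_external number of external person-level covariates.
#' @param external_loadings n_external x P matrix; entry (e, p) is the
#'   intended correlation of covariate e with standardized person-component
#'   score p (row sums of squares must be <= 1; the remainder is independent
#'   noise).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dims = c(219L, 21L, 9L), ranks = c(3L, 2L, 2L),
                           core_pattern = NULL, trend = NULL, noise_sd = 1,
                           missing_rate = 0, missing_mechanism = "MCAR",
                           score_bounds = NULL, n_external = 0L,
                           external_loadings = NULL, seed = 1L,
                           target_share = NULL, target_total_share = NULL) {
  if (!is.null(target_share) &&
      (target_share <= 0 || target_share >= 1))
    stop("target_share must be in (0, 1)")
  if (!is.null(target_total_share)) {
    if (is.null(target_share))
      stop("target_total_share requires target_share")
    if (target_total_share <= target_share || target_total_share >= 1)
      stop("target_total_share must lie in (target_share, 1)")
  }
  dims <- as.integer(dims); ranks <- as.integer(ranks)
  if (any(dims < 2)) stop("all dims must be >= 2")
  if (!ranks_admissible(ranks))
    stop("inadmissible ranks: each rank must be <= product of the other two")
  if (any(ranks > dims)) stop("ranks may not exceed dims")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  missing_mechanism <- match.arg(missing_mechanism, c("MCAR", "MAR-by-time"))
  if (is.null(core_pattern)) core_pattern <- default_core_pattern(ranks)
  core_pattern <- as.data.frame(core_pattern)
  stopifnot(all(c("p", "q", "r", "magnitude") %in% names(core_pattern)))
  if (any(core_pattern$p > ranks[1] | core_pattern$q > ranks[2] |
          core_pattern$r > ranks[3] | core_pattern$p < 1 |
          core_pattern$q < 1 | core_pattern$r < 1))
    stop("core_pattern indices out of rank range")
  if (is.null(trend)) trend <- default_trend(dims[2], dims[3])
  trend <- as.matrix(trend)
  if (!identical(dim(trend), dims[2:3])) stop("trend must be a J x K matrix")
  if (!is.null(score_bounds)) {
    if (length(score_bounds) != 2L || score_bounds[1] >= score_bounds[2])
      stop("score_bounds must be c(min, max) with min < max")
  }
  if (n_external > 0L) {
    if (is.null(external_loadings))
      stop("external_loadings required when n_external > 0")
    external_loadings <- as.matrix(external_loadings)
    if (!identical(dim(external_loadings), c(as.integer(n_external), ranks[1])))
      stop("external_loadings must be n_external x P")
    if (any(rowSums(external_loadings^2) > 1))
      stop("external_loadings row sums of squares must be <= 1")
  }
  structure(list(dims = dims, ranks = ranks, core_pattern = core_pattern,
                 trend = trend, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 score_bounds = score_bounds,
                 n_external = as.integer(n_external),
                 external_loadings = external_loadings, seed = seed,
                 target_share = target_share,
                 target_total_share = target_total_share),
            class = "synthetic_spec")
}

#' Default declining mean item trajectories
#'
#' Item-level mean scores that start around typical moderate-severity values
#' and decline toward a stable floor — the "general trend" of a treated
#' cohort improving over the first months and then stabilizing. Item levels
#' are spread over \[0.5, 1.4\] and share the time profile
#' `0.45 + 0.55 * exp(-(k - 1) / 2.2)`.
#'
#' @param J,K item and time-point counts.
#' @param scale multiplier on the whole trend matrix.
#' @return J x K matrix.
#' @export
default_trend <- function(J, K, scale = 1) {
  levels_j <- seq(0.5, 1.4, length.out = J)
  profile_k <- 0.45 + 0.55 * exp(-(seq_len(K) - 1) / 2.2)
  scale * outer(levels_j, profile_k)
}

# one strong entry per person component, each coupling a DISTINCT
# (symptom, time) component pair — distinct pairs keep the person-mode rank
# genuinely P (shared pairs would collapse it)
#' @noRd
default_core_pattern <- function(ranks) {
  P <- ranks[1]
  pairs <- expand.grid(q = seq_len(ranks[2]), r = seq_len(ranks[3]))
  q <- integer(P); r <- integer(P)
  taken <- logical(nrow(pairs))
  for (p in seq_len(P)) {
    new_q <- !(pairs$q %in% q[seq_len(p - 1)])
    new_r <- !(pairs$r %in% r[seq_len(p - 1)])
    score <- 2 * new_q + 2 * new_r
    score[taken] <- -1
    pick <- which.max(score)
    q[p] <- pairs$q[pick]; r[p] <- pairs$r[pick]
    taken[pick] <- TRUE
  }
  data.frame(p = seq_len(P), q = q, r = r,
             magnitude = 40 * (1 - 0.15 * (seq_len(P) - 1)))
}

#' Noise level targeting a structural share of the preprocessed SS
#'
#' Picks `noise_sd` so that the planted structure carries approximately
#' `target_share` of the post-preprocessing (centered, normalized) sum of
#' squares: `sd = sqrt(SS_core * (1 - f) / (f * I * J * K))`, using the fact
#' that the structure's SS equals the core's SS under orthonormal component
#' matrices.
#'
#' @param core_pattern as in [synthetic_spec()].
#' @param dims (I, J, K).
#' @param target_share fraction in (0, 1), e.g. 0.28.
#' @return noise standard deviation.
#' @export
calibrate_noise_sd <- function(core_pattern, dims, target_share) {
  stopifnot(target_share > 0, target_share < 1)
  ss_core <- sum(as.data.frame(core_pattern)$magnitude^2)
  sqrt(ss_core * (1 - target_share) / (target_share * prod(dims)))
}

#' Cohort-emulating core coupling pattern
#'
#' A (3,2,2) core in which the first person component loads on both symptom
#' components during the early (improving) phase, the second couples
#' dominantly with the somatic/persisting pair, and the third with the
#' cognitive/persisting pair — the interaction structure typical of a
#' treated depression cohort decomposition.
#'
#' @return data frame with columns `p, q, r, magnitude`.
#' @export
cohort_core_pattern <- function() {
  data.frame(
    p = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3),
    q = c(1, 1, 2, 2, 1, 1, 2, 2, 1, 1, 2, 2),
    r = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2),
    magnitude = c(15.95, 0.90, 24.02, 2.10,
                  9.38, 25.60, 18.85, 60.10,
                  16.79, 31.14, 0.99, 3.59))
}

#' Study-shaped synthetic specification
#'
#' A ready-made [synthetic_spec()] emulating a two-year depression cohort:
#' 219 persons x 21 items x 9 three-monthly assessments, a planted (3,2,2)
#' structure with the [cohort_core_pattern()] couplings, a declining general
#' trend, and 7.8% missing cells. The noise level is calibrated so the
#' planted structure carries `structure_share` of the post-preprocessing sum
#' of squares, and the trend is scaled so that trend plus structure explain
#' approximately `total_share` of the trend-retained (symptom-normalized)
#' sum of squares.
#'
#' @param seed integer seed.
#' @param structure_share fraction of preprocessed SS carried by the planted
#'   structure (default 0.28; use higher values, e.g. 0.7, for
#'   high-signal recovery experiments).
#' @param total_share target combined trend + structure share (default 0.65).
#' @param missing_rate fraction of masked cells (default 0.078).
#' @param missing_mechanism `"MCAR"` (default) or `"MAR-by-time"`.
#' @param n_external number of external covariates (default 3, with planted
#'   correlations 0.6, -0.45 and 0.38 on person components 1-3).
#' @return a [synthetic_spec()].
#' @export
study_like_spec <- function(seed = 1L, structure_share = 0.28,
                            total_share = 0.65, missing_rate = 0.078,
                            missing_mechanism = "MCAR", n_external = 3L) {
  dims <- c(219L, 21L, 9L)
  ranks <- c(3L, 2L, 2L)
  cp <- cohort_core_pattern()
  noise_sd <- calibrate_noise_sd(cp, dims, structure_share)
  trend <- default_trend(dims[2], dims[3])
  loadings <- matrix(0, 3, 3)
  diag(loadings) <- c(0.6, -0.45, 0.38)
  if (n_external == 0L) loadings <- NULL
  synthetic_spec(dims = dims, ranks = ranks, core_pattern = cp,
                 trend = trend, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 n_external = n_external,
                 external_loadings = if (is.null(loadings)) NULL
                                     else loadings[seq_len(n_external), , drop = FALSE],
                 seed = seed, target_share = structure_share,
                 target_total_share = total_share)
}

#' Generate a synthetic dataset with planted Tucker3 structure
#'
#' Draws orthonormal component matrices (QR of Gaussians), assembles the
#' planted core, and builds
#' `values = trend + (G x1 A x2 B x3 C) + noise`, optionally rounded and
#' clipped to `score_bounds`, then masks cells per the missingness
#' mechanism. External covariates are generated as
#' `L %*% z + independent noise` where `z` are the standardized person
#' component scores, so `external_loadings` are the implied correlations.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_dataset`: `dataset` ([three_way_data()]),
#'   `truth_model` ([tucker3_model()]), `truth_trend` (J x K),
#'   `external_table` (person x covariate data frame or `NULL`).
#' @export
generate_tucker3_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$dims; r <- spec$ranks
  out <- with_seed(spec$seed, {
    A <- rorth(d[1], r[1])
    B <- rorth(d[2], r[2])
    C <- rorth(d[3], r[3])
    G <- array(0, r)
    cp <- spec$core_pattern
    G[cbind(cp$p, cp$q, cp$r)] <- cp$magnitude
    structure_part <- ttm3(G, list(A, B, C))
    noise_sd <- spec$noise_sd
    if (!is.null(spec$target_share)) {
      # per-item structural SS after centering across persons; solve the
      # noise variance so the mean per-item share (which is what slab
      # normalization turns the global share into) hits the target
      cen <- sweep(structure_part, c(2L, 3L),
                   apply(structure_part, c(2L, 3L), mean), `-`)
      s_item <- apply(cen^2, 2L, sum)
      noise_slab <- (d[1] - 1) * d[3]          # E[centered noise SS] / sigma^2
      f <- spec$target_share
      share_gap <- function(v) mean(s_item / (s_item + v * noise_slab)) - f
      upper <- max(s_item) / noise_slab / f
      noise_sd <- sqrt(stats::uniroot(share_gap, c(1e-12, upper),
                                      tol = 1e-12)$root)
    }
    noise <- array(stats::rnorm(prod(d), sd = noise_sd), d)
    trend <- spec$trend
    if (!is.null(spec$target_total_share)) {
      # rescale the trend so that, on the symptom-normalized scale,
      # trend + structure explain the requested total share:
      #   1 - total = (1 - share) * SSpre / (SSpre + SStrend_norm)
      f <- spec$target_share; t_tot <- spec$target_total_share
      target_trend_ss <- ((1 - f) / (1 - t_tot) - 1) * prod(d)
      exp_s2 <- (s_item + noise_sd^2 * noise_slab) / (d[1] * d[3])
      cur_trend_ss <- d[1] * sum(sweep(trend^2, 1L, exp_s2, `/`))
      trend <- trend * sqrt(target_trend_ss / cur_trend_ss)
    }
    values <- aperm(array(trend, c(d[2], d[3], d[1])), c(3L, 1L, 2L)) +
      structure_part + noise
    if (!is.null(spec$score_bounds))
      values <- pmin(pmax(round(values), spec$score_bounds[1]),
                     spec$score_bounds[2])
    dataset <- three_way_data(
      values,
      time_labels = 3 * (seq_len(d[3]) - 1))  # three-monthly assessments
    if (spec$missing_rate > 0)
      dataset <- inject_missingness(dataset, spec$missing_rate,
                                    mechanism = spec$missing_mechanism,
                                    seed = NULL)
    external_table <- NULL
    if (spec$n_external > 0L) {
      z <- scale(A)   # standardized person component scores
      L <- spec$external_loadings
      resid_sd <- sqrt(pmax(0, 1 - rowSums(L^2)))
      ext <- z %*% t(L) +
        matrix(stats::rnorm(d[1] * spec$n_external), d[1]) %*%
          diag(resid_sd, spec$n_external)
      colnames(ext) <- paste0("covariate", seq_len(spec$n_external))
      external_table <- as.data.frame(ext)
      rownames(external_table) <- dataset$person_ids
    }
    list(dataset = dataset,
         truth_model = tucker3_model(A, B, C, G),
         trend = trend,
         external_table = external_table)
  })
  structure(list(dataset = out$dataset, truth_model = out$truth_model,
                 truth_trend = out$trend,
                 external_table = out$external_table, spec = spec),
            class = "synthetic_dataset")
}

#' Mask a fraction of cells as missing
#'
#' Exactly `round(rate * I * J * K)` observed-or-not cells are masked.
#' `"MCAR"` masks uniformly at random; `"MAR-by-time"` weights the
#' missingness odds by 1.5 per later time point (normalized to the target
#' rate), a dropout-like pattern.
#'
#' @param dataset a [three_way_data()].
#' @param rate fraction in \[0, 1).
#' @param mechanism `"MCAR"` or `"MAR-by-time"`.
#' @param seed optional integer seed.
#' @return a [three_way_data()] with additional cells masked.
#' @export
inject_missingness <- function(dataset, rate, mechanism = c("MCAR", "MAR-by-time"),
                               seed = NULL) {
  stopifnot(inherits(dataset, "three_way_data"))
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(dataset)
  d <- dim(dataset$values)
  n_cells <- prod(d)
  # target total masked fraction, counting cells already missing
  n_mask <- round(rate * n_cells) - sum(!dataset$mask)
  if (n_mask <= 0) return(dataset)
  w <- if (mechanism == "MCAR") rep(1, n_cells)
  else {
    per_time <- 1.5^(seq_len(d[3]) - 1)
    rep(per_time, each = d[1] * d[2])
  }
  observed_idx <- which(dataset$mask)
  idx <- with_seed(seed,
                   observed_idx[sample.int(length(observed_idx), n_mask,
                                           prob = w[observed_idx])])
  mask <- dataset$mask
  mask[idx] <- FALSE
  vals <- dataset$values
  vals[idx] <- NA_real_
  three_way_data(vals, mask, person_ids = dataset$person_ids,
                 item_labels = dataset$item_labels,
                 time_labels = dataset$time_labels,
                 time_unit = dataset$time_unit)
}

#' Planted truth mapped onto the preprocessed scale
#'
#' Preprocessing transforms the cube — centering across persons removes each
#' column's person mean, normalization rescales every item slab — so the
#' planted component matrices are only recoverable up to that transformation.
#' This maps the truth accordingly: person scores are centered, symptom
#' scores divided by the item scales, each matrix re-orthonormalized by QR
#' with the factor absorbed into the core. Fitted models should be compared
#' (after alignment) against this, not the raw truth.
#'
#' @param synth a `synthetic_dataset`.
#' @param state the [preprocessing_state()] of the cube the model was fitted
#'   to.
#' @return a [tucker3_model()] with orthonormal matrices.
#' @export
truth_model_preprocessed <- function(synth, state) {
  stopifnot(inherits(synth, "synthetic_dataset"),
            inherits(state, "preprocessing_state"))
  tr <- synth$truth_model
  mats <- list(scale(tr$A, center = TRUE, scale = FALSE),
               tr$B / state$scales,
               tr$C)
  G <- tr$G
  for (n in 1:3) {
    qr_n <- qr(mats[[n]])
    Qn <- qr.Q(qr_n)
    Rn <- qr.R(qr_n)
    # fix QR sign indeterminacy so each column keeps its planted orientation
    sgn <- sign(diag(Rn))
    sgn[sgn == 0] <- 1
    mats[[n]] <- sweep(Qn, 2L, sgn, `*`)
    G <- ttm(G, sgn * Rn, n)
  }
  tucker3_model(mats[[1]], mats[[2]], mats[[3]], G)
}

#' Write a synthetic dataset plus a truth sidecar
#'
#' The cube goes to a long-format CSV (see [write_long_table()]); the
#' planted model, trend and external loadings go to a JSON sidecar next to
#' it for test harnesses.
#'
#' @param synth a `synthetic_dataset`.
#' @param path CSV path; the sidecar is `paste0(path, ".truth.json")`.
#' @return `path`, invisibly.
#' @export
write_synthetic_dataset <- function(synth, path) {
  stopifnot(inherits(synth, "synthetic_dataset"))
  write_long_table(synth$dataset, path)
  truth <- list(
    ranks = unname(synth$truth_model$ranks),
    A = synth$truth_model$A, B = synth$truth_model$B,
    C = synth$truth_model$C,
    G = as.vector(synth$truth_model$G),
    trend = synth$truth_trend,
    external_table = synth$external_table)
  jsonlite::write_json(truth, paste0(path, ".truth.json"), digits = NA)
  invisible(path)
}
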