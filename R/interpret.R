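# Interpretive quantities of a pooled Tucker3 solution: per-core-element
# explained variance, component trajectory curves around the general trend,
# and correlations of person component scores with external baseline
# variables.

#' Explained variance per core element
#'
#' With orthonormal component matrices, each core element `g[p,q,r]`
#' contributes `g^2` to the model's sum of squares independently, so
#' `100 * g^2 / SS(preprocessed cube)` is the percentage of preprocessed
#' variance explained by that triple interaction. The percentages add up to
#' the model's heterogeneity fit.
#'
#' @param pooled a `pooled_solution` (or a [tucker3_model()]).
#' @param ss_preprocessed total SS of the preprocessed cube the solutions
#'   were fitted to; with slab-RMS normalization this is `I * J * K`.
#' @return a data frame sorted by person, then symptom/time component:
#'   `p, q, r, core, ev_pct`, plus `core_sd`, `ev_sd` when the pooled spread
#'   is available.
#' @export
core_explained_variance <- function(pooled, ss_preprocessed) {
  if (ss_preprocessed <= 0) stop("ss_preprocessed must be positive")
  model <- if (inherits(pooled, "pooled_solution")) pooled$mean_model else pooled
  stopifnot(inherits(model, "tucker3_model"))
  r <- model$ranks
  grid <- expand.grid(q = seq_len(r[2]), r = seq_len(r[3]), p = seq_len(r[1]))
  grid <- grid[, c("p", "q", "r")]
  g <- model$G[cbind(grid$p, grid$q, grid$r)]
  out <- data.frame(grid, core = g, ev_pct = 100 * g^2 / ss_preprocessed)
  if (inherits(pooled, "pooled_solution")) {
    gsd <- pooled$element_sd$G[cbind(grid$p, grid$q, grid$r)]
    out$core_sd <- gsd
    # delta-method spread of g^2/SS on the percentage scale
    out$ev_sd <- 100 * 2 * abs(g) * gsd / ss_preprocessed
  }
  out[order(out$p, out$q, out$r), ]
}

#' Component trajectory curves around the general trend
#'
#' For each person component p and symptom component q, the modeled time
#' curve is `sum_r g[p,q,r] * C[k,r]` — how that person component's loading
#' on that symptom component evolves over the assessments. The general
#' trend's own projection on each symptom component,
#' `sum_j B[j,q] * M[j,k] / s[j]`, is returned alongside for context.
#'
#' @param pooled a `pooled_solution` or [tucker3_model()].
#' @param state the [preprocessing_state()] of the fitted data (used for the
#'   trend context curves); optional.
#' @param time_labels optional numeric labels for the K time points.
#' @return list: `curves` (data frame: person_component, symptom_component,
#'   time, value), `trend_projection` (data frame: symptom_component, time,
#'   value; `NULL` without `state`).
#' @export
component_trajectories <- function(pooled, state = NULL, time_labels = NULL) {
  model <- if (inherits(pooled, "pooled_solution")) pooled$mean_model else pooled
  stopifnot(inherits(model, "tucker3_model"))
  r <- model$ranks
  K <- nrow(model$C)
  if (is.null(time_labels)) time_labels <- seq_len(K)
  curves <- expand.grid(time = time_labels,
                        symptom_component = seq_len(r[2]),
                        person_component = seq_len(r[1]))
  val <- numeric(nrow(curves))
  for (p in seq_len(r[1]))
    for (q in seq_len(r[2])) {
      curve <- model$C %*% model$G[p, q, ]     # K x 1
      sel <- curves$person_component == p & curves$symptom_component == q
      val[sel] <- curve
    }
  curves$value <- val
  curves <- curves[, c("person_component", "symptom_component", "time", "value")]

  trend_projection <- NULL
  if (!is.null(state)) {
    stopifnot(inherits(state, "preprocessing_state"))
    trend_s <- sweep(state$trend, 1L, state$scales, `/`)   # J x K
    proj <- crossprod(model$B, trend_s)                    # Q x K
    trend_projection <- expand.grid(time = time_labels,
                                    symptom_component = seq_len(r[2]))
    trend_projection$value <- as.vector(t(proj))
    trend_projection <- trend_projection[, c("symptom_component", "time", "value")]
  }
  list(curves = curves, trend_projection = trend_projection)
}

#' Correlations of person component scores with external variables
#'
#' For every external variable, a correlation with each person component is
#' computed in every imputed dataset and pooled: the coefficients are
#' Fisher-z transformed, averaged, and the pooled p-value uses a
#' Rubin-style total variance (within `1/(n-3)` plus `(1 + 1/m)` times the
#' between-imputation variance of z). The method per variable is Pearson,
#' or Spearman when a Shapiro-Wilk test rejects normality of that variable
#' at `normality_alpha`.
#'
#' @param person_scores a matrix (I x P), a list of such matrices (one per
#'   imputation), a `pooled_solution` (uses the rotated per-dataset person
#'   scores) or a [tucker3_model()].
#' @param external person x variable data frame or matrix (complete rows
#'   used; a constant variable is an error).
#' @param method `"auto"` (normality rule), `"pearson"` or `"spearman"`.
#' @param alpha significance level for flagging (default 0.05).
#' @param normality_alpha Shapiro-Wilk level for the auto rule.
#' @param adjust p-value adjustment across the table: `"none"` (default) or
#'   any [stats::p.adjust()] method, e.g. `"BH"`.
#' @return a `correlation_table` data frame: `variable`,
#'   `person_component`, `method`, `r` (pooled), `r_sd`
#'   (across imputations), `p_value`, `significant`.
#' @export
external_correlations <- function(person_scores, external, method = "auto",
                                  alpha = 0.05, normality_alpha = 0.05,
                                  adjust = "none") {
  scores <- person_score_list(person_scores)
  ext <- as.data.frame(external)
  I <- nrow(scores[[1]])
  if (nrow(ext) != I)
    stop("external table must align with the person scores (one row per person)")
  P <- ncol(scores[[1]])
  m <- length(scores)

  rows <- list()
  for (v in seq_len(ncol(ext))) {
    x <- as.numeric(ext[[v]])
    vname <- names(ext)[v]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
      stop(sprintf("external variable '%s' is constant; correlation undefined", vname))
    meth <- method
    if (method == "auto") {
      sw_p <- stats::shapiro.test(x[!is.na(x)])$p.value
      meth <- if (sw_p < normality_alpha) "spearman" else "pearson"
    }
    for (p in seq_len(P)) {
      rs <- vapply(scores, function(s)
        stats::cor(s[, p], x, use = "complete.obs", method = meth), 0)
      rs <- pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12)
      zs <- atanh(rs)
      zbar <- mean(zs)
      n_eff <- sum(!is.na(x))
      within <- 1 / (n_eff - 3)
      between <- if (m > 1) stats::var(zs) else 0
      total <- within + (1 + 1 / m) * between
      pval <- 2 * stats::pnorm(-abs(zbar) / sqrt(total))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = vname, person_component = p, method = meth,
        r = tanh(zbar), r_sd = if (m > 1) stats::sd(rs) else 0,
        p_value = pval, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- out$p_value < alpha
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' @noRd
person_score_list <- function(person_scores) {
  if (inherits(person_scores, "pooled_solution"))
    return(lapply(person_scores$rotated, `[[`, "A"))
  if (inherits(person_scores, "tucker3_model"))
    return(list(person_scores$A))
  if (is.matrix(person_scores) || is.data.frame(person_scores))
    return(list(as.matrix(person_scores)))
  if (is.list(person_scores)) return(lapply(person_scores, as.matrix))
  stop("unsupported person_scores input")
}
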