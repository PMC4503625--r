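# Fixed-effects three-way ANOVA variance decomposition of the
# grand-mean-subtracted cube (one observation per cell, balanced design).

anova_effects <- c("persons", "symptoms", "time",
                   "persons:symptoms", "persons:time", "symptoms:time",
                   "three-way+error", "total")

#' Three-way ANOVA variance decomposition of a complete cube
#'
#' Decomposes the total sum of squares around the grand mean into the three
#' main effects, the three pairwise interactions, and a remainder that
#' confounds the three-way interaction with error (there is one observation
#' per cell, so they are inseparable). With a balanced complete design the
#' seven effect sums of squares add up to the total exactly. Percentage
#' shares indicate how much heterogeneity sits on each mode and, crucially,
#' whether a sizeable three-way interaction justifies a three-mode
#' decomposition.
#'
#' @param x complete (imputed) raw-scale cube, all dimensions >= 2.
#' @return a `variance_decomposition`: `ss` and `pct` named over the seven
#'   effects plus `total`, and `zero_total` flag (shares reported as 0 when
#'   the cube is constant).
#' @export
three_way_anova <- function(x) {
  v <- cube_values(x)
  if (anyNA(v)) stop("cube must be complete (impute first)")
  d <- dim(v)
  if (any(d < 2)) stop("all dimensions must be >= 2 for a three-way ANOVA")
  I <- d[1]; J <- d[2]; K <- d[3]
  gm <- mean(v)
  m_i <- apply(v, 1L, mean); m_j <- apply(v, 2L, mean); m_k <- apply(v, 3L, mean)
  m_ij <- apply(v, c(1L, 2L), mean)
  m_ik <- apply(v, c(1L, 3L), mean)
  m_jk <- apply(v, c(2L, 3L), mean)

  # pairwise interaction deviations: cell mean - both main-effect means + grand mean
  ss <- c(
    persons  = J * K * sum((m_i - gm)^2),
    symptoms = I * K * sum((m_j - gm)^2),
    time     = I * J * sum((m_k - gm)^2),
    `persons:symptoms` =
      K * sum((sweep(sweep(m_ij, 1L, m_i, `-`), 2L, m_j, `-`) + gm)^2),
    `persons:time` =
      J * sum((sweep(sweep(m_ik, 1L, m_i, `-`), 2L, m_k, `-`) + gm)^2),
    `symptoms:time` =
      I * sum((sweep(sweep(m_jk, 1L, m_j, `-`), 2L, m_k, `-`) + gm)^2))

  total <- sum((v - gm)^2)
  ss["three-way+error"] <- total - sum(ss[1:6])
  ss["total"] <- total

  zero_total <- total <= .Machine$double.eps * length(v)
  pct <- if (zero_total) stats::setNames(rep(0, 8L), anova_effects)
         else 100 * ss / total
  structure(list(ss = ss[anova_effects], pct = pct[anova_effects],
                 pooled_sd_ss = NULL, pooled_sd_pct = NULL,
                 zero_total = zero_total),
            class = "variance_decomposition")
}

#' Pool ANOVA decompositions across imputed datasets
#'
#' Element-wise mean and standard deviation of the sums of squares and
#' percentage shares across the m imputations.
#'
#' @param decompositions list of `variance_decomposition` objects with
#'   identical effect keys.
#' @return a pooled `variance_decomposition` with `pooled_sd_ss` and
#'   `pooled_sd_pct` filled.
#' @export
pool_anova <- function(decompositions) {
  if (length(decompositions) < 1L) stop("need at least one decomposition")
  keys <- names(decompositions[[1]]$ss)
  for (d in decompositions)
    if (!identical(names(d$ss), keys)) stop("mismatched effect keys; cannot pool")
  ss_mat <- sapply(decompositions, function(d) d$ss)
  pct_mat <- sapply(decompositions, function(d) d$pct)
  sd0 <- function(m) if (ncol(as.matrix(m)) > 1) apply(m, 1L, stats::sd)
                     else stats::setNames(rep(0, length(keys)), keys)
  structure(list(
    ss = rowMeans(ss_mat), pct = rowMeans(pct_mat),
    pooled_sd_ss = sd0(ss_mat), pooled_sd_pct = sd0(pct_mat),
    zero_total = all(vapply(decompositions, `[[`, TRUE, "zero_total"))),
    class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, digits = 2, ...) {
  cat("Three-way ANOVA after subtraction of the grand mean\n")
  df <- as.data.frame(x)
  print(df, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.variance_decomposition <- function(x, ...) {
  df <- data.frame(effect = names(x$ss), ss = unname(x$ss),
                   pct = unname(x$pct), stringsAsFactors = FALSE)
  if (!is.null(x$pooled_sd_ss)) {
    df$ss_sd <- unname(x$pooled_sd_ss)
    df$pct_sd <- unname(x$pooled_sd_pct)
  }
  df
}
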