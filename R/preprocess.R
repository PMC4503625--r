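# Centering across the person mode (removes the general trend) and
# normalization within the symptom mode (equal item importance), invertibly.

#' Preprocessing state for invertible back-transformation
#'
#' @param trend J x K matrix `M` of per-(item, time) person means removed by
#'   centering — the "general trend" (score units).
#' @param scales length-J positive vector `s` of per-item root-mean-square
#'   scales divided out by normalization.
#' @return object of class `preprocessing_state`.
#' @export
preprocessing_state <- function(trend, scales) {
  trend <- as.matrix(trend)
  scales <- as.numeric(scales)
  if (nrow(trend) != length(scales))
    stop("trend must have one row per item scale")
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("all item scales must be positive")
  structure(list(trend = trend, scales = scales,
                 conventions = c(centering = "across persons",
                                 normalization = "symptom slab RMS = 1")),
            class = "preprocessing_state")
}

#' Center a complete cube across the person mode
#'
#' Subtracts, for every (item, time) cell, the mean over persons. The removed
#' J x K mean matrix is the general trend: the average symptom trajectory
#' shared by the sample. The centered cube describes person-specific
#' deviations around that trend.
#'
#' @param x complete array or [three_way_data()] (run after imputation).
#' @return list: `data` (centered array), `trend` (J x K matrix).
#' @export
center_across_persons <- function(x) {
  v <- cube_values(x)
  if (anyNA(v)) stop("cube must be complete before centering (impute first)")
  trend <- apply(v, c(2L, 3L), mean)
  list(data = sweep(v, c(2L, 3L), trend, `-`), trend = trend)
}

#' Normalize a centered cube within the symptom mode
#'
#' Rescales each item's I x K slab to mean square 1 (slab sum of squares
#' I*K), so every item contributes equally to the decomposition. The
#' divisors are the slab root-mean-squares.
#'
#' @param x centered array or [three_way_data()].
#' @return list: `data` (normalized array), `scales` (length-J vector).
#' @export
normalize_within_symptom <- function(x) {
  v <- cube_values(x)
  if (anyNA(v)) stop("cube must be complete before normalization")
  d <- dim(v)
  scales <- sqrt(apply(v^2, 2L, sum) / (d[1] * d[3]))
  if (any(scales <= .Machine$double.eps^0.5)) {
    j <- which(scales <= .Machine$double.eps^0.5)[1]
    lab <- if (!is.null(dimnames(v)[[2]])) dimnames(v)[[2]][j] else j
    stop(sprintf("item '%s' has (near-)zero variance after centering; cannot normalize", lab))
  }
  list(data = sweep(v, 2L, scales, `/`), scales = scales)
}

#' Center and normalize in one step
#'
#' @param x complete cube.
#' @return list: `data` (preprocessed array), `state`
#'   ([preprocessing_state()]).
#' @export
preprocess_cube <- function(x) {
  cen <- center_across_persons(x)
  nrm <- normalize_within_symptom(cen$data)
  list(data = nrm$data, state = preprocessing_state(cen$trend, nrm$scales))
}

#' Invert preprocessing
#'
#' Multiplies by the item scales and adds back the general trend,
#' reproducing the completed raw-scale cube.
#'
#' @param x preprocessed array.
#' @param state the matching [preprocessing_state()].
#' @return raw-scale array.
#' @export
invert_preprocess <- function(x, state) {
  stopifnot(inherits(state, "preprocessing_state"))
  v <- cube_values(x)
  sweep(sweep(v, 2L, state$scales, `*`), c(2L, 3L), state$trend, `+`)
}
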