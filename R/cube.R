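# Labelled persons x items x time data cube with a missingness mask,
# long-format CSV round-trip, and per-person completeness filtering.

#' Construct a labelled three-way data cube
#'
#' Holds repeated questionnaire item scores indexed by person, item and
#' assessment time. Cells absent from the source table are masked
#' (`mask = FALSE`) and carried as `NA` in `values`.
#'
#' @param values numeric I x J x K array (persons x items x time points).
#' @param mask logical array of the same shape, `TRUE` where observed.
#'   Defaults to `!is.na(values)`.
#' @param person_ids,item_labels,time_labels label vectors of lengths I, J, K;
#'   `time_labels` must be numeric and strictly increasing.
#' @param time_unit free-text unit for `time_labels` (e.g. "months").
#' @return an object of class `three_way_data`.
#' @export
three_way_data <- function(values, mask = NULL,
                           person_ids = NULL, item_labels = NULL,
                           time_labels = NULL, time_unit = "months") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a three-way array")
  d <- dim(values)
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), d))
    stop("mask must be a logical array with the same dimensions as values")
  values[!mask] <- NA_real_
  if (anyNA(values[mask]))
    stop("values contains NA at cells flagged as observed")
  if (is.null(person_ids)) person_ids <- paste0("p", seq_len(d[1]))
  if (is.null(item_labels)) item_labels <- paste0("item", seq_len(d[2]))
  if (is.null(time_labels)) time_labels <- seq_len(d[3]) - 1
  time_labels <- as.numeric(time_labels)
  if (length(person_ids) != d[1] || length(item_labels) != d[2] ||
      length(time_labels) != d[3])
    stop("label vector lengths must match the array dimensions")
  if (anyNA(time_labels) || is.unsorted(time_labels, strictly = TRUE))
    stop("time_labels must be strictly increasing")
  dimnames(values) <- dimnames(mask) <-
    list(person_ids, item_labels, as.character(time_labels))
  structure(
    list(values = values, mask = mask,
         person_ids = as.character(person_ids),
         item_labels = as.character(item_labels),
         time_labels = time_labels, time_unit = time_unit),
    class = "three_way_data")
}

#' @export
print.three_way_data <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("three_way_data: %d persons x %d items x %d time points (%s)\n",
              d[1], d[2], d[3], x$time_unit))
  cat(sprintf("  observed: %d / %d cells (%.1f%% missing)\n",
              sum(x$mask), length(x$mask), 100 * mean(!x$mask)))
  invisible(x)
}

#' @export
dim.three_way_data <- function(x) dim(x$values)

# accept either a bare array or a three_way_data
#' @noRd
cube_values <- function(x) {
  if (inherits(x, "three_way_data")) x$values else x
}

#' @noRd
as_cube <- function(x) {
  if (inherits(x, "three_way_data")) x
  else three_way_data(x)
}

#' Read a long-format table into a three-way cube
#'
#' One row per (person, time, item) with a numeric value; cells without a row
#' (or with an empty/NA value) are masked. Persons are ordered by first
#' appearance, times ascending, and items by `item_order` if supplied,
#' otherwise by first appearance.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param schema named list mapping the roles `person`, `time`, `item`,
#'   `value` to column names in the file.
#' @param item_order optional character vector fixing the questionnaire item
#'   order.
#' @param time_unit passed to [three_way_data()].
#' @return a [three_way_data()].
#' @export
read_long_table <- function(path,
                            schema = list(person = "person_id", time = "time",
                                          item = "item", value = "value"),
                            item_order = NULL, time_unit = "months") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  for (role in c("person", "time", "item", "value")) {
    if (!schema[[role]] %in% names(tab))
      stop(sprintf("column '%s' (role %s) not found in %s",
                   schema[[role]], role, path))
  }
  person <- as.character(tab[[schema$person]])
  time <- as.numeric(tab[[schema$time]])
  item <- as.character(tab[[schema$item]])
  value_raw <- tab[[schema$value]]
  value <- suppressWarnings(as.numeric(value_raw))
  bad <- which(!is.na(value_raw) & is.na(value) &
                 !(value_raw %in% c("NA", "")))
  if (length(bad))
    stop(sprintf("non-numeric value in row %d of %s: '%s'",
                 bad[1] + 1L, path, value_raw[bad[1]]))

  persons <- unique(person)
  times <- sort(unique(time))
  items <- if (is.null(item_order)) unique(item) else item_order
  if (!all(item %in% items)) stop("item_order does not cover all items present")

  key <- paste(person, time, item, sep = "\r")
  if (anyDuplicated(key)) {
    first_dup <- key[duplicated(key)][1]
    parts <- strsplit(first_dup, "\r", fixed = TRUE)[[1]]
    stop(sprintf("duplicate record for person '%s', time %s, item '%s'",
                 parts[1], parts[2], parts[3]))
  }

  values <- array(NA_real_, c(length(persons), length(items), length(times)))
  idx <- cbind(match(person, persons), match(item, items), match(time, times))
  values[idx] <- value
  three_way_data(values, person_ids = persons, item_labels = items,
                 time_labels = times, time_unit = time_unit)
}

#' Write a cube as a long-format CSV
#'
#' Masked cells are written with an empty value field, so the file
#' round-trips through [read_long_table()] exactly (values, mask, labels).
#'
#' @param dataset a [three_way_data()].
#' @param path output CSV path.
#' @param drop_missing if `TRUE`, rows for masked cells are omitted instead.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(dataset, path, drop_missing = FALSE) {
  stopifnot(inherits(dataset, "three_way_data"))
  d <- dim(dataset$values)
  grid <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  out <- data.frame(
    person_id = dataset$person_ids[grid$i],
    time = dataset$time_labels[grid$k],
    item = dataset$item_labels[grid$j],
    value = dataset$values[cbind(grid$i, grid$j, grid$k)],
    stringsAsFactors = FALSE)
  if (drop_missing) out <- out[!is.na(out$value), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter persons by the number of assessments they provided
#'
#' A time point counts as provided for a person when at least
#' `timepoint_rule` of that person's items are observed at that time; persons
#' providing fewer than `min_timepoints` time points are dropped. Values of
#' retained persons are never altered.
#'
#' @param dataset a [three_way_data()].
#' @param min_timepoints minimum number of provided time points (default 5,
#'   out of e.g. 9 three-monthly assessments).
#' @param timepoint_rule fraction of items that must be observed for a time
#'   point to count as provided (default 0.5; use 1 for a strict reading).
#' @return list with elements `dataset` (filtered) and `report`
#'   (a `selection_report`: `n_before`, `n_after`, `min_timepoints`,
#'   `per_person_observed_timepoints`).
#' @export
select_sample <- function(dataset, min_timepoints = 5L, timepoint_rule = 0.5) {
  stopifnot(inherits(dataset, "three_way_data"))
  d <- dim(dataset$values)
  if (min_timepoints < 1 || min_timepoints > d[3])
    stop("min_timepoints must be between 1 and the number of time points")
  # persons x times matrix of observed-item fractions
  frac <- apply(dataset$mask, c(1L, 3L), mean)
  provided <- rowSums(frac >= timepoint_rule)
  keep <- provided >= min_timepoints
  if (!any(keep)) stop("sample selection retained no persons")
  filtered <- three_way_data(
    dataset$values[keep, , , drop = FALSE],
    dataset$mask[keep, , , drop = FALSE],
    person_ids = dataset$person_ids[keep],
    item_labels = dataset$item_labels,
    time_labels = dataset$time_labels,
    time_unit = dataset$time_unit)
  report <- structure(
    list(n_before = d[1], n_after = sum(keep),
         min_timepoints = as.integer(min_timepoints),
         per_person_observed_timepoints =
           stats::setNames(as.integer(provided), dataset$person_ids)),
    class = "selection_report")
  list(dataset = filtered, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("sample selection: retained %d of %d persons (>= %d provided time points)\n",
              x$n_after, x$n_before, x$min_timepoints))
  invisible(x)
}
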