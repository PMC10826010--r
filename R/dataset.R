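#' Construct a longitudinal dataset
#'
#' A longitudinal dataset pairs a static table (one row per subject: the
#' metadata component) with a long-format series table (one row per subject
#' and time step: the dynamic component), under a shared [variable_schema()].
#' This mirrors the two-component structure of clinical and lifelogging
#' cohorts where per-subject attributes coexist with repeated measurements.
#'
#' @param schema An `stsg_schema` describing every variable.
#' @param static Tibble with a `subject_id` column plus one column per static
#'   variable (or its encoded expansion).
#' @param series Tibble with `subject_id`, integer time index `t` (0-based,
#'   ascending within subject) plus one column per dynamic variable.
#' @param time_unit Free-text label for the time axis (e.g. `"s"`, `"hour"`).
#' @param validate Check invariants (equal subject sets and ordering, declared
#'   columns present, codes in range). Set `FALSE` only for transient ragged
#'   states during preprocessing.
#'
#' @return A list with class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(schema, static, series, time_unit = "step",
                                 validate = TRUE) {
  d <- structure(
    list(schema = validate_schema(schema),
         static = tibble::as_tibble(static),
         series = tibble::as_tibble(series),
         time_unit = time_unit),
    class = "longitudinal_dataset"
  )
  if (validate) validate_dataset(d) else d
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  Ts <- table(x$series$subject_id)
  cat(sprintf(
    "<longitudinal_dataset> %d subjects, %s static / %s dynamic variables, T = %s\n",
    nrow(x$static),
    sum(x$schema$component == "static"),
    sum(x$schema$component == "dynamic"),
    if (length(Ts) == 0) "0" else paste(unique(range(Ts)), collapse = "-")
  ))
  invisible(x)
}

# Expanded column names a variable occupies given its current encoding.
variable_columns <- function(schema, var) {
  row <- schema_row(schema, var)
  if (row$kind == "categorical" && row$encoding == "onehot") {
    paste0(var, "=", row$categories[[1]])
  } else {
    var
  }
}

dataset_static_vars <- function(d) schema_vars(d$schema, "static")
dataset_dynamic_vars <- function(d) schema_vars(d$schema, "dynamic")

n_subjects <- function(d) nrow(d$static)

#' Dataset invariants
#'
#' Checks that the static and series tables agree on the subject set and
#' order, that every schema variable is present (and nothing undeclared is),
#' that time indices are 0..T-1 per subject, and that encoded categorical
#' codes lie within the declared category range.
#'
#' @param d A `longitudinal_dataset`.
#' @param rectangular Additionally require a common series length T.
#' @return `d`, invisibly enriched, or an error.
#' @export
validate_dataset <- function(d, rectangular = FALSE) {
  stopifnot(inherits(d, "longitudinal_dataset"))
  if (!"subject_id" %in% names(d$static)) {
    stop("static table lacks a subject_id column", call. = FALSE)
  }
  if (!all(c("subject_id", "t") %in% names(d$series))) {
    stop("series table needs subject_id and t columns", call. = FALSE)
  }
  if (anyDuplicated(d$static$subject_id)) {
    stop("static table must have one row per subject", call. = FALSE)
  }

  exp_static <- unlist(lapply(dataset_static_vars(d), variable_columns,
                              schema = d$schema))
  exp_series <- unlist(lapply(dataset_dynamic_vars(d), variable_columns,
                              schema = d$schema))
  miss_s <- setdiff(exp_static, names(d$static))
  miss_d <- setdiff(exp_series, names(d$series))
  if (length(miss_s) || length(miss_d)) {
    stop("schema error: declared column(s) missing from data: ",
         paste(c(miss_s, miss_d), collapse = ", "), call. = FALSE)
  }
  extra_s <- setdiff(names(d$static), c("subject_id", exp_static))
  extra_d <- setdiff(names(d$series), c("subject_id", "t", exp_series))
  if (length(extra_s) || length(extra_d)) {
    stop("schema error: undeclared column(s) present: ",
         paste(c(extra_s, extra_d), collapse = ", "), call. = FALSE)
  }

  sid_static <- unique(d$static$subject_id)
  if (length(exp_series) > 0 || nrow(d$series) > 0) {
    sid_series <- unique(d$series$subject_id)
    only_static <- setdiff(sid_static, sid_series)
    only_series <- setdiff(sid_series, sid_static)
    if (length(only_static) || length(only_series)) {
      stop("alignment error: subjects present in only one component: {",
           paste(c(only_static, only_series), collapse = ", "), "}",
           call. = FALSE)
    }
    if (!identical(as.character(sid_series), as.character(sid_static))) {
      stop("alignment error: subject order differs between static and series",
           call. = FALSE)
    }

    per <- split(d$series$t, factor(d$series$subject_id, levels = sid_static))
    ok <- vapply(per, function(tt) length(tt) > 0 &&
                   identical(as.integer(tt), seq_along(tt) - 1L), logical(1))
    if (!all(ok)) {
      stop("series time index must be 0..T-1 ascending per subject; offenders: ",
           paste(names(per)[!ok], collapse = ", "), call. = FALSE)
    }
    if (rectangular && length(unique(lengths(per))) > 1) {
      stop("series lengths differ across subjects; run ",
           "truncate_to_common_length() first", call. = FALSE)
    }
  }

  # label-encoded codes must be inside the declared category range
  for (v in d$schema$name[d$schema$kind == "categorical" &
                          d$schema$encoding == "label"]) {
    row <- schema_row(d$schema, v)
    tab <- if (row$component == "static") d$static else d$series
    vals <- tab[[v]]
    k <- length(row$categories[[1]])
    bad <- !is.na(vals) & (vals < 0 | vals >= k | vals != floor(vals))
    if (any(bad)) {
      stop("encoded codes out of range for ", v, call. = FALSE)
    }
  }
  invisible(d)
}

series_lengths <- function(d) {
  sid <- d$static$subject_id
  tab <- table(factor(d$series$subject_id, levels = sid))
  stats::setNames(as.integer(tab), sid)
}

series_length <- function(d) {
  Ts <- unique(series_lengths(d))
  if (length(Ts) != 1) stop("dataset is not rectangular", call. = FALSE)
  Ts
}

# n x T matrix of one dynamic column, subjects in static order
series_matrix <- function(d, column) {
  sid <- d$static$subject_id
  T_ <- series_length(d)
  ord <- order(match(d$series$subject_id, sid), d$series$t)
  matrix(d$series[[column]][ord], nrow = length(sid), ncol = T_, byrow = TRUE,
         dimnames = list(sid, NULL))
}

set_series_matrix <- function(d, column, m) {
  sid <- d$static$subject_id
  ord <- order(match(d$series$subject_id, sid), d$series$t)
  d$series[[column]][ord] <- as.vector(t(m))
  d
}

#' Read a paired static + series dataset from CSV
#'
#' Expects the standard on-disk layout: a static CSV with header
#' `subject_id,<static vars...>` and a long-format series CSV with header
#' `subject_id,t,<dynamic vars...>`, `t` ascending within subject. Missing
#' values may be empty fields or the literal `NA`.
#'
#' @param static_path,series_path CSV file paths.
#' @param schema An `stsg_schema`, or a path to a schema file.
#' @param time_unit Time-axis label stored on the dataset.
#' @return A validated `longitudinal_dataset`.
#' @export
read_dataset <- function(static_path, series_path, schema,
                         time_unit = "step") {
  if (is.character(schema)) schema <- read_schema(schema)
  schema <- validate_schema(schema)
  static <- readr::read_csv(static_path, show_col_types = FALSE,
                            na = c("", "NA"), progress = FALSE)
  series <- readr::read_csv(series_path, show_col_types = FALSE,
                            na = c("", "NA"), progress = FALSE)
  static$subject_id <- as.character(static$subject_id)
  series$subject_id <- as.character(series$subject_id)
  series$t <- as.integer(series$t)
  series <- dplyr::arrange(series, match(.data$subject_id,
                                         unique(static$subject_id)), .data$t)
  longitudinal_dataset(schema, static, series, time_unit = time_unit)
}

#' Write a dataset to the paired CSV layout
#'
#' Inverse of [read_dataset()]: `read_dataset()` on the written files (with
#' the same schema) reproduces the dataset exactly, including subject order.
#' Missing values are written as empty fields.
#'
#' @param d A `longitudinal_dataset`.
#' @param static_path,series_path Output CSV paths.
#' @param schema_path Optional path to also write the schema file.
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(d, static_path, series_path, schema_path = NULL) {
  validate_dataset(d)
  readr::write_csv(d$static, static_path, na = "", progress = FALSE)
  readr::write_csv(d$series, series_path, na = "", progress = FALSE)
  if (!is.null(schema_path)) write_schema(d$schema, schema_path)
  invisible(d)
}

#' Flatten subjects to fixed-length numeric records
#'
#' Several evaluation methods (data-labelling analysis, precision-recall
#' distributions, membership inference, TSTR regression) operate on one
#' numeric vector per subject. The representation used here is: numeric
#' static variables as-is, categorical static variables as onehot indicators,
#' then per dynamic variable its mean/min/max summary followed by
#' `series_points` evenly spaced samples of the series, which caps the
#' dimension independently of T.
#'
#' @param d A rectangular, fully observed `longitudinal_dataset` with
#'   unencoded or onehot categoricals.
#' @param series_points Number of evenly spaced samples kept per dynamic
#'   variable (default 8; 0 keeps summaries only).
#' @return A tibble with `subject_id` plus numeric feature columns.
#' @export
flatten_records <- function(d, series_points = 8) {
  validate_dataset(d, rectangular = TRUE)
  T_ <- series_length(d)
  out <- tibble::tibble(subject_id = d$static$subject_id)

  for (v in dataset_static_vars(d)) {
    row <- schema_row(d$schema, v)
    if (row$kind == "numeric") {
      out[[v]] <- as.numeric(d$static[[v]])
    } else {
      cats <- row$categories[[1]]
      if (row$encoding == "onehot") {
        for (cn in variable_columns(d$schema, v)) out[[cn]] <- d$static[[cn]]
      } else {
        vals <- d$static[[v]]
        if (row$encoding == "label") vals <- cats[as.integer(vals) + 1L]
        for (cc in cats) out[[paste0(v, "=", cc)]] <- as.numeric(vals == cc)
      }
    }
  }

  idx <- if (series_points > 0) {
    unique(pmax(1L, pmin(T_, round(seq(1, T_, length.out = series_points)))))
  } else integer(0)
  for (v in dataset_dynamic_vars(d)) {
    for (cn in variable_columns(d$schema, v)) {
      m <- series_matrix(d, cn)
      out[[paste0(cn, "_mean")]] <- unname(rowMeans(m))
      out[[paste0(cn, "_min")]] <- unname(apply(m, 1, min))
      out[[paste0(cn, "_max")]] <- unname(apply(m, 1, max))
      for (k in seq_along(idx)) {
        out[[paste0(cn, "_t", idx[k] - 1L)]] <- unname(m[, idx[k]])
      }
    }
  }
  out
}
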