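#' @title Generic preprocessing for longitudinal datasets
#' @description Missing-data handling (exclusion + linear interpolation,
#'   forward filling), truncation to a common series length, categorical
#'   encoding and min-max scaling. These are the dataset-agnostic steps that
#'   bring a raw cohort to the rectangular, fully numeric form the generative
#'   backends require.
#' @name preprocessing
NULL

# insert `new` columns so they start at position `at` of `tb`
splice_cols <- function(tb, at, new) {
  before <- if (at > 1L) tb[seq_len(at - 1L)] else tb[0]
  after <- if (at <= ncol(tb)) tb[seq(at, ncol(tb))] else tb[0]
  dplyr::bind_cols(before, tibble::as_tibble(new), after)
}

keep_subjects <- function(d, ids) {
  d$static <- d$static[d$static$subject_id %in% ids, , drop = FALSE]
  d$series <- d$series[d$series$subject_id %in% ids, , drop = FALSE]
  d
}

#' Exclude heavily missing subjects and linearly interpolate the rest
#'
#' Subjects whose total number of missing dynamic samples (summed over all
#' dynamic variables) exceeds `max_missing_per_subject` are removed and
#' reported; remaining gaps are filled by linear interpolation between the
#' nearest valid neighbours. Boundary gaps (a missing prefix or suffix) are
#' filled by nearest-valid extension, which keeps subjects rather than
#' discarding them.
#'
#' @param d A `longitudinal_dataset` with numeric dynamic variables.
#' @param max_missing_per_subject Exclusion threshold; the default 30 is the
#'   conventional cutoff for exercise-test series of a few hundred samples.
#' @return A list with elements `dataset` (no missing dynamic values) and
#'   `excluded` (character vector of removed subject ids).
#' @export
interpolate_missing <- function(d, max_missing_per_subject = 30) {
  validate_dataset(d)
  dyn <- unlist(lapply(dataset_dynamic_vars(d), variable_columns,
                       schema = d$schema))
  miss <- d$series |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_missing = sum(is.na(dplyr::pick(dplyr::all_of(dyn)))),
                     .groups = "drop")
  excluded <- miss$subject_id[miss$n_missing > max_missing_per_subject]
  keep <- setdiff(d$static$subject_id, excluded)
  d <- keep_subjects(d, keep)

  for (v in dyn) {
    per <- split(seq_len(nrow(d$series)), d$series$subject_id)
    for (sid in names(per)) {
      x <- d$series[[v]][per[[sid]]]
      if (all(is.na(x))) {
        stop("unrecoverable subject ", sid, ": variable ", v,
             " entirely missing", call. = FALSE)
      }
      if (anyNA(x)) {
        d$series[[v]][per[[sid]]] <-
          as.numeric(zoo::na.approx(x, na.rm = FALSE, rule = 2))
      }
    }
  }
  list(dataset = validate_dataset(d), excluded = excluded)
}

#' Forward-fill missing dynamic samples
#'
#' Each missing cell takes the most recent preceding valid value of the same
#' variable, the standard imputation when an absent measurement means "no
#' change since the last reading" (e.g. hourly ICU charting). A missing
#' prefix is backfilled from the first valid sample.
#'
#' @inheritParams interpolate_missing
#' @return The dataset with no missing dynamic values.
#' @export
forward_fill <- function(d) {
  validate_dataset(d)
  dyn <- unlist(lapply(dataset_dynamic_vars(d), variable_columns,
                       schema = d$schema))
  per <- split(seq_len(nrow(d$series)), d$series$subject_id)
  for (v in dyn) {
    for (sid in names(per)) {
      x <- d$series[[v]][per[[sid]]]
      if (all(is.na(x))) {
        stop("unrecoverable subject ", sid, ": variable ", v,
             " has no valid sample", call. = FALSE)
      }
      if (anyNA(x)) {
        x <- zoo::na.locf(x, na.rm = FALSE)
        x <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)  # missing prefix
        d$series[[v]][per[[sid]]] <- x
      }
    }
  }
  d
}

#' Truncate all series to the length of the shortest one
#'
#' When subjects carry unequal raw series lengths, every series is cut to its
#' first T samples, T being the minimum length over subjects, producing the
#' rectangular layout downstream stages require.
#'
#' @inheritParams interpolate_missing
#' @return The truncated (rectangular) dataset.
#' @export
truncate_to_common_length <- function(d) {
  lens <- series_lengths(d)
  if (any(lens == 0)) {
    stop("subject(s) with zero samples: ",
         paste(names(lens)[lens == 0], collapse = ", "), call. = FALSE)
  }
  T_ <- min(lens)
  d$series <- d$series[d$series$t < T_, , drop = FALSE]
  validate_dataset(d, rectangular = TRUE)
}

#' Encode / decode categorical variables
#'
#' `encode_categoricals()` maps each categorical variable to integer codes
#' (`scheme = "label"`, codes 0..k-1 in schema category order — the format the
#' DGAN backend embeds) or to k indicator columns named `var=category`
#' summing to one per row (`scheme = "onehot"` — the format the WGAN-GP
#' consumes). `decode_categoricals()` inverts either encoding exactly
#' (onehot by argmax when rows are not exactly indicators).
#'
#' @inheritParams interpolate_missing
#' @param scheme `"label"` or `"onehot"`.
#' @return The re-encoded dataset with its schema's `encoding` field updated.
#' @export
encode_categoricals <- function(d, scheme = c("onehot", "label")) {
  scheme <- match.arg(scheme)
  validate_dataset(d)
  for (v in d$schema$name[d$schema$kind == "categorical"]) {
    row <- schema_row(d$schema, v)
    if (row$encoding != "none") {
      stop("variable ", v, " already encoded (", row$encoding,
           "); decode first", call. = FALSE)
    }
    cats <- row$categories[[1]]
    comp <- if (row$component == "static") "static" else "series"
    vals <- as.character(d[[comp]][[v]])
    code <- match(vals, cats) - 1L
    if (any(is.na(code) & !is.na(vals))) {
      stop("unknown category for ", v, ": ",
           paste(unique(vals[is.na(code) & !is.na(vals)]), collapse = ", "),
           call. = FALSE)
    }
    if (scheme == "label") {
      d[[comp]][[v]] <- code
    } else {
      ind <- purrr::map(seq_along(cats), function(k) as.numeric(code == k - 1L))
      names(ind) <- paste0(v, "=", cats)
      tb <- d[[comp]]
      pos <- match(v, names(tb))
      d[[comp]] <- splice_cols(tb[setdiff(names(tb), v)], pos, ind)
    }
    d$schema$encoding[d$schema$name == v] <- scheme
  }
  validate_dataset(d)
}

#' @rdname encode_categoricals
#' @export
decode_categoricals <- function(d) {
  for (v in d$schema$name[d$schema$kind == "categorical"]) {
    row <- schema_row(d$schema, v)
    if (row$encoding == "none") next
    cats <- row$categories[[1]]
    comp <- if (row$component == "static") "static" else "series"
    if (row$encoding == "label") {
      d[[comp]][[v]] <- cats[as.integer(d[[comp]][[v]]) + 1L]
    } else {
      cols <- paste0(v, "=", cats)
      m <- as.matrix(d[[comp]][cols])
      lab <- cats[max.col(m, ties.method = "first")]
      lab[rowSums(is.na(m)) > 0] <- NA_character_
      tb <- d[[comp]]
      pos <- match(cols[1], names(tb))
      tb <- tb[setdiff(names(tb), cols)]
      d[[comp]] <- splice_cols(tb, pos, stats::setNames(list(lab), v))
    }
    d$schema$encoding[d$schema$name == v] <- "none"
  }
  validate_dataset(d)
}

#' Min-max scale numeric variables to [0, 1]
#'
#' Scales every numeric variable (static and dynamic) by its observed
#' minimum and maximum so generator outputs can use a sigmoid range; constant
#' variables map to 0. `inverse_scale()` restores the original units exactly
#' (within floating-point tolerance), including constants.
#'
#' @inheritParams interpolate_missing
#' @return `scale_minmax()`: a list with `dataset` and `scaling` (an
#'   `stsg_scaling` tibble of per-column min/max). `inverse_scale()`: the
#'   dataset in original units.
#' @export
scale_minmax <- function(d) {
  validate_dataset(d)
  num <- d$schema$name[d$schema$kind == "numeric"]
  rows <- purrr::map(num, function(v) {
    comp <- if (schema_row(d$schema, v)$component == "static") "static"
            else "series"
    x <- d[[comp]][[v]]
    tibble::tibble(variable = v, min = min(x, na.rm = TRUE),
                   max = max(x, na.rm = TRUE))
  })
  scaling <- dplyr::bind_rows(rows)
  class(scaling) <- unique(c("stsg_scaling", class(scaling)))
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    comp <- if (schema_row(d$schema, v)$component == "static") "static"
            else "series"
    rng <- scaling$max[i] - scaling$min[i]
    d[[comp]][[v]] <- if (rng == 0) {
      rep(0, length(d[[comp]][[v]]))
    } else {
      (d[[comp]][[v]] - scaling$min[i]) / rng
    }
  }
  list(dataset = d, scaling = scaling)
}

#' @rdname scale_minmax
#' @param scaling The `stsg_scaling` state returned by `scale_minmax()`.
#' @export
inverse_scale <- function(d, scaling) {
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    if (!v %in% d$schema$name) next
    comp <- if (schema_row(d$schema, v)$component == "static") "static"
            else "series"
    rng <- scaling$max[i] - scaling$min[i]
    d[[comp]][[v]] <- if (rng == 0) {
      rep(scaling$min[i], length(d[[comp]][[v]]))
    } else {
      d[[comp]][[v]] * rng + scaling$min[i]
    }
  }
  d
}

#' Filter subjects by a predicate over their static row and series
#'
#' The generic cohort-selection mechanism: `predicate(static_row, series)`
#' receives one subject's static row (1-row tibble) and series (tibble) and
#' returns `TRUE` to retain the subject.
#'
#' @inheritParams interpolate_missing
#' @param predicate `function(static_row, series) -> logical(1)`.
#' @return A list with `dataset` (retained subjects) and `excluded` ids.
#' @export
filter_subjects <- function(d, predicate) {
  validate_dataset(d)
  sid <- d$static$subject_id
  per <- split(d$series, factor(d$series$subject_id, levels = sid))
  keep <- vapply(seq_along(sid), function(i) {
    ok <- tryCatch(predicate(d$static[i, , drop = FALSE], per[[i]]),
                   error = function(e) {
                     stop("predicate failed on subject ", sid[i], ": ",
                          conditionMessage(e), call. = FALSE)
                   })
    if (!is.logical(ok) || length(ok) != 1 || is.na(ok)) {
      stop("predicate failed on subject ", sid[i],
           ": did not return TRUE/FALSE", call. = FALSE)
    }
    ok
  }, logical(1))
  list(dataset = keep_subjects(d, sid[keep]), excluded = sid[!keep])
}
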