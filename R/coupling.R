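#' Per-subject series summary statistics
#'
#' Computes the maximum, minimum and mean of each dynamic variable per
#' subject. These summaries are the "meaningful statistical measurements"
#' treated as additional metadata: the coupling step matches synthetic
#' metadata rows to series through them.
#'
#' @param d A rectangular, fully observed `longitudinal_dataset`.
#' @return A tibble with `subject_id` and columns `<var>_max`, `<var>_min`,
#'   `<var>_mean` per dynamic variable, in the variable's original units.
#' @export
summarize_series <- function(d) {
  validate_dataset(d, rectangular = TRUE)
  dyn <- unlist(lapply(dataset_dynamic_vars(d), variable_columns,
                       schema = d$schema))
  if (any(vapply(dyn, function(v) anyNA(d$series[[v]]), logical(1)))) {
    stop("series contain missing values; run interpolate_missing() or ",
         "forward_fill() first", call. = FALSE)
  }
  out <- tibble::tibble(subject_id = d$static$subject_id)
  for (v in dyn) {
    m <- series_matrix(d, v)
    out[[paste0(v, "_max")]] <- unname(apply(m, 1, max))
    out[[paste0(v, "_min")]] <- unname(apply(m, 1, min))
    out[[paste0(v, "_mean")]] <- unname(rowMeans(m))
  }
  out
}

summary_columns <- function(summary) setdiff(names(summary), "subject_id")

#' Augment a metadata table with series summaries
#'
#' Extends the static table with the per-subject summary statistics of the
#' series ([summarize_series()]), yielding the augmented metadata on which
#' the metadata-only generator is trained in the A1 and A2 strategies. The
#' returned dataset is static-only (the series component is intentionally
#' dropped: downstream, series re-enter through coupling).
#'
#' @param d A `longitudinal_dataset` (its static component is augmented), or
#'   a static-only dataset if `summary` is supplied.
#' @param summary Optional summary tibble from [summarize_series()];
#'   computed from `d` when `NULL`.
#' @return A static-only `longitudinal_dataset` whose schema gains
#'   3 x (number of dynamic variables) numeric static columns.
#' @export
augment_metadata <- function(d, summary = NULL) {
  if (is.null(summary)) summary <- summarize_series(d)
  if (!identical(as.character(summary$subject_id),
                 as.character(d$static$subject_id))) {
    stop("alignment error: summary subjects differ from static table",
         call. = FALSE)
  }
  cols <- summary_columns(summary)
  static <- dplyr::bind_cols(d$static, summary[cols])
  sch <- subset_schema(d$schema, "static")
  if (length(cols)) {
    sch <- dplyr::bind_rows(sch, variable_schema(
      name = cols, kind = "numeric", component = "static",
      categories = vector("list", length(cols))))
  }
  longitudinal_dataset(validate_schema(sch), static,
                       tibble::tibble(subject_id = character(0),
                                      t = integer(0)),
                       time_unit = d$time_unit)
}

# Jonker-Volgenant shortest-augmenting-path solver for the rectangular
# (n <= m) minimum-cost assignment problem; returns the matched column per
# row. O(n * m^2) with vectorized inner sweeps.
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("cost matrix must have nrow <= ncol", call. = FALSE)
  ur <- numeric(n + 1)          # row potentials, index r + 1 (row 0 virtual)
  vc <- numeric(m + 1)          # column potentials, index j + 1 (col 0 virtual)
  p <- integer(m + 1)           # p[j + 1]: row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    way <- integer(m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- cost[i0, free] - ur[i0 + 1] - vc[free + 1]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) - 1L              # 0-based used columns
      ur[p[usedj + 1] + 1] <- ur[p[usedj + 1] + 1] + delta
      vc[usedj + 1] <- vc[usedj + 1] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_col <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) match_col[p[j + 1]] <- j
  match_col
}

greedy_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  used <- rep(FALSE, m)
  match_col <- integer(n)
  for (i in seq_len(n)) {
    j <- which(!used)[which.min(cost[i, !used])]
    match_col[i] <- j
    used[j] <- TRUE
  }
  match_col
}

#' Coherently couple synthetic metadata to a series pool
#'
#' Pairs each synthetic (augmented) metadata row with a distinct subject
#' from a series pool so that the distance between the synthesized summary
#' statistics and the pool subject's actual summaries is as small as
#' possible. Distances are Euclidean in summary space, by default after
#' per-column standardization by the pool's mean and SD (so variables of
#' different units weigh comparably). `method = "hungarian"` minimizes the
#' total distance globally (optimal assignment); `"greedy"` pairs rows in
#' input order to the nearest unused pool subject (faster, order-dependent,
#' never better than hungarian). Each pool series is used at most once.
#'
#' @param synthetic A static-only `longitudinal_dataset` carrying the
#'   summary columns (`<var>_max/_min/_mean`), e.g. sampled from a generator
#'   trained on [augment_metadata()] output.
#' @param pool A `longitudinal_dataset` providing the series (real for A1,
#'   synthetic for A2); must have at least as many subjects as `synthetic`.
#' @param method `"hungarian"` (default) or `"greedy"`.
#' @param standardize Standardize summary columns by pool mean/SD before
#'   computing distances.
#' @param keep_summaries Keep the synthetic summary columns in the output
#'   metadata (default drops them: they disagree with the attached series).
#' @return A list with `dataset` (coupled `longitudinal_dataset`) and
#'   `coupling` (an `stsg_coupling`: per-pair distances, total, method).
#' @export
couple <- function(synthetic, pool, method = c("hungarian", "greedy"),
                   standardize = TRUE, keep_summaries = FALSE) {
  method <- match.arg(method)
  pool_summary <- summarize_series(pool)
  cols <- summary_columns(pool_summary)
  missing_cols <- setdiff(cols, names(synthetic$static))
  if (length(missing_cols)) {
    stop("synthetic metadata lacks summary column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- n_subjects(synthetic); m <- n_subjects(pool)
  if (n > m) {
    stop("capacity error: ", n, " synthetic rows but only ", m,
         " pool subjects", call. = FALSE)
  }

  S <- as.matrix(synthetic$static[cols])
  P <- as.matrix(pool_summary[cols])
  if (standardize) {
    mu <- colMeans(P)
    sdv <- pmax(apply(P, 2, stats::sd), 1e-12)
    S <- sweep(sweep(S, 2, mu), 2, sdv, "/")
    P <- sweep(sweep(P, 2, mu), 2, sdv, "/")
  }
  tP <- t(P)
  cost <- t(vapply(seq_len(n), function(i) sqrt(colSums((tP - S[i, ])^2)),
                   numeric(m)))
  if (m == 1) cost <- matrix(cost, nrow = n)

  match_col <- if (method == "hungarian") hungarian_assign(cost)
               else greedy_assign(cost)
  dist_i <- cost[cbind(seq_len(n), match_col)]

  pairing <- tibble::tibble(
    synthetic_id = synthetic$static$subject_id,
    pool_id = pool$static$subject_id[match_col],
    distance = dist_i
  )
  coupling <- structure(
    list(pairing = pairing, total_distance = sum(dist_i), method = method),
    class = "stsg_coupling")

  # assemble: synthetic static (summaries optionally dropped) + paired series
  static <- synthetic$static
  sch_static <- subset_schema(synthetic$schema, "static")
  if (!keep_summaries) {
    static <- static[setdiff(names(static), cols)]
    sch_static <- validate_schema(
      sch_static[!sch_static$name %in% cols, , drop = FALSE])
  }
  T_ <- series_length(pool)
  pool_rows <- unlist(lapply(match_col, function(j) {
    (j - 1L) * T_ + seq_len(T_)
  }))
  ord <- order(match(pool$series$subject_id, pool$static$subject_id),
               pool$series$t)
  series <- pool$series[ord, , drop = FALSE][pool_rows, , drop = FALSE]
  series$subject_id <- rep(synthetic$static$subject_id, each = T_)

  schema <- validate_schema(dplyr::bind_rows(
    sch_static, subset_schema(pool$schema, "dynamic")))
  ds <- longitudinal_dataset(schema, static, series,
                             time_unit = pool$time_unit)
  list(dataset = ds, coupling = coupling)
}

#' @export
print.stsg_coupling <- function(x, ...) {
  cat(sprintf("<stsg_coupling> %s assignment, %d pairs, total distance %.4g\n",
              x$method, nrow(x$pairing), x$total_distance))
  invisible(x)
}
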