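# Independent oracles used across the suite. These deliberately re-derive
# quantities with different code paths than the implementation.

# all permutations of a vector (for exhaustive assignment search, n <= 7)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# exhaustive minimum-cost assignment of rows to distinct columns
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in all_perms(seq_len(ncol(cost)))) {
    tot <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (tot < best) best <- tot
  }
  best
}

# scan-based reference gap filler: forward fill then backfill the prefix
scan_forward_fill <- function(x) {
  last <- NA
  for (i in seq_along(x)) {
    if (!is.na(x[i])) last <- x[i] else x[i] <- last
  }
  first <- x[which(!is.na(x))[1]]
  x[is.na(x)] <- first
  x
}

# reference linear interpolation with nearest-valid boundary extension
scan_interpolate <- function(x) {
  obs <- which(!is.na(x))
  out <- x
  for (i in seq_along(x)) {
    if (!is.na(x[i])) next
    lo <- max(obs[obs < i], -Inf)
    hi <- min(obs[obs > i], Inf)
    out[i] <- if (!is.finite(lo)) x[hi]
              else if (!is.finite(hi)) x[lo]
              else x[lo] + (x[hi] - x[lo]) * (i - lo) / (hi - lo)
  }
  out
}

# closed-form lambda sweep for two-distribution precision/recall, written
# independently of the package implementation
oracle_prd_sweep <- function(p, q, n_angles) {
  angles <- (seq_len(n_angles) / (n_angles + 1)) * pi / 2
  t(vapply(angles, function(th) {
    l <- tan(th)
    c(alpha = sum(pmin(l * p, q)), beta = sum(pmin(p, q / l)))
  }, numeric(2)))
}

# column-wise independent shuffling: keeps marginals, destroys associations
shuffle_control <- function(d, seed) {
  stsg:::with_seed(seed, {
    n <- nrow(d$static)
    for (v in d$schema$name[d$schema$component == "static"]) {
      d$static[[v]] <- d$static[[v]][sample(n)]
    }
    for (v in d$schema$name[d$schema$component == "dynamic"]) {
      m <- stsg:::series_matrix(d, v)[sample(n), , drop = FALSE]
      d <- stsg:::set_series_matrix(d, v, m)
    }
    d
  })
}

# a tiny hand-buildable dataset: one dynamic variable from a matrix
series_dataset <- function(m, static = NULL, var = "y") {
  n <- nrow(m); T_ <- ncol(m)
  sid <- sprintf("s%03d", seq_len(n))
  if (is.null(static)) static <- tibble::tibble(subject_id = sid,
                                                x = seq_len(n))
  static$subject_id <- sid
  svars <- setdiff(names(static), "subject_id")
  schema <- variable_schema(
    name = c(svars, var),
    kind = "numeric",
    component = c(rep("static", length(svars)), "dynamic"),
    categories = vector("list", length(svars) + 1)
  )
  series <- tibble::tibble(subject_id = rep(sid, each = T_),
                           t = rep(seq_len(T_) - 1L, n))
  series[[var]] <- as.vector(t(m))
  longitudinal_dataset(schema, static, series)
}

# series of one fold, keyed for bit-exact multiset comparison
series_keys <- function(d) {
  vars <- d$schema$name[d$schema$component == "dynamic"]
  sid <- d$static$subject_id
  vapply(sid, function(s) {
    rows <- d$series[d$series$subject_id == s, vars, drop = FALSE]
    paste(vapply(rows, function(col) paste(sprintf("%.15g", col),
                                           collapse = ","), character(1)),
          collapse = ";")
  }, character(1))
}
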