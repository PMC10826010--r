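#' Membership inference attack (MIA)
#'
#' Simulates an adversary who holds a fraction of the records used to train
#' the generator plus published synthetic data, and tries to tell members
#' (training subjects) from non-members. The candidate set contains
#' `known_fraction` of `real_train` (members) and an equally sized sample
#' of `real_holdout` (non-members, the false-positive population that makes
#' precision well defined). Records are flattened and per-column min-max
#' normalized on the union of candidates and synthetic records; a candidate
#' is flagged as disclosed when any synthetic record lies within cosine
#' distance `threshold` of it (a single match suffices). Precision is
#' TP / (TP + FP), defined as 0 when nothing is flagged.
#'
#' @param real_train Real dataset the generator was trained on.
#' @param real_holdout Real dataset disjoint from `real_train`.
#' @param synth Synthetic dataset (assumed public).
#' @param known_fraction Fraction of `real_train` the adversary holds,
#'   in `(0, 1]`.
#' @param threshold Cosine-distance disclosure threshold (default 0.2).
#' @param seed Integer seed for the candidate draws.
#' @param series_points Flattening resolution, see [flatten_records()].
#' @return A one-row tibble: `known_fraction`, `precision`, `n_flagged`,
#'   `tp`, `fp`.
#' @export
mia <- function(real_train, real_holdout, synth, known_fraction,
                threshold = 0.2, seed = 1L, series_points = 8) {
  if (known_fraction <= 0 || known_fraction > 1) {
    stop("known_fraction must lie in (0, 1]", call. = FALSE)
  }
  Xtr <- record_matrix(real_train, series_points)
  Xho <- record_matrix(real_holdout, series_points)
  Xsy <- record_matrix(synth, series_points)

  k <- max(1L, round(known_fraction * nrow(Xtr)))
  if (nrow(Xho) < k) {
    stop("holdout too small: need ", k, " non-member candidates, have ",
         nrow(Xho), call. = FALSE)
  }
  with_seed(seed, {
    mem <- Xtr[sample.int(nrow(Xtr), k), , drop = FALSE]
    non <- Xho[sample.int(nrow(Xho), k), , drop = FALSE]
    cand <- rbind(mem, non)
    is_member <- c(rep(TRUE, k), rep(FALSE, k))

    # per-column min-max on the union so no unit dominates the angle
    un <- rbind(cand, Xsy)
    lo <- apply(un, 2, min); hi <- apply(un, 2, max)
    rng <- pmax(hi - lo, 1e-12)
    norm01 <- function(M) sweep(sweep(M, 2, lo), 2, rng, "/")
    C <- norm01(cand); S <- norm01(Xsy)

    cn <- sqrt(rowSums(C^2)); sn <- sqrt(rowSums(S^2))
    sim <- (C %*% t(S)) / (pmax(cn, 1e-12) %o% pmax(sn, 1e-12))
    dist <- 1 - sim
    flagged <- apply(dist <= threshold, 1, any)

    tp <- sum(flagged & is_member); fp <- sum(flagged & !is_member)
    tibble::tibble(
      known_fraction = known_fraction,
      precision = if (tp + fp == 0) 0 else tp / (tp + fp),
      n_flagged = tp + fp, tp = tp, fp = fp)
  })
}

#' @rdname mia
#' @param fractions Grid of adversary knowledge fractions (default
#'   `seq(0.1, 0.5, by = 0.1)`). Each fraction is evaluated with a seed
#'   derived as `seed + round(1000 * fraction)`, so single-fraction [mia()]
#'   calls with the same derived seed reproduce each row exactly.
#' @return `mia_curve()`: an `stsg_mia` with the per-fraction table.
#' @export
mia_curve <- function(real_train, real_holdout, synth,
                      fractions = seq(0.1, 0.5, by = 0.1), threshold = 0.2,
                      seed = 1L, series_points = 8) {
  rows <- purrr::map(fractions, function(f) {
    mia(real_train, real_holdout, synth, known_fraction = f,
        threshold = threshold, seed = seed + round(1000 * f),
        series_points = series_points)
  })
  structure(list(result = dplyr::bind_rows(rows), threshold = threshold,
                 seed = seed),
            class = "stsg_mia")
}

#' @export
print.stsg_mia <- function(x, ...) {
  cat(sprintf("<stsg_mia> threshold %.2f\n", x$threshold))
  print(x$result)
  invisible(x)
}
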