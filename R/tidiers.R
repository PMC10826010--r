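# broom-style tidiers: tidy() returns the per-unit table of a result,
# glance() a one-row summary.

#' @export
tidy.stsg_generator <- function(x, ...) x$trace

#' @export
glance.stsg_generator <- function(x, ...) {
  last <- x$trace[nrow(x$trace), , drop = FALSE]
  tibble::tibble(backend = x$backend, mode = x$mode, n_train = x$n_train,
                 steps = nrow(x$trace),
                 final_gen_loss = last$gen_loss %||% NA_real_)
}

#' @export
tidy.stsg_report <- function(x, ...) x$per_fold

#' @export
glance.stsg_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = c("mean", "std"))
  dplyr::bind_cols(
    tibble::tibble(approach = x$provenance$approach,
                   backend = x$provenance$backend,
                   n_folds = length(x$seeds)),
    wide)
}

#' @export
tidy.stsg_prd <- function(x, ...) x$pairs

#' @export
glance.stsg_prd <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs),
                 max_f8 = f_gamma(x, 8),
                 max_f1 = f_gamma(x, 1))
}

#' @export
tidy.stsg_dla <- function(x, ...) x$result

#' @export
glance.stsg_dla <- function(x, ...) tibble::tibble(mean_auroc = x$mean_auroc)

#' @export
tidy.stsg_tstr <- function(x, ...) x$result

#' @export
glance.stsg_tstr <- function(x, ...) {
  tibble::tibble(target = x$target, similarity = x$similarity)
}

#' @export
tidy.stsg_mia <- function(x, ...) x$result

#' @export
glance.stsg_mia <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 mean_precision = mean(x$result$precision),
                 max_precision = max(x$result$precision))
}

#' @export
tidy.stsg_acf_mae <- function(x, ...) x$result

#' @export
tidy.stsg_coupling <- function(x, ...) x$pairing

#' @export
glance.stsg_coupling <- function(x, ...) {
  tibble::tibble(method = x$method, n_pairs = nrow(x$pairing),
                 total_distance = x$total_distance,
                 mean_distance = mean(x$pairing$distance))
}

#' @export
tidy.stsg_assoc <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    var1 = rep(rownames(m), times = ncol(m)),
    var2 = rep(colnames(m), each = nrow(m)),
    association = as.vector(m)
  )
}
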