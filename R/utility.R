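#' Train-on-synthetic-test-on-real utility assessment
#'
#' Measures whether models built from synthetic data behave like models
#' built from real data. Twin regressors (random forest, kNN, decision
#' tree, linear SVM, MLP — the regression counterparts of the DLA
#' classifier settings) are trained once on the real training set (TRTR)
#' and once on the synthetic set (TSTR); both are evaluated on the same
#' held-out real test set with the mean absolute error. The utility score
#' is the cosine similarity between the two per-regressor MAE vectors:
#' 1 means synthetic-trained models err exactly like real-trained ones.
#'
#' The regression task predicts the per-subject mean of `target` from all
#' remaining flattened features (the target's own summary and sampled
#' series columns are excluded from the design).
#'
#' @param real_train,real_test Disjoint real `longitudinal_dataset`s (or
#'   record data frames).
#' @param synth Synthetic dataset produced without access to `real_test`.
#' @param target Dynamic-variable name (numeric) to predict.
#' @param regressors Subset of `c("rf", "knn", "dt", "svm", "mlp")`.
#' @param seed Integer seed controlling all model fits.
#' @param series_points Flattening resolution, see [flatten_records()].
#' @return An `stsg_tstr`: per-regressor MAE under TRTR and TSTR, plus
#'   `similarity` in `[0, 1]`.
#' @export
tstr_trtr <- function(real_train, real_test, synth, target,
                      regressors = c("rf", "knn", "dt", "svm", "mlp"),
                      seed = 1L, series_points = 8) {
  Xtr <- record_matrix(real_train, series_points)
  Xte <- record_matrix(real_test, series_points)
  Xsy <- record_matrix(synth, series_points)
  ycol <- paste0(target, "_mean")
  if (!ycol %in% colnames(Xtr)) {
    stop("target must be a numeric dynamic variable; no column ", ycol,
         call. = FALSE)
  }
  drop <- grep(paste0("^", target, "_"), colnames(Xtr), value = TRUE)
  feats <- setdiff(colnames(Xtr), drop)

  y_tr <- Xtr[, ycol]; y_te <- Xte[, ycol]; y_sy <- Xsy[, ycol]
  if (stats::sd(y_tr) == 0 || stats::sd(y_sy) == 0) {
    stop("degenerate target: zero variance", call. = FALSE)
  }

  fit_side <- function(X, y) {
    vapply(regressors, function(mo) {
      pred <- ml_regress(mo, X[, feats, drop = FALSE], y,
                         Xte[, feats, drop = FALSE], seed = seed)
      mean(abs(pred - y_te))
    }, numeric(1))
  }
  mae_trtr <- fit_side(Xtr, y_tr)
  mae_tstr <- fit_side(Xsy, y_sy)
  sim <- sum(mae_trtr * mae_tstr) /
    (sqrt(sum(mae_trtr^2)) * sqrt(sum(mae_tstr^2)))

  structure(list(
    result = tibble::tibble(model = regressors,
                            mae_trtr = unname(mae_trtr),
                            mae_tstr = unname(mae_tstr)),
    similarity = sim, target = target, seed = seed),
    class = "stsg_tstr")
}

#' @export
print.stsg_tstr <- function(x, ...) {
  cat(sprintf("<stsg_tstr> target %s, TSTR similarity %.4f\n",
              x$target, x$similarity))
  print(x$result)
  invisible(x)
}
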