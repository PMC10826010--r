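#' Cramér's V from a contingency table
#'
#' \eqn{V = \sqrt{\chi^2 / (n \cdot \min(r - 1, c - 1))}} with the standard
#' Pearson chi-squared statistic (no continuity correction). Zero-marginal
#' rows and columns are dropped before computation; if fewer than two rows
#' or columns remain the association is undefined and `NA` is returned.
#'
#' @param tab A matrix (or table) of nonnegative counts.
#' @return A value in `[0, 1]`, or `NA` if undefined.
#' @examples
#' cramers_v(matrix(c(10, 0, 0, 10), 2))   # 1: perfect association
#' cramers_v(matrix(c(5, 5, 5, 5), 2))     # 0: exact independence
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  if (n == 0) stop("empty table", call. = FALSE)
  k <- min(nrow(tab) - 1L, ncol(tab) - 1L)
  if (k < 1) return(NA_real_)
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  as.numeric(sqrt(chi2 / (n * k)))
}

# R^2 of regressing a numeric feature on categorical group indicators
# (equals the between-group share of the total sum of squares)
mixed_r2 <- function(num, cat) {
  ok <- !is.na(num) & !is.na(cat)
  num <- num[ok]; cat <- as.character(cat[ok])
  tot <- sum((num - mean(num))^2)
  if (tot == 0 || length(unique(cat)) < 2) return(NA_real_)
  gm <- tapply(num, cat, mean)
  gn <- tapply(num, cat, length)
  sum(gn * (gm - mean(num))^2) / tot
}

#' Mixed-type association matrix
#'
#' Pairwise associations over all variables of a dataset: Pearson r for
#' numeric pairs, Cramér's V (from chi-squared) for categorical pairs, and
#' the R-squared of regressing the numeric feature on the categorical one
#' for mixed pairs. Dynamic variables enter through per-subject
#' representatives: their series mean (`include` contains `"dynamic"`)
#' and/or their full max/min/mean summary triple (`"summaries"`).
#' Zero-variance features yield masked (`NA`) cells rather than silent
#' zeros, mirroring the blank cells of association heatmaps.
#'
#' @param d A rectangular, complete `longitudinal_dataset` (or a plain
#'   data frame of records, treated as all-static).
#' @param include Character subset of `c("static", "dynamic", "summaries")`.
#' @return An `stsg_assoc`: list with `matrix` (symmetric, unit diagonal
#'   where defined), `vars` (name/kind tibble) and `include`.
#' @export
mixed_association_matrix <- function(d, include = c("static", "dynamic")) {
  include <- match.arg(include, c("static", "dynamic", "summaries"),
                       several.ok = TRUE)
  cols <- list(); kinds <- character(0)

  if (inherits(d, "longitudinal_dataset")) {
    if (n_subjects(d) < 2) stop("insufficient data: need >= 2 subjects",
                                call. = FALSE)
    if ("static" %in% include) {
      for (v in dataset_static_vars(d)) {
        row <- schema_row(d$schema, v)
        if (row$encoding == "onehot") {
          cc <- variable_columns(d$schema, v)
          m <- as.matrix(d$static[cc])
          cols[[v]] <- row$categories[[1]][max.col(m, ties.method = "first")]
        } else if (row$encoding == "label") {
          cols[[v]] <- row$categories[[1]][as.integer(d$static[[v]]) + 1L]
        } else {
          cols[[v]] <- d$static[[v]]
        }
        kinds <- c(kinds, row$kind)
      }
    }
    if (any(c("dynamic", "summaries") %in% include)) {
      sm <- summarize_series(d)
      for (v in dataset_dynamic_vars(d)) {
        if ("dynamic" %in% include) {
          cols[[v]] <- sm[[paste0(v, "_mean")]]
          kinds <- c(kinds, "numeric")
        }
        if ("summaries" %in% include) {
          for (s in c("max", "min")) {
            cols[[paste0(v, "_", s)]] <- sm[[paste0(v, "_", s)]]
            kinds <- c(kinds, "numeric")
          }
          if (!"dynamic" %in% include) {
            cols[[paste0(v, "_mean")]] <- sm[[paste0(v, "_mean")]]
            kinds <- c(kinds, "numeric")
          }
        }
      }
    }
  } else {
    df <- tibble::as_tibble(d)
    df$subject_id <- NULL
    if (nrow(df) < 2) stop("insufficient data: need >= 2 rows", call. = FALSE)
    for (v in names(df)) {
      cols[[v]] <- df[[v]]
      kinds <- c(kinds, if (is.numeric(df[[v]])) "numeric" else "categorical")
    }
  }

  p <- length(cols)
  M <- matrix(NA_real_, p, p, dimnames = list(names(cols), names(cols)))
  defined <- function(i) {
    if (kinds[i] == "numeric") stats::sd(cols[[i]]) > 0
    else length(unique(cols[[i]])) > 1
  }
  def <- vapply(seq_len(p), defined, logical(1))
  for (i in seq_len(p)) {
    if (def[i]) M[i, i] <- 1
    if (i == 1) next
    for (j in seq_len(i - 1)) {
      if (!def[i] || !def[j]) next
      val <- if (kinds[i] == "numeric" && kinds[j] == "numeric") {
        stats::cor(cols[[i]], cols[[j]])
      } else if (kinds[i] == "categorical" && kinds[j] == "categorical") {
        cramers_v(table(cols[[i]], cols[[j]]))
      } else if (kinds[i] == "numeric") {
        mixed_r2(cols[[i]], cols[[j]])
      } else {
        mixed_r2(cols[[j]], cols[[i]])
      }
      M[i, j] <- M[j, i] <- val
    }
  }
  structure(list(matrix = M,
                 vars = tibble::tibble(name = names(cols), kind = kinds),
                 include = include),
            class = "stsg_assoc")
}

#' @export
print.stsg_assoc <- function(x, ...) {
  cat(sprintf("<stsg_assoc> %d variables (%d masked cells)\n",
              nrow(x$matrix), sum(is.na(x$matrix))))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Correlation-preservation score between two association matrices
#'
#' Flattens the strict lower triangles of both matrices over their jointly
#' defined cells and returns the cosine similarity of the two vectors
#' (1 means identical correlation structure). `variant = "printed"`
#' additionally exposes a normalization by the product of the vector sums
#' instead of the product of norms; it is not bounded in `[-1, 1]` and is
#' kept only for comparability.
#'
#' @param real_assoc,synth_assoc `stsg_assoc` objects or plain square
#'   matrices with identical variable order.
#' @param variant `"cosine"` (default) or `"printed"`.
#' @return A single number (in `[-1, 1]` for `"cosine"`).
#' @export
correlation_similarity <- function(real_assoc, synth_assoc,
                                   variant = c("cosine", "printed")) {
  variant <- match.arg(variant)
  R <- as_assoc_matrix(real_assoc); S <- as_assoc_matrix(synth_assoc)
  if (!identical(dim(R), dim(S))) {
    stop("association matrices must have the same shape", call. = FALSE)
  }
  lt <- lower.tri(R)
  ok <- lt & !is.na(R) & !is.na(S)
  if (!any(ok)) stop("undefined similarity: all cells masked", call. = FALSE)
  x <- R[ok]; y <- S[ok]
  if (variant == "cosine") {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) {
      stop("undefined similarity: zero-norm correlation vector",
           call. = FALSE)
    }
    sum(x * y) / (nx * ny)
  } else {
    sum(x * y) / (sum(x) * sum(y))
  }
}

#' Data-labelling analysis (DLA)
#'
#' Trains five classifiers (random forest, kNN, decision tree, linear SVM
#' and an MLP — see [ml_model_configs] in the package source for the exact
#' settings) to distinguish real records (label 0) from synthetic records
#' (label 1) on a stratified 70/30 split, simulating a GAN discriminator.
#' AUROC near 0.5 means the sources are indistinguishable; near 1 means the
#' synthetic data is easily separated.
#'
#' @param real,synth `longitudinal_dataset`s (flattened internally via
#'   [flatten_records()]) or record data frames with identical columns.
#' @param split Held-out fraction for evaluation (default 0.3).
#' @param seed Integer seed for the split and model fits.
#' @param classifiers Subset of `c("rf", "knn", "dt", "svm", "mlp")`.
#' @return An `stsg_dla`: tibble with per-classifier AUROC and the
#'   configuration echo, plus `mean_auroc`.
#' @export
dla <- function(real, synth, split = 0.3, seed = 1L,
                classifiers = c("rf", "knn", "dt", "svm", "mlp")) {
  Xr <- record_matrix(real); Xs <- record_matrix(synth)
  if (!identical(colnames(Xr), colnames(Xs))) {
    stop("real and synthetic records must share identical columns",
         call. = FALSE)
  }
  X <- rbind(Xr, Xs)
  y <- c(rep(0, nrow(Xr)), rep(1, nrow(Xs)))

  with_seed(seed, {
    test_idx <- c(sample.int(nrow(Xr), max(1, round(split * nrow(Xr)))),
                  nrow(Xr) + sample.int(nrow(Xs),
                                        max(1, round(split * nrow(Xs)))))
    tr <- setdiff(seq_along(y), test_idx)
    aurocs <- vapply(classifiers, function(mo) {
      sc <- ml_classify(mo, X[tr, , drop = FALSE], y[tr],
                        X[test_idx, , drop = FALSE], seed = seed)
      as.numeric(pROC::auc(y[test_idx], sc, quiet = TRUE,
                           direction = "<", levels = c(0, 1)))
    }, numeric(1))
    res <- dplyr::left_join(
      tibble::tibble(model = classifiers, auroc = unname(aurocs)),
      ml_model_configs(), by = "model")
    structure(list(result = res, mean_auroc = mean(aurocs)),
              class = "stsg_dla")
  })
}

#' @export
print.stsg_dla <- function(x, ...) {
  cat(sprintf("<stsg_dla> mean AUROC %.3f\n", x$mean_auroc))
  print(x$result[c("model", "auroc")])
  invisible(x)
}

#' Precision-recall distribution (PRD) curve
#'
#' Compares a synthetic sample with a real one through the
#' precision/recall-for-distributions construction: the pooled records are
#' clustered, per-cluster histograms p (real) and q (synthetic) are formed,
#' and for a sweep of trade-off slopes \eqn{\lambda = \tan\theta} over
#' `n_angles` angles in \eqn{(0, \pi/2)} the pairs
#' \deqn{\alpha(\lambda) = \sum_c \min(\lambda p_c, q_c), \quad
#'       \beta(\lambda) = \sum_c \min(p_c, q_c / \lambda)}
#' are collected. \eqn{\alpha} (precision) reflects synthetic sample
#' quality, \eqn{\beta} (recall) the coverage of the real distribution.
#'
#' @param real,synth `longitudinal_dataset`s or record data frames.
#' @param n_clusters Number of pooled k-means clusters (default 20).
#' @param n_angles Number of \eqn{\lambda} sweep angles (default 1001; the
#'   symmetric grid guarantees the \eqn{\lambda \leftrightarrow 1/\lambda}
#'   closure of the pair set).
#' @param seed Seed for the clustering.
#' @return An `stsg_prd`: tibble of `(alpha, beta)` pairs plus settings.
#' @export
prd_curve <- function(real, synth, n_clusters = 20, n_angles = 1001,
                      seed = 1L) {
  Xr <- record_matrix(real); Xs <- record_matrix(synth)
  if (nrow(Xr) == 0 || nrow(Xs) == 0) stop("empty sample", call. = FALSE)
  pool <- rbind(Xr, Xs)
  st <- ml_scale_fit(pool)
  pool <- ml_scale_apply(pool, st)
  k <- min(n_clusters, nrow(unique(pool)))
  cl <- with_seed(seed, stats::kmeans(pool, centers = k, nstart = 5,
                                      iter.max = 50))$cluster
  p <- tabulate(cl[seq_len(nrow(Xr))], k) / nrow(Xr)
  q <- tabulate(cl[nrow(Xr) + seq_len(nrow(Xs))], k) / nrow(Xs)
  prd_from_histograms(p, q, n_angles = n_angles,
                      settings = list(n_clusters = k, n_angles = n_angles))
}

#' @rdname prd_curve
#' @param p,q Probability histograms over a shared support (real and
#'   synthetic); `prd_from_histograms()` is the clustering-free entry point.
#' @param settings Optional settings list stored on the result.
#' @export
prd_from_histograms <- function(p, q, n_angles = 1001, settings = NULL) {
  if (length(p) != length(q)) stop("histograms differ in length",
                                   call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stop("histograms must sum to 1", call. = FALSE)
  }
  theta <- seq_len(n_angles) * (pi / 2) / (n_angles + 1)
  lambda <- tan(theta)
  alpha <- vapply(lambda, function(l) sum(pmin(l * p, q)), numeric(1))
  beta <- vapply(lambda, function(l) sum(pmin(p, q / l)), numeric(1))
  structure(list(
    pairs = tibble::tibble(lambda = lambda, alpha = alpha, beta = beta),
    settings = settings %||% list(n_clusters = NA_integer_,
                                  n_angles = n_angles)),
    class = "stsg_prd")
}

#' @export
print.stsg_prd <- function(x, ...) {
  cat(sprintf("<stsg_prd> %d (alpha, beta) pairs, max F8 = %.4f\n",
              nrow(x$pairs), f_gamma(x, 8)))
  invisible(x)
}

#' Maximum F-score of a PRD curve
#'
#' Merges a PRD curve into a single value:
#' \deqn{F_\gamma = (1 + \gamma^2) \frac{\alpha \beta}{\gamma^2 \alpha + \beta}}
#' maximized over the curve's pairs, with \eqn{F = 0} when
#' \eqn{\alpha = \beta = 0}. \eqn{\gamma > 1} weighs recall (coverage)
#' higher than precision; \eqn{\gamma = 8} is the conventional reporting
#' choice for this evaluation.
#'
#' @param curve An `stsg_prd` (or anything with `$pairs` alpha/beta columns,
#'   or a two-column data frame).
#' @param gamma Positive weighting factor.
#' @return The maximum F-score in `[0, 1]`.
#' @export
f_gamma <- function(curve, gamma = 8) {
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  pairs <- if (inherits(curve, "stsg_prd")) curve$pairs
           else tibble::as_tibble(curve)
  a <- pairs$alpha; b <- pairs$beta
  den <- gamma^2 * a + b
  f <- ifelse(den == 0, 0, (1 + gamma^2) * a * b / den)
  if (length(f) == 0) stop("empty curve", call. = FALSE)
  max(f)
}

#' Autocorrelation mean absolute error
#'
#' Per dynamic variable: the sample autocorrelation function at lags
#' `1..max_lag` is computed for each subject and averaged over subjects,
#' separately for the real and synthetic datasets; the MAE between the two
#' mean functions is reported (lower is better, 0 for identical series
#' sets, e.g. the real-coupling baseline). Constant series contribute no
#' ACF; a variable whose every series is constant is masked with a warning.
#'
#' @param real,synth Rectangular, complete `longitudinal_dataset`s sharing
#'   dynamic variables (T may differ; lags above the shorter T are not
#'   used).
#' @param max_lag Largest lag; default `min(40, T - 1)`.
#' @return An `stsg_acf_mae`: tibble `(variable, mae)` plus `mean_mae`.
#' @export
autocorrelation_mae <- function(real, synth, max_lag = NULL) {
  vars <- intersect(dataset_dynamic_vars(real), dataset_dynamic_vars(synth))
  if (!length(vars)) stop("no shared dynamic variables", call. = FALSE)
  T_ <- min(series_length(real), series_length(synth))
  if (is.null(max_lag)) max_lag <- min(40L, T_ - 1L)
  if (max_lag >= T_) stop("max_lag must be < T", call. = FALSE)

  mean_acf <- function(d, v) {
    m <- series_matrix(d, v)
    acfs <- apply(m, 1, function(x) {
      if (stats::sd(x) == 0) return(rep(NA_real_, max_lag))
      as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                            demean = TRUE)$acf)[-1]
    })
    if (all(is.na(acfs))) return(NULL)
    rowMeans(matrix(acfs, nrow = max_lag), na.rm = TRUE)
  }

  rows <- purrr::map(vars, function(v) {
    ar <- mean_acf(real, v); as <- mean_acf(synth, v)
    if (is.null(ar) || is.null(as)) {
      warning("variable ", v, " constant in all subjects; masked")
      return(tibble::tibble(variable = v, mae = NA_real_))
    }
    tibble::tibble(variable = v, mae = mean(abs(ar - as)))
  })
  res <- dplyr::bind_rows(rows)
  structure(list(result = res, mean_mae = mean(res$mae, na.rm = TRUE),
                 max_lag = max_lag),
            class = "stsg_acf_mae")
}

#' @export
print.stsg_acf_mae <- function(x, ...) {
  cat(sprintf("<stsg_acf_mae> mean MAE %.4f over lags 1..%d\n",
              x$mean_mae, x$max_lag))
  print(x$result)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
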