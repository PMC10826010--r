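test_that("cramers_v reproduces hand-computed values", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2)), 1.0)
  expect_equal(cramers_v(matrix(c(5, 5, 5, 5), 2)), 0.0)
  # chi2 = 5.0505, n = 20 -> V = sqrt(chi2 / 20) = 0.5025
  expect_equal(cramers_v(matrix(c(8, 3, 2, 7), 2)), 0.5025, tolerance = 1e-4)
  # permutation invariance of rows/columns
  tab <- matrix(c(8, 3, 2, 7), 2)
  expect_equal(cramers_v(tab), cramers_v(tab[2:1, 2:1]))
  # zero marginals are dropped; degenerate tables are undefined
  expect_equal(cramers_v(rbind(c(8, 2, 0), c(3, 7, 0))),
               cramers_v(rbind(c(8, 2), c(3, 7))))
  expect_true(is.na(cramers_v(matrix(c(5, 5), 1))))
})

test_that("correlation similarity follows the cosine hand cases", {
  mk <- function(v) {   # 3x3 matrix with lower triangle (v1, v2, masked)
    m <- diag(3)
    m[2, 1] <- m[1, 2] <- v[1]
    m[3, 1] <- m[1, 3] <- v[2]
    m[3, 2] <- m[2, 3] <- NA
    m
  }
  expect_equal(correlation_similarity(mk(c(1, 0)), mk(c(0, 1))), 0)
  expect_equal(correlation_similarity(mk(c(1, 1)), mk(c(1, 0))), 0.7071,
               tolerance = 1e-4)
  expect_equal(correlation_similarity(mk(c(0.4, -0.2)), mk(c(0.4, -0.2))), 1)
  # scale invariance in each argument
  expect_equal(correlation_similarity(mk(c(0.8, 0.2)), mk(c(0.4, 0.1))), 1)
  expect_error(correlation_similarity(mk(c(NA, NA)), mk(c(NA, NA))),
               "masked|undefined")
})

test_that("the mixed association matrix handles all variable-pair types", {
  stsg:::with_seed(31, {
    n <- 2000
    df <- tibble::tibble(
      a = rnorm(n),
      b = NA_real_,
      g = sample(c("u", "v", "w"), n, replace = TRUE),
      h = sample(c("x", "y"), n, replace = TRUE)
    )
    df$b <- 2 * df$a + rnorm(n, 0, 1e-9)      # perfectly linear pair
    df$h <- ifelse(df$g == "u", "x", df$h)    # dependent categorical pair
    A <- mixed_association_matrix(df)
    expect_equal(A$matrix["a", "b"], 1, tolerance = 1e-6)
    expect_true(A$matrix["g", "h"] > 0.2)
    # numeric feature independent of a category: mixed cell near 0
    expect_lt(abs(A$matrix["a", "g"]), 0.05)
    expect_true(isSymmetric(A$matrix))
  })
})

test_that("association matrices are invariant under subject reordering and mask zero variance", {
  fx <- make_exercise_fixture(fixture_spec(30, 12, seed = 13))
  A <- mixed_association_matrix(fx)
  perm <- stsg:::with_seed(3, sample(30))
  fx2 <- fx
  fx2$static <- fx2$static[perm, ]
  fx2$series <- fx2$series[order(match(fx2$series$subject_id,
                                       fx2$static$subject_id), fx2$series$t), ]
  A2 <- mixed_association_matrix(fx2)
  expect_equal(A$matrix, A2$matrix)

  fx$static$temperature <- 21      # zero-variance feature -> masked row
  A3 <- mixed_association_matrix(fx)
  expect_true(all(is.na(A3$matrix["temperature", ])))
  expect_error(mixed_association_matrix(
    stsg:::keep_subjects(fx, fx$static$subject_id[1])), "insufficient")
})

test_that("histogram-mode PRD equals the independent lambda sweep", {
  for (pq in list(list(p = c(0.5, 0.5), q = c(1, 0)),
                  list(p = c(0.2, 0.3, 0.5), q = c(0.6, 0.1, 0.3)))) {
    curve <- prd_from_histograms(pq$p, pq$q, n_angles = 201)
    oracle <- oracle_prd_sweep(pq$p, pq$q, 201)
    expect_lt(max(abs(curve$pairs$alpha - oracle[, "alpha"])), 1e-12)
    expect_lt(max(abs(curve$pairs$beta - oracle[, "beta"])), 1e-12)
  }
})

test_that("PRD attains (1,1) for identical distributions and (0,0) for disjoint ones", {
  ident <- prd_from_histograms(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(max(pmin(ident$pairs$alpha, ident$pairs$beta)), 1)
  disj <- prd_from_histograms(c(1, 0), c(0, 1))
  expect_equal(max(disj$pairs$alpha), 0)
  expect_equal(max(disj$pairs$beta), 0)
  # all pairs live in the unit square; lambda <-> 1/lambda closure
  stsg:::with_seed(14, {
    p <- runif(5); p <- p / sum(p)
    q <- runif(5); q <- q / sum(q)
    cv <- prd_from_histograms(p, q, n_angles = 101)
    expect_true(all(cv$pairs$alpha >= 0 & cv$pairs$alpha <= 1 + 1e-12))
    expect_true(all(cv$pairs$beta >= 0 & cv$pairs$beta <= 1 + 1e-12))
    flip <- prd_from_histograms(q, p, n_angles = 101)
    expect_equal(sort(round(cv$pairs$alpha, 10)),
                 sort(round(flip$pairs$beta, 10)))
  })
})

test_that("clustered PRD separates identical from disjoint samples", {
  stsg:::with_seed(15, {
    X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("u", "v")))
    same <- prd_curve(tibble::as_tibble(X),
                      tibble::as_tibble(X + rnorm(400, 0, 1e-6)),
                      n_clusters = 10, seed = 2)
    expect_gt(f_gamma(same, 8), 0.98)
    far <- prd_curve(tibble::as_tibble(X),
                     tibble::as_tibble(X + 50), n_clusters = 10, seed = 2)
    expect_lt(f_gamma(far, 8), 0.05)
  })
})

test_that("f_gamma matches hand evaluations and reduces to alpha on the diagonal", {
  expect_equal(f_gamma(tibble::tibble(alpha = 0.5, beta = 0.5), 8), 0.5)
  expect_equal(f_gamma(tibble::tibble(alpha = 1, beta = 0), 8), 0)
  expect_equal(f_gamma(tibble::tibble(alpha = 0.9, beta = 0.6), 8), 0.6031,
               tolerance = 1e-4)
  for (g in c(0.5, 1, 8)) {
    expect_equal(f_gamma(tibble::tibble(alpha = 0.37, beta = 0.37), g), 0.37)
  }
  expect_error(f_gamma(tibble::tibble(alpha = 1, beta = 1), gamma = 0),
               "gamma")
})

test_that("DLA separates shifted samples and echoes the model settings", {
  stsg:::with_seed(16, {
    n <- 150
    Xr <- tibble::as_tibble(matrix(rnorm(n * 6), n, 6,
                                   dimnames = list(NULL, paste0("f", 1:6))))
    Xs <- Xr + 10   # +10 pooled SD in every column
    r <- dla(Xr, Xs, seed = 3)
    expect_gt(r$mean_auroc, 0.95)
    expect_equal(r$result$model, c("rf", "knn", "dt", "svm", "mlp"))
    expect_match(r$result$configuration[r$result$model == "rf"],
                 "100.*Gini")
    expect_match(r$result$configuration[r$result$model == "mlp"],
                 "64.*32.*relu.*adam")
  })
})

test_that("autocorrelation MAE is zero on identity and tracks known processes", {
  fx <- make_exercise_fixture(fixture_spec(20, 24, seed = 17))
  expect_equal(autocorrelation_mae(fx, fx)$mean_mae, 0)

  stsg:::with_seed(18, {
    wn1 <- series_dataset(matrix(rnorm(500 * 128), 500))
    wn2 <- series_dataset(matrix(rnorm(500 * 128), 500))
    expect_lt(autocorrelation_mae(wn1, wn2)$mean_mae, 0.05)

    # AR(1) phi = 0.9 vs white noise: lag-1 ACF difference near phi
    ar <- series_dataset(t(vapply(1:300, function(i) {
      as.numeric(arima.sim(list(ar = 0.9), 128))
    }, numeric(128))))
    wn <- series_dataset(matrix(rnorm(300 * 128), 300))
    mae1 <- autocorrelation_mae(ar, wn, max_lag = 1)$mean_mae
    expect_lt(abs(mae1 - 0.9), 0.1)
  })

  const <- series_dataset(matrix(5, 10, 16))
  expect_warning(autocorrelation_mae(const, const), "constant")
})
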