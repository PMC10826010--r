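base_cfg <- function(approach, jitter = 0.1, n_folds = 3, seed = 2, ...) {
  run_config(approach, "baseline", jitter = jitter, n_folds = n_folds,
             seed = seed, ...)
}

test_that("A1 outputs only series that exist bit-exactly in the real pool", {
  real <- make_exercise_fixture(fixture_spec(25, 12, seed = 31))
  real_keys <- series_keys(real)

  for (cfg in list(base_cfg("A1", jitter = 0.2, seed = 4),
                   run_config("A1", "wgan_gp",
                              backend_config = wgan_gp_config(
                                epochs = 2, batch_size = 10,
                                noise_dim = 8, hidden = c(16, 16), seed = 5),
                              n_folds = 2, seed = 6))) {
    runs <- run_a1(real, cfg)
    expect_length(runs$folds, cfg$n_folds)
    for (fold in runs$folds) {
      expect_equal(stsg:::n_subjects(fold), 25)
      expect_true(all(series_keys(fold) %in% real_keys))
    }
  }
})

test_that("A1 with the copy baseline reproduces real augmented rows at zero distance", {
  real <- make_exercise_fixture(fixture_spec(20, 10, seed = 32))
  runs <- run_a1(real, base_cfg("A1", jitter = 0))
  for (f in seq_along(runs$folds)) {
    expect_equal(runs$couplings[[f]]$total_distance, 0)
    got <- runs$folds[[f]]$static[-1]
    expect_equal(as.data.frame(got), as.data.frame(real$static[-1]))
  }
})

test_that("A2 couples synthetic metadata to synthetic series of real dimensions", {
  real <- make_exercise_fixture(fixture_spec(20, 10, seed = 33))
  runs <- run_a2(real, base_cfg("A2", jitter = 0.2))
  real_keys <- series_keys(real)
  fresh <- FALSE
  for (fold in runs$folds) {
    expect_equal(stsg:::n_subjects(fold), 20)
    expect_equal(stsg:::series_length(fold), 10)
    expect_identical(sort(names(fold$static)), sort(names(real$static)))
    if (!all(series_keys(fold) %in% real_keys)) fresh <- TRUE
  }
  expect_true(fresh)  # jitter > 0: synthesized series leave the real pool

  # copy case: re-pairing of real rows and series at zero distance
  runs0 <- run_a2(real, base_cfg("A2", jitter = 0))
  expect_equal(runs0$couplings[[1]]$total_distance, 0)
  expect_true(all(series_keys(runs0$folds[[1]]) %in% real_keys))
})

test_that("A3 generates jointly without any coupling step", {
  real <- make_exercise_fixture(fixture_spec(20, 12, seed = 34))
  runs <- run_a3(real, base_cfg("A3"))
  expect_equal(runs$provenance$coupling, "none")
  expect_true(all(vapply(runs$couplings, is.null, logical(1))))
  expect_length(unique(runs$config$fold_seeds), 3)

  dg <- run_config("A3", "dgan",
                   backend_config = dgan_config(S = 4, epochs = 1,
                                                batch_size = 10,
                                                noise_dim = 6,
                                                hidden = c(8, 8),
                                                rnn_hidden = 8, seed = 2),
                   n_folds = 2, seed = 3)
  runs2 <- run_a3(real, dg)
  for (fold in runs2$folds) {
    expect_silent(validate_dataset(fold, rectangular = TRUE))
    expect_equal(stsg:::series_length(fold), 12)
  }

  expect_error(run_a2(real, dg), "configuration error")
})

test_that("pseudo-cross-validation aggregates fold metrics as mean and sample SD", {
  real <- make_exercise_fixture(fixture_spec(40, 10, seed = 35))
  cfg <- base_cfg("A2", jitter = 0.15, n_folds = 3,
                  metrics = c("correlation_similarity", "prd_f8",
                              "autocorrelation_mae"))
  rep <- pseudo_cross_validate(real, cfg)
  expect_equal(sort(unique(rep$per_fold$metric)),
               sort(cfg$metrics))
  for (m in cfg$metrics) {
    v <- rep$per_fold$value[rep$per_fold$metric == m]
    expect_equal(rep$aggregate$mean[rep$aggregate$metric == m], mean(v))
    expect_equal(rep$aggregate$std[rep$aggregate$metric == m], sd(v))
  }
})

test_that("identical copy folds give zero dispersion on resemblance metrics", {
  real <- make_exercise_fixture(fixture_spec(40, 10, seed = 36))
  cfg <- base_cfg("A1", jitter = 0, n_folds = 3,
                  metrics = c("correlation_similarity", "prd_f8",
                              "autocorrelation_mae", "dla_auroc"))
  rep <- pseudo_cross_validate(real, cfg)
  expect_equal(rep$aggregate$std, rep(0, 4))
  expect_equal(
    rep$aggregate$mean[rep$aggregate$metric == "correlation_similarity"], 1)
  expect_equal(rep$pooled_correlation_similarity, 1, tolerance = 1e-9)
})

test_that("evaluation reports round-trip through their file format", {
  real <- make_exercise_fixture(fixture_spec(30, 10, seed = 37))
  cfg <- base_cfg("A3", n_folds = 2,
                  metrics = c("correlation_similarity", "prd_f8"))
  rep <- pseudo_cross_validate(real, cfg)
  dir <- withr::local_tempdir()
  write_evaluation_report(rep, dir)
  back <- read_evaluation_report(dir)
  expect_equal(as.data.frame(back$per_fold), as.data.frame(rep$per_fold))
  expect_equal(as.data.frame(back$aggregate), as.data.frame(rep$aggregate))
  expect_equal(back$seeds, rep$seeds)
  expect_equal(back$pooled_correlation_similarity,
               rep$pooled_correlation_similarity)
  expect_equal(back$provenance$approach, rep$provenance$approach)
})

test_that("identical configuration and seeds give identical reports", {
  real <- make_exercise_fixture(fixture_spec(30, 10, seed = 38))
  cfg <- base_cfg("A2", jitter = 0.1, n_folds = 2,
                  metrics = c("correlation_similarity", "mia_precision"))
  r1 <- pseudo_cross_validate(real, cfg)
  r2 <- pseudo_cross_validate(real, cfg)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$aggregate, r2$aggregate)
})

test_that("approach comparison applies the Welch test with the documented conventions", {
  mk_report <- function(values) {
    per <- tidyr::expand_grid(fold = seq_along(values[[1]]),
                              metric = names(values))
    per$value <- unlist(lapply(seq_len(nrow(per)), function(i) {
      values[[per$metric[i]]][per$fold[i]]
    }))
    structure(list(per_fold = per, seeds = seq_along(values[[1]])),
              class = "stsg_report")
  }
  a <- mk_report(list(m1 = rep(0.5, 8), m2 = c(0, 0, 0, 0, 0, 0, 0, 0)))
  b <- mk_report(list(m1 = rep(0.5, 8),
                      m2 = 1 + rnorm(8, 0, 1e-6)))
  cmp <- compare_approaches(a, b)
  # identical zero-variance vectors: p = 1 by convention, not significant
  expect_equal(cmp$p_value[cmp$metric == "m1"], 1)
  expect_false(cmp$significant[cmp$metric == "m1"])
  # 0s vs 1s with tiny jitter: overwhelming evidence
  expect_lt(cmp$p_value[cmp$metric == "m2"], 1e-6)
  expect_true(cmp$significant[cmp$metric == "m2"])

  # significance is the strict p < sl comparison
  set.seed(40)
  x <- rnorm(8); y <- rnorm(8, 1)
  p <- stsg:::welch_p(x, y)
  r1 <- compare_approaches(mk_report(list(m = x)), mk_report(list(m = y)),
                           sl = p + 1e-9)
  r2 <- compare_approaches(mk_report(list(m = x)), mk_report(list(m = y)),
                           sl = p - 1e-9)
  expect_true(r1$significant)
  expect_false(r2$significant)

  expect_error(compare_approaches(a, mk_report(list(zz = rep(1, 8)))),
               "metric sets differ")
})

test_that("report tidiers and glance expose fold values and aggregates", {
  real <- make_exercise_fixture(fixture_spec(25, 10, seed = 39))
  cfg <- base_cfg("A1", n_folds = 2,
                  metrics = c("correlation_similarity", "prd_f8"))
  rep <- pseudo_cross_validate(real, cfg)
  expect_identical(tidy(rep), rep$per_fold)
  gl <- glance(rep)
  expect_equal(gl$approach, "A1")
  expect_equal(gl$mean_correlation_similarity,
               rep$aggregate$mean[rep$aggregate$metric ==
                                    "correlation_similarity"])
})
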