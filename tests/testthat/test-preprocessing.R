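test_that("interpolate_missing fills gaps linearly and excludes heavy subjects", {
  m <- rbind(c(1, NA, 3, 4), c(5, 6, 7, 8))
  d <- series_dataset(m)
  out <- interpolate_missing(d, max_missing_per_subject = 30)
  expect_equal(out$excluded, character(0))
  expect_equal(stsg:::series_matrix(out$dataset, "y")[1, ], c(1, 2, 3, 4),
               ignore_attr = TRUE)

  # a subject with 31 missing samples crosses the 30-point exclusion rule
  m2 <- matrix(rnorm(3 * 40), 3, 40)
  m2[2, 1:31] <- NA
  m2[3, 1:30] <- NA
  d2 <- series_dataset(m2)
  out2 <- interpolate_missing(d2, max_missing_per_subject = 30)
  expect_equal(out2$excluded, "s002")
  expect_equal(stsg:::n_subjects(out2$dataset), 2)
  expect_false(anyNA(out2$dataset$series$y))
})

test_that("boundary gaps use nearest-valid extension, matching the scan oracle", {
  x <- c(NA, 2, NA, NA, 8, NA)
  d <- series_dataset(matrix(x, 1))
  out <- interpolate_missing(d, 30)$dataset
  expect_equal(stsg:::series_matrix(out, "y")[1, ], scan_interpolate(x),
               ignore_attr = TRUE)
  expect_equal(stsg:::series_matrix(out, "y")[1, 1:3], c(2, 2, 4),
               ignore_attr = TRUE)

  # property: random gap patterns equal the oracle; complete data unchanged
  stsg:::with_seed(42, {
    for (i in 1:20) {
      x <- rnorm(12)
      x[sample(12, sample(0:8, 1))] <- NA
      if (all(is.na(x))) next
      got <- stsg:::series_matrix(
        interpolate_missing(series_dataset(matrix(x, 1)), 30)$dataset, "y")[1, ]
      expect_equal(got, scan_interpolate(x), ignore_attr = TRUE)
    }
  })
})

test_that("interpolate_missing errors on a retained subject with a fully missing variable", {
  d <- series_dataset(matrix(c(NA, NA, NA, 1, 2, 3), 2, byrow = TRUE))
  expect_error(interpolate_missing(d, 30), "unrecoverable subject s001")
})

test_that("forward_fill holds the last valid value and backfills the prefix", {
  d <- series_dataset(matrix(c(5, NA, NA, 7), 1))
  expect_equal(stsg:::series_matrix(forward_fill(d), "y")[1, ], c(5, 5, 5, 7),
               ignore_attr = TRUE)
  # fully observed series unchanged
  d2 <- series_dataset(matrix(1:8, 2))
  expect_equal(forward_fill(d2)$series, d2$series)
  # backfill-first-sample rule vs the scan oracle
  x <- c(NA, 3, NA)
  got <- stsg:::series_matrix(forward_fill(series_dataset(matrix(x, 1))),
                              "y")[1, ]
  expect_equal(got, scan_forward_fill(x), ignore_attr = TRUE)
  expect_equal(got, c(3, 3, 3), ignore_attr = TRUE)
})

test_that("forward_fill is idempotent on random missingness patterns", {
  d <- inject_missingness(make_icu_fixture(fixture_spec(6, 24, seed = 3,
                                                        family = "icu")),
                          rate = 0.15, pattern = "block", seed = 4)
  once <- forward_fill(d)
  expect_equal(forward_fill(once)$series, once$series)
  expect_false(anyNA(once$series))
})

test_that("truncate_to_common_length cuts every series to the shortest", {
  sid <- c("a", "b", "c")
  lens <- c(5L, 7L, 9L)
  schema <- variable_schema(c("x", "y"), c("numeric", "numeric"),
                            c("static", "dynamic"), list(NULL, NULL))
  series <- tibble::tibble(
    subject_id = rep(sid, times = lens),
    t = unlist(lapply(lens, function(l) seq_len(l) - 1L)),
    y = rnorm(sum(lens)))
  d <- longitudinal_dataset(schema,
                            tibble::tibble(subject_id = sid, x = 1:3), series)
  out <- truncate_to_common_length(d)
  expect_equal(stsg:::series_length(out), 5)
  expect_equal(out$series$y[out$series$subject_id == "b"],
               series$y[series$subject_id == "b"][1:5])

  # equal lengths unchanged; degenerate min; zero-length error
  d_eq <- series_dataset(matrix(1:8, 2))
  expect_equal(truncate_to_common_length(d_eq)$series, d_eq$series)
  lens2 <- c(1L, 10L)
  series2 <- tibble::tibble(subject_id = rep(c("a", "b"), times = lens2),
                            t = c(0L, seq_len(10L) - 1L), y = rnorm(11))
  d2 <- longitudinal_dataset(schema,
                             tibble::tibble(subject_id = c("a", "b"), x = 1:2),
                             series2)
  expect_equal(stsg:::series_length(truncate_to_common_length(d2)), 1)
})

test_that("categorical encodings are exact inverses and follow schema order", {
  d <- make_icu_fixture(fixture_spec(30, 8, seed = 6, family = "icu"))
  lab <- encode_categoricals(d, "label")
  # codes assigned by schema order: F -> 0, M -> 1
  expect_equal(sort(unique(lab$static$gender)), c(0, 1))
  expect_equal(lab$static$gender, as.numeric(d$static$gender == "M"))
  expect_equal(decode_categoricals(lab)$static, d$static)

  oh <- encode_categoricals(d, "onehot")
  eth_cols <- paste0("ethnicity=", c("white", "black", "hispanic", "asian",
                                     "other"))
  expect_true(all(eth_cols %in% names(oh$static)))
  expect_equal(rowSums(as.matrix(oh$static[eth_cols])), rep(1, 30),
               ignore_attr = TRUE)
  expect_equal(decode_categoricals(oh)$static, d$static)

  bad <- d
  bad$static$ethnicity[1] <- "martian"
  expect_error(encode_categoricals(bad, "label"), "unknown category")
})

test_that("min-max scaling maps to [0,1], handles constants, and inverts exactly", {
  d <- series_dataset(matrix(c(2, 4, 6, 3, 3, 3), 2, byrow = TRUE))
  sc <- scale_minmax(d)
  expect_equal(stsg:::series_matrix(sc$dataset, "y")[1, ], c(0, 0.5, 1),
               ignore_attr = TRUE)
  # constant subject row is part of the same variable; whole-column scaling
  expect_true(all(sc$dataset$series$y >= 0 & sc$dataset$series$y <= 1))
  back <- inverse_scale(sc$dataset, sc$scaling)
  expect_equal(back$series$y, d$series$y, tolerance = 1e-9)

  # a constant variable maps to 0 and inverts to the constant
  dc <- series_dataset(matrix(c(3, 3, 3, 3), 2))
  scc <- scale_minmax(dc)
  expect_equal(scc$dataset$series$y, rep(0, 4))
  expect_equal(inverse_scale(scc$dataset, scc$scaling)$series$y, rep(3, 4))

  # random fixture: inverse o forward is the identity within 1e-9
  fx <- make_exercise_fixture(fixture_spec(10, 12, seed = 2))
  s2 <- scale_minmax(fx)
  b2 <- inverse_scale(s2$dataset, s2$scaling)
  expect_equal(b2$series, fx$series, tolerance = 1e-9)
  expect_equal(b2$static, fx$static, tolerance = 1e-9)
})

test_that("filter_subjects applies predicates and reports exclusions", {
  fx <- make_exercise_fixture(fixture_spec(20, 8, seed = 9))
  corrupted <- c("s0003", "s0007", "s0015")
  fx$static$age[fx$static$subject_id %in% corrupted] <- NA

  out <- filter_subjects(fx, function(st, se) !anyNA(st))
  expect_equal(stsg:::n_subjects(out$dataset), 17)
  expect_equal(sort(out$excluded), corrupted)

  ident <- filter_subjects(fx, function(st, se) TRUE)
  expect_equal(ident$dataset$static, fx$static)
  expect_equal(ident$excluded, character(0))

  # threshold predicate equals a brute-force scan
  thr <- 120
  out2 <- filter_subjects(fx, function(st, se) mean(se$HR) > thr)
  keys <- vapply(split(fx$series$HR, fx$series$subject_id), mean, numeric(1))
  expect_equal(sort(out2$dataset$static$subject_id),
               sort(names(keys)[keys[fx$static$subject_id] > thr]))

  expect_error(filter_subjects(fx, function(st, se) stop("boom")),
               "predicate failed on subject s0001")
})
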