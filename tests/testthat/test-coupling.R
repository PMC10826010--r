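test_that("series summaries are exact and match a brute-force scan", {
  d <- series_dataset(matrix(c(1, 2, 3, 4, 4, 4), 2, byrow = TRUE))
  sm <- summarize_series(d)
  expect_equal(sm$y_max, c(3, 4))
  expect_equal(sm$y_min, c(1, 4))
  expect_equal(sm$y_mean, c(2, 4))

  fx <- make_exercise_fixture(fixture_spec(50, 16, seed = 12))
  sm2 <- summarize_series(fx)
  for (v in c("HR", "VE")) {
    per <- split(fx$series[[v]], fx$series$subject_id)[fx$static$subject_id]
    expect_equal(sm2[[paste0(v, "_max")]],
                 unname(vapply(per, max, numeric(1))))
    expect_equal(sm2[[paste0(v, "_mean")]],
                 unname(vapply(per, mean, numeric(1))))
  }

  dm <- inject_missingness(fx, 0.05, seed = 1)
  expect_error(summarize_series(dm), "missing values")
})

test_that("augment_metadata extends the static table by 3 columns per dynamic variable", {
  fx <- make_exercise_fixture(fixture_spec(8, 10, seed = 3))
  aug <- augment_metadata(fx)
  expect_equal(ncol(aug$static) - 1, 6 + 3 * 5)   # 6 static + 15 summaries
  expect_equal(sum(aug$schema$component == "static"), 21)
  expect_equal(nrow(aug$series), 0)

  # stripping the augmented columns recovers the original static table
  sm <- summarize_series(fx)
  stripped <- aug$static[setdiff(names(aug$static),
                                 setdiff(names(sm), "subject_id"))]
  expect_equal(stripped, fx$static)

  # mismatched subjects are rejected
  sm_bad <- sm[c(2, 1, 3:8), ]
  expect_error(augment_metadata(fx, sm_bad), "alignment error")
})

test_that("hungarian assignment equals the exhaustive optimum on the 3x3 instance", {
  real_pts <- rbind(c(1, 1), c(5, 5), c(9, 9))
  syn_pts <- rbind(c(5.1, 5.0), c(0.9, 1.1), c(9.2, 8.8))
  cost <- as.matrix(stats::dist(rbind(syn_pts, real_pts)))[1:3, 4:6]
  sol <- stsg:::hungarian_assign(cost)
  expect_equal(sol, c(2L, 1L, 3L))  # s1->(5,5), s2->(1,1), s3->(9,9)
  expect_equal(sum(cost[cbind(1:3, sol)]), brute_force_assignment(cost))
})

test_that("hungarian is optimal and greedy never beats it on random instances", {
  stsg:::with_seed(77, {
    for (i in 1:40) {
      n <- sample(2:6, 1)
      m <- n + sample(0:2, 1)
      cost <- matrix(runif(n * m), n, m)
      h <- stsg:::hungarian_assign(cost)
      g <- stsg:::greedy_assign(cost)
      expect_equal(anyDuplicated(h), 0)
      th <- sum(cost[cbind(seq_len(n), h)])
      tg <- sum(cost[cbind(seq_len(n), g)])
      expect_equal(th, brute_force_assignment(cost), tolerance = 1e-12)
      expect_gte(tg, th - 1e-12)
    }
  })
})

test_that("an adversarial instance separates greedy from hungarian", {
  # nearest-first on row 1 forces an expensive leftover for row 2
  cost <- rbind(c(1, 2), c(1.1, 100))
  expect_equal(stsg:::greedy_assign(cost), c(1L, 2L))
  h <- stsg:::hungarian_assign(cost)
  expect_equal(h, c(2L, 1L))
  expect_lt(sum(cost[cbind(1:2, h)]), sum(cost[cbind(1:2, c(1L, 2L))]))
})

test_that("coupling recovers a permutation at zero distance and reorders series", {
  fx <- make_exercise_fixture(fixture_spec(12, 10, seed = 4))
  aug <- augment_metadata(fx)
  perm <- stsg:::with_seed(5, sample(12))
  syn <- aug
  syn$static <- syn$static[perm, ]
  syn$static$subject_id <- sprintf("syn%02d", 1:12)

  res <- couple(syn, fx, method = "hungarian")
  expect_equal(res$coupling$total_distance, 0)
  expect_equal(res$coupling$pairing$pool_id, fx$static$subject_id[perm])
  expect_equal(stsg:::series_matrix(res$dataset, "HR"),
               stsg:::series_matrix(fx, "HR")[perm, ], ignore_attr = TRUE)
  # summaries dropped by default; kept on request
  expect_false("HR_mean" %in% names(res$dataset$static))
  res2 <- couple(syn, fx, keep_summaries = TRUE)
  expect_true("HR_mean" %in% names(res2$dataset$static))
})

test_that("coupling is invariant to pool reordering and enforces capacity", {
  fx <- make_exercise_fixture(fixture_spec(10, 10, seed = 6))
  aug <- augment_metadata(fx)
  syn <- aug
  syn$static <- syn$static[1:6, ]
  syn$static$subject_id <- sprintf("syn%02d", 1:6)

  res_a <- couple(syn, fx)
  perm <- c(4, 1, 7, 10, 2, 3, 9, 5, 8, 6)
  fx_perm <- fx
  fx_perm$static <- fx_perm$static[perm, ]
  fx_perm$series <- fx_perm$series[order(match(fx_perm$series$subject_id,
                                               fx_perm$static$subject_id),
                                         fx_perm$series$t), ]
  res_b <- couple(syn, fx_perm)
  expect_equal(res_a$coupling$total_distance, res_b$coupling$total_distance)
  expect_equal(res_a$coupling$pairing$pool_id, res_b$coupling$pairing$pool_id)

  big <- aug
  big$static <- dplyr::bind_rows(aug$static, aug$static)
  big$static$subject_id <- sprintf("syn%02d", 1:20)
  expect_error(couple(big, fx), "capacity error")
})

test_that("greedy coupling total is never below hungarian on fixtures", {
  fx <- make_exercise_fixture(fixture_spec(15, 10, seed = 8))
  aug <- augment_metadata(fx)
  g <- train_baseline(aug, jitter = 0.3, mode = "metadata_only", seed = 1)
  syn <- generate(g, 12, seed = 2)
  th <- couple(syn, fx, method = "hungarian")$coupling$total_distance
  tg <- couple(syn, fx, method = "greedy")$coupling$total_distance
  expect_gte(tg, th - 1e-12)
})
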