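small_wgan_cfg <- function(epochs = 1, seed = 3) {
  wgan_gp_config(epochs = epochs, batch_size = 10,
                 critic_updates_per_gen = 2, noise_dim = 8,
                 hidden = c(16, 16), seed = seed)
}

test_that("the alignment penalty honours its closed-form contract", {
  R <- diag(2); R[2, 1] <- R[1, 2] <- 0.5
  S <- diag(2); S[2, 1] <- S[1, 2] <- 0.3
  expect_equal(correlation_alignment_penalty(R, S, 10), 2.0)
  expect_equal(correlation_alignment_penalty(R, R, 10), 0)
  expect_equal(correlation_alignment_penalty(R, S, 0), 0)
  expect_error(correlation_alignment_penalty(R, diag(3), 10), "same shape")

  # symmetry, nonnegativity and degree-1 homogeneity in lambda
  stsg:::with_seed(4, {
    for (i in 1:10) {
      A <- stsg:::batch_pearson(matrix(rnorm(40), 10, 4))$R
      B <- stsg:::batch_pearson(matrix(rnorm(40), 10, 4))$R
      l <- runif(1, 0, 20)
      expect_equal(correlation_alignment_penalty(A, B, l),
                   correlation_alignment_penalty(B, A, l))
      expect_gte(correlation_alignment_penalty(A, B, l), 0)
      expect_equal(correlation_alignment_penalty(A, B, 3 * l),
                   3 * correlation_alignment_penalty(A, B, l))
    }
  })
})

test_that("baseline jitter = 0 produces verbatim copies of real records", {
  d <- make_exercise_fixture(fixture_spec(15, 12, seed = 2))
  g <- train_baseline(d, jitter = 0)

  # n = training size: the training data itself, in order
  s <- generate(g, 15, seed = 9)
  expect_equal(s$series[c("t", "HR", "VO2", "VCO2", "RR", "VE")],
               d$series[c("t", "HR", "VO2", "VCO2", "RR", "VE")])

  # any n: every sampled record equals some real record exactly
  s2 <- generate(g, 40, seed = 10)
  real_keys <- series_keys(d)
  expect_true(all(series_keys(s2) %in% real_keys))
})

test_that("baseline jitter preserves per-variable means within Monte-Carlo error", {
  d <- make_exercise_fixture(fixture_spec(50, 12, seed = 5))
  g <- train_baseline(d, jitter = 0.1)
  s <- generate(g, 1000, seed = 11)
  for (v in c("HR", "VE")) {
    se <- sd(d$series[[v]]) * sqrt(1 + 0.1^2) / sqrt(1000)
    expect_lt(abs(mean(s$series[[v]]) - mean(d$series[[v]])),
              3 * se * sqrt(stsg:::series_length(d)))
  }
  for (v in c("age", "weight")) {
    se <- sd(d$static[[v]]) * sqrt(1 + 0.1^2) / sqrt(1000)
    expect_lt(abs(mean(s$static[[v]]) - mean(d$static[[v]])), 4 * se)
  }
})

test_that("WGAN-GP smoke training yields finite traces of the expected length", {
  d <- make_exercise_fixture(fixture_spec(20, 12, seed = 1))
  g <- train_wgan_gp(d, small_wgan_cfg(epochs = 2), mode = "joint")
  expect_equal(nrow(g$trace), 2 * 2)  # epochs x steps (20 %/% 10)
  expect_true(all(is.finite(g$trace$critic_loss)))
  expect_true(all(is.finite(g$trace$gen_loss)))

  s <- generate(g, 6, seed = 4)
  expect_equal(stsg:::n_subjects(s), 6)
  expect_equal(stsg:::series_length(s), 12)
  expect_silent(validate_dataset(s, rectangular = TRUE))
  expect_true(all(s$static$sex %in% c("F", "M")))
  expect_true(all(is.finite(as.matrix(s$series[-(1:2)]))))

  # lambda = 0 zeroes the recorded alignment penalty
  cfg0 <- small_wgan_cfg(); cfg0$lambda_align <- 0
  g0 <- train_wgan_gp(d, cfg0, mode = "joint")
  expect_equal(g0$trace$align_penalty, rep(0, nrow(g0$trace)))
})

test_that("WGAN-GP training is bit-reproducible under a fixed seed", {
  d <- make_exercise_fixture(fixture_spec(15, 10, seed = 8))
  g1 <- train_wgan_gp(d, small_wgan_cfg(), mode = "metadata_only")
  g2 <- train_wgan_gp(d, small_wgan_cfg(), mode = "metadata_only")
  expect_identical(g1$trace, g2$trace)
  expect_identical(generate(g1, 5, seed = 3)$static,
                   generate(g2, 5, seed = 3)$static)
})

test_that("generated values lie in the scaled range before inversion", {
  d <- make_exercise_fixture(fixture_spec(15, 10, seed = 8))
  g <- train_wgan_gp(d, small_wgan_cfg(), mode = "joint")
  Z <- stsg:::with_seed(1, matrix(rnorm(8 * g$config$noise_dim), 8))
  raw <- stsg:::nn_forward(g$G, Z, keep_cache = FALSE)
  expect_true(all(raw >= 0 & raw <= 1))  # sigmoid output layer
})

test_that("DGAN batch generation runs T/S recurrent iterations", {
  d <- make_icu_fixture(fixture_spec(12, 48, seed = 3, family = "icu"))
  cfg <- dgan_config(S = 6, epochs = 1, batch_size = 12, noise_dim = 8,
                     hidden = c(16, 16), rnn_hidden = 12, seed = 5)
  g <- train_dgan(d, cfg)
  expect_equal(g$n_it, 8)  # 48 / 6
  expect_true(all(is.finite(g$trace$aux_critic_loss)))
  expect_true(all(is.finite(g$trace$comb_critic_loss)))

  s <- generate(g, 5, seed = 6)
  expect_equal(stsg:::n_subjects(s), 5)
  expect_equal(stsg:::series_length(s), 48)
  expect_true(all(s$static$ethnicity %in%
                    c("white", "black", "hispanic", "asian", "other")))

  g2 <- train_dgan(d, cfg)
  expect_identical(g$trace, g2$trace)
})

test_that("DGAN pads and trims when S does not divide T", {
  d <- make_exercise_fixture(fixture_spec(10, 14, seed = 2))
  cfg <- dgan_config(S = 4, epochs = 1, batch_size = 10, noise_dim = 6,
                     hidden = c(8, 8), rnn_hidden = 8, seed = 1)
  g <- train_dgan(d, cfg)
  expect_equal(g$n_it, 4)        # ceiling(14 / 4)
  expect_equal(g$T_pad, 16)
  s <- generate(g, 4, seed = 2)
  expect_equal(stsg:::series_length(s), 14)
})

test_that("generator tidiers expose the trace and a one-row summary", {
  d <- make_exercise_fixture(fixture_spec(10, 10, seed = 2))
  g <- train_wgan_gp(d, small_wgan_cfg(), mode = "joint")
  expect_identical(tidy(g), g$trace)
  gl <- glance(g)
  expect_equal(gl$backend, "wgan_gp")
  expect_equal(gl$steps, nrow(g$trace))
})
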