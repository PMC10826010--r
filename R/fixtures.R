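# Seed hygiene: every stochastic entry point evaluates under a local RNG
# state so callers' streams are never disturbed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for a fixture dataset
#'
#' Fixture datasets are fully synthetic cohorts with the statistical
#' structure longitudinal health data exhibits — a metadata component that
#' drives the shape of each subject's series — so that every pipeline stage
#' is exercisable without any external download.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param T Series length in time steps (>= 8).
#' @param seed Integer seed; fixtures are bit-reproducible given the seed.
#' @param family `"exercise"` (graded-exercise-test shape: warmup plateau,
#'   linear ramp, saturation, recovery; 5 cardiorespiratory series driven by
#'   age/sex/weight) or `"icu"` (hourly charting shape: step-like series
#'   driven by a piecewise-constant latent severity state, binary and
#'   five-class categorical metadata).
#' @param missing_rate Fraction of dynamic cells to mask (in `[0, 1)`),
#'   applied via [inject_missingness()]; 0 leaves the data complete.
#' @param metadata_effect Nonnegative multiplier on every static-variable
#'   coefficient in the generating equations; 0 decouples metadata from the
#'   series entirely, larger values strengthen the coupling. Default 1.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_subjects, T, seed, family = c("exercise", "icu"),
                         missing_rate = 0, metadata_effect = 1) {
  family <- match.arg(family)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (T < 8) stop("T must be >= 8", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (metadata_effect < 0) stop("metadata_effect must be >= 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), T = as.integer(T),
                 seed = as.integer(seed), family = family,
                 missing_rate = missing_rate,
                 metadata_effect = metadata_effect),
            class = "fixture_spec")
}

# piecewise effort profile in [0, 1]: warmup 15%, ramp 50%, plateau 20%,
# recovery 15% (ending at 40% effort)
effort_profile <- function(T) {
  t <- seq_len(T)
  w <- max(1, round(0.15 * T)); r <- round(0.5 * T); s <- round(0.2 * T)
  out <- numeric(T)
  ramp_idx <- (w + 1):(w + r)
  out[ramp_idx] <- seq(0, 1, length.out = r)
  sat_idx <- (w + r + 1):min(T, w + r + s)
  out[sat_idx] <- 1
  rec_idx <- setdiff(seq_len(T), c(seq_len(w), ramp_idx, sat_idx))
  if (length(rec_idx)) out[rec_idx] <- seq(1, 0.4, length.out = length(rec_idx) + 1)[-1]
  out
}

#' Generate an exercise-test fixture
#'
#' Emulates a graded treadmill test: heart rate (HR), oxygen uptake (VO2),
#' carbon-dioxide output (VCO2), respiratory rate (RR) and exhaled volume
#' (VE) follow a warmup-plateau / linear ramp / saturation / recovery
#' profile. Each variable's resting and saturation levels are linear
#' functions of age, sex and weight scaled by `metadata_effect`, plus
#' subject-level Gaussian noise; VCO2 and VE are built from VO2 and RR, so
#' dynamic-dynamic and static-summary correlations are nonzero by
#' construction. Generating equations (effort profile m(t) in `[0,1]`,
#' e = `metadata_effect`, z_age/z_wt standardized age and weight, M = 1 for
#' males):
#' \deqn{HR(t) = base + (sat - base) m(t) + \epsilon_t}
#' with `base = 75 + 3 e z_age`, `sat = 185 + e (2 z_age + 1.5 z_wt + 3 M)`;
#' VO2 analogous with weight/sex-driven saturation; `VCO2(t) = 0.92 VO2(t)`,
#' `VE(t) = 0.8 RR(t) + 12 VO2(t)`, each plus noise.
#'
#' @param spec A [fixture_spec()] with `family = "exercise"`.
#' @return A `longitudinal_dataset` with static variables
#'   `age, sex, height, weight, temperature, humidity` and dynamic variables
#'   `HR, VO2, VCO2, RR, VE`.
#' @export
make_exercise_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$family != "exercise") stop("spec family must be 'exercise'",
                                      call. = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_subjects; T_ <- spec$T; e <- spec$metadata_effect
    sid <- sprintf("s%04d", seq_len(n))

    age <- round(stats::rnorm(n, 30, 8), 1)
    sex <- ifelse(stats::runif(n) < 0.85, "M", "F")
    height <- round(stats::rnorm(n, 175, 7), 1)
    weight <- round(stats::rnorm(n, 73, 10), 1)
    temperature <- round(stats::rnorm(n, 22.9, 1.8), 1)
    humidity <- round(stats::rnorm(n, 47, 8), 1)

    z_age <- (age - 30) / 8
    z_wt <- (weight - 73) / 10
    male <- as.numeric(sex == "M")
    m_t <- effort_profile(T_)

    ramped <- function(base, sat, noise_sd) {
      prof <- outer(base, rep(1, T_)) +
        outer(sat - base, rep(1, T_)) * matrix(m_t, n, T_, byrow = TRUE)
      prof + matrix(stats::rnorm(n * T_, 0, noise_sd), n, T_)
    }

    hr_base <- 75 + e * 3 * z_age + stats::rnorm(n, 0, 3)
    hr_sat <- 185 + e * (2 * z_age + 1.5 * z_wt + 3 * male) +
      stats::rnorm(n, 0, 4)
    HR <- ramped(hr_base, hr_sat, 2)

    vo2_base <- 0.5 + e * (0.05 * z_wt + 0.05 * male) + stats::rnorm(n, 0, 0.05)
    vo2_sat <- 3.5 + e * (0.4 * z_wt + 0.5 * male - 0.2 * z_age) +
      stats::rnorm(n, 0, 0.25)
    VO2 <- ramped(vo2_base, vo2_sat, 0.08)

    VCO2 <- 0.92 * VO2 + matrix(stats::rnorm(n * T_, 0, 0.06), n, T_)

    rr_base <- 15 - e * 0.5 * z_age + stats::rnorm(n, 0, 1.5)
    rr_sat <- 45 + e * (1.5 * male + 1 * z_wt) + stats::rnorm(n, 0, 3)
    RR <- ramped(rr_base, rr_sat, 1)

    VE <- 0.8 * RR + 12 * VO2 + matrix(stats::rnorm(n * T_, 0, 1), n, T_)

    schema <- variable_schema(
      name = c("age", "sex", "height", "weight", "temperature", "humidity",
               "HR", "VO2", "VCO2", "RR", "VE"),
      kind = c("numeric", "categorical", rep("numeric", 4), rep("numeric", 5)),
      component = c(rep("static", 6), rep("dynamic", 5)),
      categories = c(list(NULL, c("F", "M")), rep(list(NULL), 9))
    )
    static <- tibble::tibble(subject_id = sid, age = age, sex = sex,
                             height = height, weight = weight,
                             temperature = temperature, humidity = humidity)
    series <- tibble::tibble(
      subject_id = rep(sid, each = T_),
      t = rep(seq_len(T_) - 1L, times = n),
      HR = as.vector(t(HR)), VO2 = as.vector(t(VO2)),
      VCO2 = as.vector(t(VCO2)), RR = as.vector(t(RR)),
      VE = as.vector(t(VE))
    )
    d <- longitudinal_dataset(schema, static, series, time_unit = "step")
    if (spec$missing_rate > 0) {
      d <- inject_missingness(d, spec$missing_rate, "random",
                              seed = spec$seed + 1L)
    }
    d
  })
}

#' Generate an ICU-charting fixture
#'
#' Emulates hourly critical-care charting: a per-subject latent severity
#' state (3 levels, first-order Markov with high persistence) drives
#' step-like series — systolic/diastolic pressure, inspired-oxygen fraction
#' (FiO2), urine output, vasopressor dose and Glasgow Coma Scale (GCS).
#' FiO2 and vasopressor are exactly piecewise constant, which makes the
#' family a natural stress test for forward filling. Static metadata is a
#' binary gender and a five-class ethnicity; `metadata_effect` shifts the
#' severity baseline by gender.
#'
#' @param spec A [fixture_spec()] with `family = "icu"`.
#' @param gender_split Probability of the `"M"` class (mixing weight of the
#'   binary gender sampler).
#' @return A `longitudinal_dataset` with static `gender, ethnicity` and
#'   dynamic `systolic, diastolic, fio2, urine, vasopressor, gcs`.
#' @export
make_icu_fixture <- function(spec, gender_split = 0.5) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$family != "icu") stop("spec family must be 'icu'", call. = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_subjects; T_ <- spec$T; e <- spec$metadata_effect
    sid <- sprintf("p%04d", seq_len(n))
    eth_levels <- c("white", "black", "hispanic", "asian", "other")

    gender <- ifelse(stats::runif(n) < gender_split, "M", "F")
    ethnicity <- sample(eth_levels, n, replace = TRUE,
                        prob = c(0.40, 0.25, 0.15, 0.12, 0.08))
    eth_shift <- c(white = 0, black = 0.2, hispanic = 0.1, asian = -0.1,
                   other = 0)[ethnicity]
    sev_bias <- e * (0.3 * (gender == "M") + eth_shift)

    # latent severity path per subject: states 1 (stable) .. 3 (critical)
    states <- matrix(1L, n, T_)
    for (i in seq_len(n)) {
      p_up <- stats::plogis(-2 + sev_bias[i])
      s <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
      for (tt in seq_len(T_)) {
        states[i, tt] <- s
        if (stats::runif(1) < 0.125) {  # leave state, expected dwell 8 h
          s <- if (stats::runif(1) < 0.5 + p_up) min(3L, s + 1L)
               else max(1L, s - 1L)
        }
      }
    }

    lev <- function(v) matrix(v[states], n, T_)
    noise <- function(sd) matrix(stats::rnorm(n * T_, 0, sd), n, T_)
    subj <- function(sd) matrix(stats::rnorm(n, 0, sd), n, T_)

    systolic <- lev(c(112, 96, 82)) - 4 * e * matrix(gender == "M", n, T_) +
      subj(5) + noise(2)
    diastolic <- 0.62 * systolic + subj(3) + noise(1.5)
    fio2 <- lev(c(0.21, 0.40, 0.60))
    urine <- pmax(0, lev(c(80, 45, 15)) + subj(8) + noise(5))
    vasopressor <- lev(c(0, 0.05, 0.2))
    gcs <- pmin(15, pmax(3, round(lev(c(14, 11, 7)) + subj(0.8) + noise(0.5))))

    schema <- variable_schema(
      name = c("gender", "ethnicity", "systolic", "diastolic", "fio2",
               "urine", "vasopressor", "gcs"),
      kind = c("categorical", "categorical", rep("numeric", 6)),
      component = c("static", "static", rep("dynamic", 6)),
      categories = c(list(c("F", "M"), eth_levels), rep(list(NULL), 6))
    )
    static <- tibble::tibble(subject_id = sid, gender = gender,
                             ethnicity = ethnicity)
    series <- tibble::tibble(
      subject_id = rep(sid, each = T_),
      t = rep(seq_len(T_) - 1L, times = n),
      systolic = as.vector(t(systolic)), diastolic = as.vector(t(diastolic)),
      fio2 = as.vector(t(fio2)), urine = as.vector(t(urine)),
      vasopressor = as.vector(t(vasopressor)), gcs = as.vector(t(gcs))
    )
    d <- longitudinal_dataset(schema, static, series, time_unit = "hour")
    if (spec$missing_rate > 0) {
      d <- inject_missingness(d, spec$missing_rate, "block",
                              seed = spec$seed + 1L)
    }
    d
  })
}

#' Mask dynamic cells to create missingness
#'
#' Masks exactly `round(rate * total dynamic cells)` cells. Under the
#' `"random"` pattern the cells are drawn uniformly; under `"block"` the
#' mask is placed as contiguous runs of up to `block_length` samples within
#' one subject and variable, emulating sensor dropouts.
#'
#' @param d A `longitudinal_dataset`.
#' @param rate Fraction of dynamic cells to mask, in `[0, 1)`.
#' @param pattern `"random"` or `"block"`.
#' @param seed Integer seed.
#' @param block_length Run length for the block pattern.
#' @return The dataset with `NA`s injected.
#' @export
inject_missingness <- function(d, rate, pattern = c("random", "block"),
                               seed = 1L, block_length = 8L) {
  pattern <- match.arg(pattern)
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(d)
  dyn <- unlist(lapply(dataset_dynamic_vars(d), variable_columns,
                       schema = d$schema))
  n_rows <- nrow(d$series)
  total <- n_rows * length(dyn)
  n_mask <- round(rate * total)
  if (n_mask == 0) return(d)

  with_seed(seed, {
    if (pattern == "random") {
      cells <- sample.int(total, n_mask)
      for (k in seq_along(dyn)) {
        rows <- cells[(cells - 1) %/% n_rows == k - 1] - (k - 1) * n_rows
        if (length(rows)) d$series[[dyn[k]]][rows] <- NA
      }
    } else {
      per <- split(seq_len(n_rows), d$series$subject_id)
      budget <- n_mask
      guard <- 0
      while (budget > 0 && guard < 100 * n_mask) {
        guard <- guard + 1
        sid <- sample(names(per), 1)
        v <- sample(dyn, 1)
        rows <- per[[sid]]
        len <- min(block_length, budget, length(rows))
        start <- sample.int(length(rows) - len + 1L, 1)
        idx <- rows[start:(start + len - 1L)]
        fresh <- idx[!is.na(d$series[[v]][idx])]
        d$series[[v]][fresh] <- NA
        budget <- budget - length(fresh)
      }
    }
    d
  })
}
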