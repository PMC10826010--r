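#' Run configuration for the generation strategies
#'
#' Bundles everything one experiment needs: the strategy (A1: synthetic
#' metadata coupled to real series; A2: metadata and series synthesized
#' separately, then coupled; A3: joint synthesis), the backend and its
#' config, the pseudo-cross-validation fold count and seeds, and the
#' evaluation settings.
#'
#' By default one generator is trained and sampled once per fold with
#' distinct seeds (cheap, isolates sampling variability);
#' `retrain_per_fold = TRUE` retrains the backend per fold instead.
#'
#' @param approach `"A1"`, `"A2"` or `"A3"`.
#' @param backend `"baseline"`, `"wgan_gp"` or `"dgan"`.
#' @param backend_config A [wgan_gp_config()] / [dgan_config()]; `NULL`
#'   uses the backend defaults. Ignored by the baseline.
#' @param jitter Baseline-backend noise scale (see [train_baseline()]).
#' @param n_folds Number of pseudo-cross-validation folds (>= 2 for
#'   aggregate statistics; 8 is the conventional choice).
#' @param seed Master seed; per-fold sampling seeds are derived from it and
#'   are pairwise distinct.
#' @param retrain_per_fold Retrain the backend for every fold.
#' @param couple_method Assignment method for A1/A2, see [couple()].
#' @param metrics Metrics evaluated per fold by [pseudo_cross_validate()].
#' @param target Numeric dynamic variable for the TSTR task (default:
#'   first dynamic variable).
#' @param holdout_fraction Fraction of subjects held out from generator
#'   training and reserved as the real test/holdout set for the utility
#'   and privacy metrics. Must leave enough holdout subjects to draw the
#'   non-member sample at the largest MIA fraction, i.e.
#'   `holdout_fraction >= max(mia_fractions) * (1 - holdout_fraction)`;
#'   the default 0.35 satisfies this for the standard 0.1-0.5 grid.
#' @param mia_fractions,mia_threshold MIA settings, see [mia_curve()].
#' @param series_points Flattening resolution for record-based metrics.
#' @return A `run_config` list.
#' @export
run_config <- function(approach = c("A1", "A2", "A3"),
                       backend = c("baseline", "wgan_gp", "dgan"),
                       backend_config = NULL, jitter = 0.05,
                       n_folds = 8, seed = 1L, retrain_per_fold = FALSE,
                       couple_method = c("hungarian", "greedy"),
                       metrics = c("correlation_similarity", "prd_f8",
                                   "dla_auroc", "autocorrelation_mae",
                                   "tstr_similarity", "mia_precision"),
                       target = NULL, holdout_fraction = 0.35,
                       mia_fractions = seq(0.1, 0.5, by = 0.1),
                       mia_threshold = 0.2, series_points = 8) {
  approach <- match.arg(approach)
  backend <- match.arg(backend)
  couple_method <- match.arg(couple_method)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  cfg <- list(approach = approach, backend = backend,
              backend_config = backend_config, jitter = jitter,
              n_folds = as.integer(n_folds), seed = as.integer(seed),
              retrain_per_fold = retrain_per_fold,
              couple_method = couple_method, metrics = metrics,
              target = target, holdout_fraction = holdout_fraction,
              mia_fractions = mia_fractions, mia_threshold = mia_threshold,
              series_points = series_points)
  cfg$fold_seeds <- cfg$seed + 101L * seq_len(cfg$n_folds)
  structure(cfg, class = "run_config")
}

train_backend <- function(d, config, mode, seed_shift = 0L) {
  switch(config$backend,
    baseline = train_baseline(d, jitter = config$jitter, mode = mode,
                              seed = config$seed),
    wgan_gp = {
      bc <- config$backend_config %||% wgan_gp_config()
      bc$seed <- bc$seed + seed_shift
      train_wgan_gp(d, bc, mode = mode)
    },
    dgan = {
      bc <- config$backend_config %||% dgan_config()
      bc$seed <- bc$seed + seed_shift
      if (mode == "series_only") {
        stop("configuration error: the dgan backend generates series only ",
             "conditionally on metadata (joint mode)", call. = FALSE)
      }
      train_dgan(d, bc, mode = if (mode == "joint") "joint"
                               else "metadata_only")
    })
}

new_runs <- function(approach, config, folds, couplings) {
  structure(list(approach = approach, config = config, folds = folds,
                 couplings = couplings,
                 provenance = list(
                   approach = approach, backend = config$backend,
                   coupling = if (approach == "A3") "none"
                              else config$couple_method,
                   seeds = config$fold_seeds)),
            class = "stsg_runs")
}

#' @export
print.stsg_runs <- function(x, ...) {
  cat(sprintf("<stsg_runs> %s via %s backend, %d folds (coupling: %s)\n",
              x$approach, x$config$backend, length(x$folds),
              x$provenance$coupling))
  invisible(x)
}

#' Run generation strategy A1, A2 or A3
#'
#' `run_a1()`: the series are assumed non-disclosive and stay real. Real
#' series are summarized ([summarize_series()]) and the summaries appended
#' to the metadata ([augment_metadata()]); a metadata-only generator is
#' trained on the augmented table; each fold samples synthetic augmented
#' metadata and couples it to the real series pool ([couple()]). Every
#' output series is bit-identical to some real series.
#'
#' `run_a2()`: a metadata-only generator is trained on the augmented
#' metadata and, separately, a series-only generator on the series; each
#' fold samples both, summarizes the synthetic series and couples the
#' synthetic metadata to the synthetic series pool.
#'
#' `run_a3()`: one joint model generates aligned metadata and series in a
#' single step; no coupling is involved.
#'
#' @param real A complete, rectangular `longitudinal_dataset`.
#' @param config A [run_config()] (its `approach` field is overridden by
#'   the function called).
#' @return An `stsg_runs`: per-fold synthetic `longitudinal_dataset`s of
#'   the real dataset's dimensions, plus coupling results where relevant.
#' @export
run_a1 <- function(real, config) {
  validate_dataset(real, rectangular = TRUE)
  aug <- augment_metadata(real)
  n <- n_subjects(real)
  gen <- if (!config$retrain_per_fold) {
    train_backend(aug, config, "metadata_only")
  }
  folds <- vector("list", config$n_folds)
  couplings <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    g <- if (config$retrain_per_fold) {
      train_backend(aug, config, "metadata_only", seed_shift = f)
    } else gen
    syn_meta <- generate(g, n, seed = config$fold_seeds[f])
    res <- couple(syn_meta, real, method = config$couple_method)
    folds[[f]] <- res$dataset
    couplings[[f]] <- res$coupling
  }
  new_runs("A1", config, folds, couplings)
}

#' @rdname run_a1
#' @export
run_a2 <- function(real, config) {
  validate_dataset(real, rectangular = TRUE)
  aug <- augment_metadata(real)
  n <- n_subjects(real)
  gen_meta <- if (!config$retrain_per_fold) {
    train_backend(aug, config, "metadata_only")
  }
  gen_series <- if (!config$retrain_per_fold) {
    train_backend(real, config, "series_only")
  }
  folds <- vector("list", config$n_folds)
  couplings <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    gm <- if (config$retrain_per_fold) {
      train_backend(aug, config, "metadata_only", seed_shift = f)
    } else gen_meta
    gs <- if (config$retrain_per_fold) {
      train_backend(real, config, "series_only", seed_shift = f)
    } else gen_series
    syn_meta <- generate(gm, n, seed = config$fold_seeds[f])
    syn_series <- generate(gs, n, seed = config$fold_seeds[f] + 1L)
    res <- couple(syn_meta, syn_series, method = config$couple_method)
    folds[[f]] <- res$dataset
    couplings[[f]] <- res$coupling
  }
  new_runs("A2", config, folds, couplings)
}

#' @rdname run_a1
#' @export
run_a3 <- function(real, config) {
  validate_dataset(real, rectangular = TRUE)
  n <- n_subjects(real)
  gen <- if (!config$retrain_per_fold) train_backend(real, config, "joint")
  folds <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    g <- if (config$retrain_per_fold) {
      train_backend(real, config, "joint", seed_shift = f)
    } else gen
    folds[[f]] <- generate(g, n, seed = config$fold_seeds[f])
  }
  new_runs("A3", config, folds, vector("list", config$n_folds))
}

run_approach <- function(real, config) {
  switch(config$approach,
         A1 = run_a1(real, config),
         A2 = run_a2(real, config),
         A3 = run_a3(real, config))
}

#' Pseudo-cross-validated evaluation of a generation strategy
#'
#' Splits the real cohort into a generator-training part and a holdout
#' part, runs the configured strategy, and evaluates every enabled metric
#' on each of the `n_folds` equally dimensioned synthetic datasets:
#' resemblance (correlation similarity, PRD max F8, DLA mean AUROC,
#' autocorrelation MAE) against the training part, utility (TSTR
#' similarity) and privacy (mean MIA precision over the adversary-knowledge
#' grid) using the holdout as the real test / non-member population.
#' Fold values are aggregated as mean and sample SD. A pooled correlation
#' similarity — computed from the element-wise mean of the per-fold
#' association matrices — is reported alongside the per-fold aggregate.
#'
#' @param real A complete, rectangular `longitudinal_dataset`.
#' @param config A [run_config()].
#' @return An `stsg_report` with `per_fold`, `aggregate`, the pooled
#'   correlation similarity, seeds and provenance.
#' @export
pseudo_cross_validate <- function(real, config) {
  validate_dataset(real, rectangular = TRUE)
  n <- n_subjects(real)
  n_hold <- max(2L, round(config$holdout_fraction * n))
  hold_idx <- with_seed(config$seed,
                        sort(sample.int(n, n_hold)))
  sid <- real$static$subject_id
  d_train <- keep_subjects(real, sid[-hold_idx])
  d_hold <- keep_subjects(real, sid[hold_idx])

  runs <- run_approach(d_train, config)
  target <- config$target %||% dataset_dynamic_vars(real)[1]

  assoc_train <- mixed_association_matrix(d_train)
  assoc_folds <- list()
  rows <- list()
  for (f in seq_along(runs$folds)) {
    fold <- runs$folds[[f]]
    vals <- c()
    if ("correlation_similarity" %in% config$metrics) {
      assoc_folds[[f]] <- mixed_association_matrix(fold)
      vals["correlation_similarity"] <-
        correlation_similarity(assoc_train, assoc_folds[[f]])
    }
    if ("prd_f8" %in% config$metrics) {
      vals["prd_f8"] <- f_gamma(prd_curve(d_train, fold,
                                          seed = config$seed), 8)
    }
    if ("dla_auroc" %in% config$metrics) {
      vals["dla_auroc"] <- dla(d_train, fold, seed = config$seed)$mean_auroc
    }
    if ("autocorrelation_mae" %in% config$metrics) {
      vals["autocorrelation_mae"] <-
        autocorrelation_mae(d_train, fold)$mean_mae
    }
    if ("tstr_similarity" %in% config$metrics) {
      vals["tstr_similarity"] <- tstr_trtr(
        d_train, d_hold, fold, target = target, seed = config$seed,
        series_points = config$series_points)$similarity
    }
    if ("mia_precision" %in% config$metrics) {
      mc <- mia_curve(d_train, d_hold, fold,
                      fractions = config$mia_fractions,
                      threshold = config$mia_threshold, seed = config$seed,
                      series_points = config$series_points)
      vals["mia_precision"] <- mean(mc$result$precision)
    }
    rows[[f]] <- tibble::tibble(fold = f, metric = names(vals),
                                value = unname(vals))
  }
  per_fold <- dplyr::bind_rows(rows)
  aggregate <- per_fold |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     std = stats::sd(.data$value), .groups = "drop")

  pooled_sim <- if (length(assoc_folds)) {
    mats <- lapply(assoc_folds, `[[`, "matrix")
    meanmat <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m))) /
      Reduce(`+`, lapply(mats, function(m) !is.na(m) * 1))
    correlation_similarity(assoc_train$matrix, meanmat)
  } else NA_real_

  structure(list(
    per_fold = per_fold, aggregate = aggregate,
    pooled_correlation_similarity = pooled_sim,
    seeds = config$fold_seeds,
    provenance = c(runs$provenance,
                   list(config_hash = rlang::hash(unclass(config)),
                        n_train = n_subjects(d_train),
                        n_holdout = n_subjects(d_hold), target = target))),
    class = "stsg_report")
}

#' @export
print.stsg_report <- function(x, ...) {
  cat(sprintf("<stsg_report> %s via %s, %d folds\n",
              x$provenance$approach, x$provenance$backend,
              length(x$seeds)))
  print(x$aggregate)
  if (!is.na(x$pooled_correlation_similarity)) {
    cat(sprintf("pooled correlation similarity: %.4f\n",
                x$pooled_correlation_similarity))
  }
  invisible(x)
}

# Welch two-sample t-test with the documented degenerate-case convention:
# two identical zero-variance fold vectors give p = 1 (no evidence of a
# difference), distinct zero-variance vectors give p = 0.
welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b)$p.value
}

#' Pairwise comparison of two evaluation reports
#'
#' Welch two-sample t-tests per metric across pseudo-cross-validation
#' folds; a p-value below the significance level means the metric differs
#' significantly between the two strategies.
#'
#' @param report_a,report_b `stsg_report`s sharing metric set and fold
#'   count.
#' @param sl Significance level (default 0.05).
#' @return A tibble `(metric, p_value, significant)`.
#' @export
compare_approaches <- function(report_a, report_b, sl = 0.05) {
  ma <- sort(unique(report_a$per_fold$metric))
  mb <- sort(unique(report_b$per_fold$metric))
  if (!identical(ma, mb)) {
    stop("metric sets differ between reports", call. = FALSE)
  }
  if (length(report_a$seeds) < 2 || length(report_b$seeds) < 2) {
    stop("need >= 2 folds per report", call. = FALSE)
  }
  rows <- purrr::map(ma, function(m) {
    a <- report_a$per_fold$value[report_a$per_fold$metric == m]
    b <- report_b$per_fold$value[report_b$per_fold$metric == m]
    p <- welch_p(a, b)
    tibble::tibble(metric = m, p_value = p, significant = p < sl)
  })
  dplyr::bind_rows(rows)
}

#' Write / read an evaluation report
#'
#' The on-disk report is a directory with `per_fold.csv`,
#' `aggregate.csv` and `meta.json` (seeds, provenance, pooled correlation
#' similarity); reading it back reproduces the report's tables exactly.
#'
#' @param report An `stsg_report`.
#' @param dir Report directory (created if needed).
#' @return `write_evaluation_report()` returns `dir` invisibly;
#'   `read_evaluation_report()` returns an `stsg_report`.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$per_fold, file.path(dir, "per_fold.csv"),
                   progress = FALSE)
  readr::write_csv(report$aggregate, file.path(dir, "aggregate.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(seeds = report$seeds,
         pooled_correlation_similarity = report$pooled_correlation_similarity,
         provenance = report$provenance),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname write_evaluation_report
#' @export
read_evaluation_report <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  per_fold <- readr::read_csv(file.path(dir, "per_fold.csv"),
                              show_col_types = FALSE, progress = FALSE)
  per_fold$fold <- as.integer(per_fold$fold)
  structure(list(
    per_fold = per_fold,
    aggregate = readr::read_csv(file.path(dir, "aggregate.csv"),
                                show_col_types = FALSE, progress = FALSE),
    pooled_correlation_similarity =
      meta$pooled_correlation_similarity %||% NA_real_,
    seeds = meta$seeds, provenance = meta$provenance),
    class = "stsg_report")
}
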