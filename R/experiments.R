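#' Prediction accuracy metrics
#'
#' Pearson correlation and mean squared error between predicted and measured
#' phenotypes — the test-set accuracies R_SL (base predictor) and R_SSL
#' (augmented predictor) of the validation design. If either vector is
#' constant the correlation is undefined: it is returned as `NA` with a
#' warning, while the MSE is still reported.
#'
#' @param predictions Tibble `animal_id, prediction` (from
#'   [predict_phenotypes()]) or a numeric vector.
#' @param actual Tibble with `animal_id` and a numeric phenotype column, or a
#'   numeric vector. When both carry animal IDs they are aligned by ID.
#' @return A one-row tibble `correlation, mse, n`.
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(2, 4, 6)) # correlation 1, mse 14/3
#' @export
evaluate_predictions <- function(predictions, actual) {
  if (is.data.frame(predictions)) {
    ids <- predictions$animal_id
    pred <- setNames(predictions$prediction, ids)
    act <- align_phenotypes(actual, ids, arg = "actual")
    pred <- unname(pred)
  } else {
    pred <- as.numeric(predictions)
    act <- align_phenotypes(actual, names(predictions) %||% seq_along(pred),
                            arg = "actual")
    if (length(act) != length(pred)) {
      stop_selfgp("Prediction and phenotype lengths differ.", "selfgp_error_metrics")
    }
  }
  n <- length(pred)
  if (n < 3) {
    stop_selfgp("At least 3 test animals are required to evaluate accuracy.",
                "selfgp_error_metrics")
  }
  mse <- mean((pred - act)^2)
  if (sd(pred) == 0 || sd(act) == 0) {
    warn("Correlation undefined: constant predictions or phenotypes; returning NA.")
    r <- NA_real_
  } else {
    r <- cor(pred, act)
  }
  tibble(correlation = r, mse = mse, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiment configuration
#'
#' Settings for the validation designs: supervised learning curves over a
#' grid of labeled training-set sizes, labeled/unlabeled ratio sweeps, and
#' the plateau search for the optimal number of self-trained animals. The
#' defaults are the study design this package models: learning-curve sizes
#' 20 to 540 in steps of 20, labeled sizes \{300, 400, 500\} crossed with
#' unlabeled sizes \{200, 400, 600, 800\}, 100 replicates per setting,
#' plateau increments of 200 animals and a per-replicate stopping tolerance
#' of 0.01% on the correlation-as-percentage scale (0.0001 absolute).
#'
#' @param labeled_sizes Integer vector of labeled training-set sizes.
#' @param unlabeled_sizes Integer vector of unlabeled set sizes for
#'   [ratio_sweep()].
#' @param n_replicates Replicates per setting.
#' @param plateau_increment Unlabeled animals added per plateau step.
#' @param plateau_tolerance Per-replicate stopping tolerance on the absolute
#'   correlation improvement; `0` disables early stopping (the search runs to
#'   pool exhaustion).
#' @param ci_method `"t"` (default) or `"normal"` for 95% confidence
#'   intervals.
#' @param spec A [predictor_spec()].
#' @param seed Master seed; every replicate of every setting draws its own
#'   seed via [stream_seed()], so any cell is independently reproducible.
#' @return A validated `experiment_config` list.
#' @export
experiment_config <- function(labeled_sizes = seq(20, 540, by = 20),
                              unlabeled_sizes = c(200, 400, 600, 800),
                              n_replicates = 100,
                              plateau_increment = 200,
                              plateau_tolerance = 1e-4,
                              ci_method = c("t", "normal"),
                              spec = predictor_spec(),
                              seed = 1) {
  ci_method <- match.arg(ci_method)
  if (any(labeled_sizes < 1) || any(unlabeled_sizes < 0)) {
    stop_selfgp("Sizes must be positive (unlabeled sizes may be 0).", "selfgp_error_config")
  }
  if (n_replicates < 1 || plateau_increment < 1 || plateau_tolerance < 0) {
    stop_selfgp("n_replicates and plateau_increment must be positive; plateau_tolerance non-negative.",
                "selfgp_error_config")
  }
  structure(list(labeled_sizes = as.integer(labeled_sizes),
                 unlabeled_sizes = as.integer(unlabeled_sizes),
                 n_replicates = as.integer(n_replicates),
                 plateau_increment = as.integer(plateau_increment),
                 plateau_tolerance = plateau_tolerance,
                 ci_method = ci_method, spec = spec, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Summarise per-replicate metrics with 95% confidence intervals
#'
#' Mean and 95% confidence interval over replicate values, grouped by any
#' setting columns present. The half-width is
#' `t(0.975, n - 1) * sd / sqrt(n)` (or the normal quantile when
#' `ci_method = "normal"`); with a single replicate the interval is `NA`.
#'
#' @param replicates Tibble of per-replicate values.
#' @param value Name of the value column to summarise.
#' @param by Character vector of grouping (setting) columns.
#' @param ci_method `"t"` or `"normal"`.
#' @return A tibble with `mean`, `ci_lower`, `ci_upper`, `n_replicates` per
#'   group.
#' @export
summarize_replicates <- function(replicates, value = "correlation",
                                 by = character(0), ci_method = c("t", "normal")) {
  ci_method <- match.arg(ci_method)
  replicates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      ci_half = ci_half_width(.data[[value]], ci_method),
      n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(ci_lower = .data$mean - .data$ci_half,
                  ci_upper = .data$mean + .data$ci_half) |>
    dplyr::select(dplyr::all_of(by), "mean", "ci_lower", "ci_upper", "n_replicates")
}

ci_half_width <- function(x, ci_method = "t", level = 0.95) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  q <- if (ci_method == "t") qt(1 - (1 - level) / 2, n - 1) else
    stats::qnorm(1 - (1 - level) / 2)
  q * sd(x) / sqrt(n)
}

sample_ids <- function(ids, n) ids[sample.int(length(ids), n)]

#' Supervised learning curve
#'
#' For each labeled training-set size `n`, draws `n_replicates` random
#' without-replacement samples of `n` animals from the training pool, trains
#' the supervised base predictor on each, and evaluates it on the fixed test
#' set. Replicate seeds come from independent [stream_seed()] streams, so
#' runs are reproducible cell by cell.
#'
#' @param pool A [prediction_set()]: the labeled training pool.
#' @param test A [prediction_set()]: the fixed test set.
#' @param config An [experiment_config()].
#' @return A `learning_curve` object: list of tibbles `replicates`
#'   (`n_labeled, replicate, correlation, mse`) and `summary` (per size and
#'   metric: mean and 95% CI).
#' @export
learning_curve <- function(pool, test, config = experiment_config()) {
  stopifnot(inherits(pool, "prediction_set"), inherits(test, "prediction_set"))
  pool_ids <- animal_ids(pool$genotypes)
  sizes <- config$labeled_sizes
  if (max(sizes) > length(pool_ids)) {
    stop_selfgp(sprintf("Largest labeled size (%d) exceeds the pool (%d animals).",
                        max(sizes), length(pool_ids)), "selfgp_error_experiment")
  }
  reps <- purrr::map_dfr(sizes, function(n) {
    purrr::map_dfr(seq_len(config$n_replicates), function(r) {
      s <- stream_seed(config$seed, sprintf("learning_curve:n=%d:rep=%d", n, r))
      ids <- withr::with_seed(s, sample_ids(pool_ids, n))
      f <- train_base(gm_subset(pool$genotypes, animals = ids),
                      pool$phenotypes[match(ids, pool$phenotypes$animal_id), ],
                      config$spec)
      m <- evaluate_predictions(predict_phenotypes(f, test$genotypes),
                                test$phenotypes)
      tibble(n_labeled = n, replicate = r,
             correlation = m$correlation, mse = m$mse)
    })
  })
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_replicates(reps, "correlation", "n_labeled",
                                       config$ci_method), metric = "correlation"),
    dplyr::mutate(summarize_replicates(reps, "mse", "n_labeled",
                                       config$ci_method), metric = "mse"))
  structure(list(replicates = reps, summary = summary, config = config),
            class = "learning_curve")
}

#' Labeled/unlabeled ratio sweep
#'
#' For every combination of labeled size and unlabeled size, runs
#' `n_replicates` paired self-training experiments: sample both sets, run
#' [self_train()], evaluate the base predictor `f` and the augmented
#' predictor `f*` on the identical fixed test set, and record the paired
#' per-replicate differences in correlation and MSE. Cells whose sizes
#' exceed the pools are skipped with a warning, never silently.
#'
#' @param pool_labeled [prediction_set()] of phenotyped animals.
#' @param pool_unlabeled [genotype_matrix()] (or [prediction_set()], whose
#'   phenotypes are ignored) of genotype-only animals.
#' @param test Fixed test [prediction_set()].
#' @param config An [experiment_config()].
#' @return A `ratio_sweep` object: `replicates` tibble (`n_labeled,
#'   n_unlabeled, replicate, r_sl, r_ssl, mse_sl, mse_ssl, correlation_gain,
#'   mse_change`) and `summary` (per cell: mean gain and 95% CI); the gain is
#'   `R_SSL - R_SL`, so positive values favor self-training.
#' @export
ratio_sweep <- function(pool_labeled, pool_unlabeled, test,
                        config = experiment_config()) {
  stopifnot(inherits(pool_labeled, "prediction_set"),
            inherits(test, "prediction_set"))
  G_unlab <- if (inherits(pool_unlabeled, "prediction_set"))
    pool_unlabeled$genotypes else pool_unlabeled
  stopifnot(is_geno_matrix(G_unlab))
  lab_ids <- animal_ids(pool_labeled$genotypes)
  unlab_ids <- animal_ids(G_unlab)
  grid <- tidyr::expand_grid(n_labeled = config$labeled_sizes,
                             n_unlabeled = config$unlabeled_sizes)
  feasible <- grid$n_labeled <= length(lab_ids) &
    grid$n_unlabeled <= length(unlab_ids)
  if (any(!feasible)) {
    warn(sprintf("Skipping %d infeasible cell(s) whose sizes exceed the pools.",
                 sum(!feasible)))
    grid <- grid[feasible, ]
  }
  reps <- purrr::pmap_dfr(grid, function(n_labeled, n_unlabeled) {
    purrr::map_dfr(seq_len(config$n_replicates), function(r) {
      s <- stream_seed(config$seed, sprintf("ratio_sweep:nl=%d:nu=%d:rep=%d",
                                            n_labeled, n_unlabeled, r))
      draws <- withr::with_seed(s, list(
        lab = sample_ids(lab_ids, n_labeled),
        unlab = sample_ids(unlab_ids, n_unlabeled)))
      st <- self_train(
        gm_subset(pool_labeled$genotypes, animals = draws$lab),
        pool_labeled$phenotypes[match(draws$lab, pool_labeled$phenotypes$animal_id), ],
        gm_subset(G_unlab, animals = draws$unlab),
        config$spec)
      m_sl <- evaluate_predictions(predict_phenotypes(st$base, test$genotypes),
                                   test$phenotypes)
      m_ssl <- evaluate_predictions(predict_phenotypes(st$augmented, test$genotypes),
                                    test$phenotypes)
      tibble(n_labeled = n_labeled, n_unlabeled = n_unlabeled, replicate = r,
             r_sl = m_sl$correlation, r_ssl = m_ssl$correlation,
             mse_sl = m_sl$mse, mse_ssl = m_ssl$mse,
             correlation_gain = m_ssl$correlation - m_sl$correlation,
             mse_change = m_ssl$mse - m_sl$mse)
    })
  })
  by <- c("n_labeled", "n_unlabeled")
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_replicates(reps, "correlation_gain", by,
                                       config$ci_method), metric = "correlation_gain"),
    dplyr::mutate(summarize_replicates(reps, "mse_change", by,
                                       config$ci_method), metric = "mse_change"),
    dplyr::mutate(summarize_replicates(reps, "r_sl", by, config$ci_method),
                  metric = "r_sl"),
    dplyr::mutate(summarize_replicates(reps, "r_ssl", by, config$ci_method),
                  metric = "r_ssl"))
  structure(list(replicates = reps, summary = summary, config = config),
            class = "ratio_sweep")
}

# one plateau replicate: base predictor + nested unlabeled growth until the
# per-step correlation improvement drops below tol (or the pool runs out).
# Exposed internally so the acceptance replay oracle can re-run it.
plateau_one_replicate <- function(pool_labeled, G_unlab, test, n_labeled,
                                  increment, tol, spec, seed) {
  lab_ids <- animal_ids(pool_labeled$genotypes)
  unlab_ids <- animal_ids(G_unlab)
  draws <- withr::with_seed(seed, list(
    lab = sample_ids(lab_ids, n_labeled),
    perm = sample(unlab_ids)))
  G1 <- gm_subset(pool_labeled$genotypes, animals = draws$lab)
  P1 <- pool_labeled$phenotypes[match(draws$lab, pool_labeled$phenotypes$animal_id), ]
  f <- train_base(G1, P1, spec)
  p1 <- align_phenotypes(P1, animal_ids(G1), arg = "P1")
  base_corr <- evaluate_predictions(predict_phenotypes(f, test$genotypes),
                                    test$phenotypes)$correlation
  # predictions for the full permuted pool once; nested subsets reuse them
  p_all <- predict_phenotypes(f, gm_subset(G_unlab, animals = draws$perm))
  prev <- base_corr
  k <- 0L
  exhausted <- FALSE
  corr_k <- base_corr
  repeat {
    nu <- (k + 1L) * increment
    if (nu > length(unlab_ids)) {
      exhausted <- TRUE
      break
    }
    ids_u <- draws$perm[seq_len(nu)]
    G_comb <- gm_rbind(G1, gm_subset(G_unlab, animals = ids_u))
    y_comb <- c(setNames(p1, animal_ids(G1)),
                setNames(p_all$prediction[seq_len(nu)], ids_u))
    f_star <- train_base(G_comb, y_comb, spec)
    corr_k <- evaluate_predictions(predict_phenotypes(f_star, test$genotypes),
                                   test$phenotypes)$correlation
    k <- k + 1L
    delta <- corr_k - prev
    prev <- corr_k
    if (tol > 0 && delta < tol) break
  }
  tibble(n_labeled = n_labeled,
         n_unlabeled_stop = k * increment,
         ratio = k * increment / n_labeled,
         baseline_correlation = base_corr,
         final_correlation = corr_k,
         improvement = corr_k - base_corr,
         steps_evaluated = k, exhausted = exhausted)
}

#' Plateau search for the optimal number of self-trained animals
#'
#' For each labeled training-set size and each replicate: sample the labeled
#' set, then grow the self-trained set in increments of
#' `plateau_increment` animals (nested draws: each step adds new animals to
#' the previous set) and stop at the first step whose correlation improvement
#' over the previous step falls below `plateau_tolerance` — or when the
#' unlabeled pool is exhausted, which is flagged. Reported per replicate are
#' the stopping ratio (self-trained / measured animals, the optimal-ratio
#' quantity) and the total correlation improvement over the supervised
#' baseline (the maximum-improvement quantity). No step beyond the stopping
#' point is ever evaluated.
#'
#' @inheritParams ratio_sweep
#' @return A `plateau_search` object: `replicates` tibble (`n_labeled,
#'   replicate, n_unlabeled_stop, ratio, baseline_correlation,
#'   final_correlation, improvement, steps_evaluated, exhausted`) and
#'   `summary` with means and 95% CIs of ratio and improvement per labeled
#'   size.
#' @export
plateau_search <- function(pool_labeled, pool_unlabeled, test,
                           config = experiment_config()) {
  stopifnot(inherits(pool_labeled, "prediction_set"),
            inherits(test, "prediction_set"))
  G_unlab <- if (inherits(pool_unlabeled, "prediction_set"))
    pool_unlabeled$genotypes else pool_unlabeled
  stopifnot(is_geno_matrix(G_unlab))
  if (config$plateau_increment > nrow(G_unlab)) {
    stop_selfgp("Unlabeled pool is smaller than one plateau increment.",
                "selfgp_error_experiment")
  }
  reps <- purrr::map_dfr(config$labeled_sizes, function(nl) {
    purrr::map_dfr(seq_len(config$n_replicates), function(r) {
      s <- stream_seed(config$seed, sprintf("plateau:nl=%d:rep=%d", nl, r))
      dplyr::mutate(
        plateau_one_replicate(pool_labeled, G_unlab, test, nl,
                              config$plateau_increment,
                              config$plateau_tolerance, config$spec, s),
        replicate = r)
    })
  })
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_replicates(reps, "ratio", "n_labeled",
                                       config$ci_method), metric = "ratio"),
    dplyr::mutate(summarize_replicates(reps, "improvement", "n_labeled",
                                       config$ci_method), metric = "improvement"))
  structure(list(replicates = reps, summary = summary, config = config),
            class = "plateau_search")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %d sizes x %d replicates\n",
              length(unique(x$replicates$n_labeled)), x$config$n_replicates))
  print(x$summary)
  invisible(x)
}

#' @export
print.ratio_sweep <- function(x, ...) {
  cat(sprintf("<ratio_sweep> %d cells x %d replicates\n",
              nrow(unique(x$replicates[c("n_labeled", "n_unlabeled")])),
              x$config$n_replicates))
  print(x$summary)
  invisible(x)
}

#' @export
print.plateau_search <- function(x, ...) {
  cat(sprintf("<plateau_search> %d labeled sizes x %d replicates\n",
              length(unique(x$replicates$n_labeled)), x$config$n_replicates))
  print(x$summary)
  invisible(x)
}

#' @rdname learning_curve
#' @param x A result object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.learning_curve <- function(x, ...) x$summary

#' @rdname ratio_sweep
#' @param x A result object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ratio_sweep <- function(x, ...) x$summary

#' @rdname plateau_search
#' @param x A result object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.plateau_search <- function(x, ...) x$summary
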