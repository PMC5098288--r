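test_that("accuracy metrics match hand computations", {
  m <- evaluate_predictions(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m$correlation, 1)
  expect_equal(m$mse, 14 / 3)
  # perfect predictor
  p <- c(0.3, -0.2, 1.4, 0)
  mp <- evaluate_predictions(p, p)
  expect_equal(mp$correlation, 1)
  expect_equal(mp$mse, 0)
  # sign flip of centered values
  x <- c(-1, 0, 2, -1)
  expect_equal(evaluate_predictions(-x, x)$correlation, -1)
  # constant vector: correlation undefined, mse still returned
  expect_warning(mc <- evaluate_predictions(c(1, 1, 1), c(1, 2, 3)),
                 "undefined")
  expect_true(is.na(mc$correlation))
  expect_equal(mc$mse, mean(c(0, 1, 4)))
  expect_error(evaluate_predictions(c(1, 2), c(1, 2)),
               class = "selfgp_error_metrics")
})

test_that("metrics align predictions and phenotypes by animal id", {
  pr <- tibble::tibble(animal_id = c("a", "b", "c"), prediction = c(1, 2, 3))
  actual <- tibble::tibble(animal_id = c("c", "a", "b"), rfi = c(6, 2, 4))
  expect_equal(evaluate_predictions(pr, actual)$correlation, 1)
})

test_that("replicate summaries use the t-based 95% interval", {
  x <- c(0.21, 0.25, 0.19, 0.30, 0.27)
  s <- summarize_replicates(tibble::tibble(correlation = x))
  tt <- t.test(x)
  expect_equal(s$mean, mean(x))
  expect_equal(s$ci_lower, tt$conf.int[1])
  expect_equal(s$ci_upper, tt$conf.int[2])
  # single replicate: interval undefined but value kept
  s1 <- summarize_replicates(tibble::tibble(correlation = 0.4))
  expect_equal(s1$mean, 0.4)
  expect_true(is.na(s1$ci_lower))
})

make_pools <- function(seed = 51, n = 260, m = 120, h2 = 0.5) {
  pop <- quick_pop(n = n, m = m, seed = seed, h2 = h2,
                   cohort_variance_fraction = 0)
  ids <- animal_ids(pop$genotypes)
  k <- floor(n / 3)
  list(
    pool = prediction_set(gm_subset(pop$genotypes, animals = ids[1:k]),
                          pop$true_rfi[1:k, ]),
    unlab = gm_subset(pop$genotypes, animals = ids[(k + 1):(2 * k)]),
    test = prediction_set(gm_subset(pop$genotypes, animals = ids[(2 * k + 1):n]),
                          pop$true_rfi[(2 * k + 1):n, ]))
}

test_that("learning curves are reproducible and degenerate correctly at full pool size", {
  pools <- make_pools()
  n_pool <- nrow(pools$pool$genotypes)
  cfg <- experiment_config(labeled_sizes = c(20, n_pool), n_replicates = 4, seed = 3)
  lc1 <- learning_curve(pools$pool, pools$test, cfg)
  lc2 <- learning_curve(pools$pool, pools$test, cfg)
  expect_identical(lc1$replicates, lc2$replicates)
  # n = pool size: every replicate trains on the same animals -> zero CI width
  full <- lc1$replicates[lc1$replicates$n_labeled == n_pool, ]
  expect_equal(var(full$correlation), 0)
  s_full <- lc1$summary[lc1$summary$n_labeled == n_pool &
                          lc1$summary$metric == "correlation", ]
  expect_equal(s_full$ci_upper - s_full$ci_lower, 0)
  # a size exceeding the pool errors
  expect_error(learning_curve(pools$pool, pools$test,
                              experiment_config(labeled_sizes = n_pool + 1,
                                                n_replicates = 2)),
               class = "selfgp_error_experiment")
})

test_that("ratio sweeps pair the base and augmented predictors within replicates", {
  pools <- make_pools(seed = 52)
  cfg <- experiment_config(labeled_sizes = 40, unlabeled_sizes = c(0, 30),
                           n_replicates = 3, seed = 9)
  rs <- ratio_sweep(pools$pool, pools$unlab, pools$test, cfg)
  reps <- rs$replicates
  # zero unlabeled animals: supervised equivalence makes the paired gain 0
  zero <- reps[reps$n_unlabeled == 0, ]
  expect_true(all(abs(zero$correlation_gain) < 1e-9))
  # per-cell mean gain equals the mean of per-replicate paired differences
  cell <- reps[reps$n_unlabeled == 30, ]
  s <- rs$summary[rs$summary$n_unlabeled == 30 &
                    rs$summary$metric == "correlation_gain", ]
  expect_equal(s$mean, mean(cell$r_ssl - cell$r_sl))
  # determinism
  rs2 <- ratio_sweep(pools$pool, pools$unlab, pools$test, cfg)
  expect_identical(rs$replicates, rs2$replicates)
  # infeasible cells are reported, not silent
  cfg_big <- experiment_config(labeled_sizes = 40,
                               unlabeled_sizes = c(30, 10000),
                               n_replicates = 2, seed = 9)
  expect_warning(ratio_sweep(pools$pool, pools$unlab, pools$test, cfg_big),
                 "infeasible")
})

test_that("plateau search stops by rule: immediately at infinite tolerance, at exhaustion at zero", {
  pools <- make_pools(seed = 53)
  n_unlab <- nrow(pools$unlab)
  cfg_inf <- experiment_config(labeled_sizes = 40, n_replicates = 3,
                               plateau_increment = 20,
                               plateau_tolerance = Inf, seed = 21)
  ps <- plateau_search(pools$pool, pools$unlab, pools$test, cfg_inf)
  expect_true(all(ps$replicates$steps_evaluated == 1))
  expect_true(all(ps$replicates$ratio == 20 / 40))
  expect_false(any(ps$replicates$exhausted))
  # zero tolerance disables early stopping: runs to pool exhaustion, flagged
  cfg0 <- experiment_config(labeled_sizes = 40, n_replicates = 2,
                            plateau_increment = 30, plateau_tolerance = 0,
                            seed = 22)
  ps0 <- plateau_search(pools$pool, pools$unlab, pools$test, cfg0)
  expect_true(all(ps0$replicates$exhausted))
  expect_true(all(ps0$replicates$n_unlabeled_stop ==
                    floor(n_unlab / 30) * 30))
  # pool smaller than one increment errors
  expect_error(plateau_search(pools$pool, pools$unlab, pools$test,
                              experiment_config(labeled_sizes = 40,
                                                n_replicates = 1,
                                                plateau_increment = n_unlab + 1)),
               class = "selfgp_error_experiment")
})

test_that("seed streams are deterministic and label-sensitive", {
  expect_identical(stream_seed(7, "x:1"), stream_seed(7, "x:1"))
  expect_false(stream_seed(7, "x:1") == stream_seed(7, "x:2"))
  expect_false(stream_seed(7, "x:1") == stream_seed(8, "x:1"))
  s <- vapply(1:500, function(i) stream_seed(1, paste0("rep", i)), integer(1))
  expect_equal(anyDuplicated(s), 0)
})

test_that("result objects expose tidy summaries and plots", {
  pools <- make_pools(seed = 54)
  cfg <- experiment_config(labeled_sizes = c(20, 40), n_replicates = 2, seed = 2)
  lc <- learning_curve(pools$pool, pools$test, cfg)
  expect_s3_class(tidy(lc), "tbl_df")
  expect_s3_class(autoplot(lc), "ggplot")
  rs <- ratio_sweep(pools$pool, pools$unlab, pools$test,
                    experiment_config(labeled_sizes = 20, unlabeled_sizes = 20,
                                      n_replicates = 2, seed = 2))
  expect_s3_class(autoplot(rs), "ggplot")
  ps <- plateau_search(pools$pool, pools$unlab, pools$test,
                       experiment_config(labeled_sizes = 20, n_replicates = 2,
                                         plateau_increment = 40,
                                         plateau_tolerance = Inf, seed = 2))
  expect_s3_class(autoplot(ps), "ggplot")
})
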