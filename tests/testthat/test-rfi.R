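test_that("with the variance ratio fixed at zero the fit is ordinary least squares", {
  rec <- simulate_mm_records(n_cohorts = 30, per_cohort = 8, sigma2_r = 0,
                             sigma2_e = 0.5, seed = 11)
  fit <- fit_rfi_model(rec, gamma = 0)
  df <- rec
  df$ysc <- factor(df$ysc)
  df$par_age <- factor(df$par_age)
  ols <- lm(dmi ~ ysc + par_age + dim + milk_e + mbw, df,
            contrasts = list(ysc = "contr.sum", par_age = "contr.sum"))
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$sigma2_ration, 0)
  expect_true(all(fit$ration_blups == 0))
})

test_that("slopes are recovered on data simulated under the model", {
  rec <- simulate_mm_records(n_cohorts = 60, per_cohort = 15, sigma2_r = 0,
                             sigma2_e = 0.01,
                             beta = c(dim = 0.01, milk_e = 0.4, mbw = 0.02),
                             seed = 12)
  fit <- fit_rfi_model(rec)
  expect_equal(fit$beta2, 0.4, tolerance = 0.02)
  expect_equal(fit$beta1, 0.01, tolerance = 0.02)
  expect_equal(fit$beta3, 0.02, tolerance = 0.02)
})

test_that("REML estimates agree with the lme4 oracle", {
  skip_if_not_installed("lme4")
  rec <- simulate_mm_records(n_cohorts = 40, per_cohort = 10, sigma2_r = 0.3,
                             sigma2_e = 1, seed = 13)
  fit <- fit_rfi_model(rec)
  df <- rec
  df$ysc <- factor(df$ysc)
  df$par_age <- factor(df$par_age)
  lmm <- lme4::lmer(dmi ~ ysc + par_age + dim + milk_e + mbw + (1 | ration),
                    df, REML = TRUE,
                    contrasts = list(ysc = "contr.sum", par_age = "contr.sum"))
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(fit$sigma2_ration, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lmm)), tolerance = 1e-5)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(lmm)), tolerance = 1e-6)
  blup <- lme4::ranef(lmm)$ration
  expect_equal(unname(fit$ration_blups[rownames(blup)]), blup[[1]],
               tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("degenerate designs raise rank-deficiency errors", {
  rec <- simulate_mm_records(n_cohorts = 4, per_cohort = 10, seed = 14)
  rec$ysc <- "Y01"
  rec$par_age <- "P01"
  rec$dim <- 100
  rec$milk_e <- 30
  rec$mbw <- 128
  expect_error(fit_rfi_model(rec), "rank deficient", class = "selfgp_error_rfi")
  # fewer than 2 cohorts
  rec2 <- simulate_mm_records(n_cohorts = 4, per_cohort = 10, seed = 15)
  rec2$ration <- "R001"
  expect_error(fit_rfi_model(rec2), "cohorts", class = "selfgp_error_rfi")
})

test_that("weekly residuals behave like model residuals", {
  rec <- simulate_mm_records(n_cohorts = 30, per_cohort = 10, sigma2_r = 0.25,
                             sigma2_e = 1, seed = 16)
  fit <- fit_rfi_model(rec)
  res <- weekly_residuals(fit, rec)
  # intercept + sum-to-zero parameterization makes residuals sum to zero
  expect_lt(abs(mean(res$residual)), 1e-6 * sd(rec$dmi))
  # a record generated exactly at the fitted mean structure has residual ~ 0
  rec1 <- rec[1, ]
  rec1$dmi <- rec1$dmi - res$residual[1]
  expect_lt(abs(weekly_residuals(fit, rec1)$residual), 1e-8)
  # adding a constant to dmi shifts mu and leaves residuals unchanged
  rec_c <- rec
  rec_c$dmi <- rec_c$dmi + 5
  fit_c <- fit_rfi_model(rec_c, gamma = fit$gamma)
  expect_equal(fit_c$mu, fit$mu + 5, tolerance = 1e-8)
  expect_equal(weekly_residuals(fit_c, rec_c)$residual, res$residual,
               tolerance = 1e-8)
  # unseen factor level errors rather than getting a silent zero
  rec_u <- rec[1, ]
  rec_u$ysc <- "Y99"
  expect_error(weekly_residuals(fit, rec_u), "Y99",
               class = "selfgp_error_rfi_levels")
})

test_that("residuals are invariant to the fixed-effect parameterization", {
  rec <- simulate_mm_records(n_cohorts = 25, per_cohort = 8, sigma2_r = 0.2,
                             seed = 17)
  fit <- fit_rfi_model(rec)
  res <- weekly_residuals(fit, rec)
  df <- rec
  df$ysc <- factor(df$ysc)
  df$par_age <- factor(df$par_age)
  # treatment-contrast GLS fit at the same variance ratio gives the same residuals
  X_tr <- model.matrix(~ ysc + par_age + dim + milk_e + mbw, df)
  g <- fit$gamma
  Z <- model.matrix(~ 0 + factor(ration), df)
  H_inv <- diag(nrow(df)) - Z %*% solve(crossprod(Z) + diag(ncol(Z)) / g, t(Z))
  beta_tr <- solve(t(X_tr) %*% H_inv %*% X_tr, t(X_tr) %*% H_inv %*% df$dmi)
  r_fixed <- df$dmi - X_tr %*% beta_tr
  u <- solve(crossprod(Z) + diag(ncol(Z)) / g, t(Z) %*% r_fixed)
  expect_equal(as.numeric(r_fixed - Z %*% u), res$residual, tolerance = 1e-6)
})

test_that("per-animal aggregation is the arithmetic mean of weekly residuals", {
  res <- tibble::tibble(animal_id = c("a", "b", "b", "b", "b", "c"),
                        residual = c(0.7, 1.0, -1.0, 0.5, -0.5, -0.2))
  agg <- aggregate_rfi(res)
  expect_equal(agg$rfi[agg$animal_id == "a"], 0.7)   # single week
  expect_equal(agg$rfi[agg$animal_id == "b"], 0)     # symmetric set
  expect_equal(agg$n_weeks, c(1L, 4L, 1L))
  expect_equal(nrow(agg), length(unique(res$animal_id)))
  # weighted mean of per-animal rfi recovers the overall residual mean
  expect_equal(sum(agg$rfi * agg$n_weeks) / sum(agg$n_weeks),
               mean(res$residual))
})

test_that("fixed-effect bias shrinks as the data grow", {
  est <- vapply(c(200, 3200), function(n_rec) {
    rec <- simulate_mm_records(n_cohorts = 20, per_cohort = n_rec / 20,
                               sigma2_r = 0.1, sigma2_e = 1,
                               beta = c(dim = 0.01, milk_e = 0.4, mbw = 0.02),
                               seed = 18)
    fit_rfi_model(rec)$beta2
  }, numeric(1))
  expect_lt(abs(est[2] - 0.4), abs(est[1] - 0.4))
})

test_that("tidy and glance expose the fit in rectangular form", {
  rec <- simulate_mm_records(n_cohorts = 10, per_cohort = 10, seed = 19)
  fit <- fit_rfi_model(rec)
  td <- tidy(fit)
  expect_true(all(c("term", "level", "estimate") %in% names(td)))
  # sum-to-zero: per-factor effects sum to zero
  expect_equal(sum(td$estimate[td$term == "ysc"]), 0, tolerance = 1e-10)
  expect_equal(sum(td$estimate[td$term == "par_age"]), 0, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(rec))
  expect_true(gl$sigma2_resid > 0)
})
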