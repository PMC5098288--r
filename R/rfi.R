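#' Fit the residual-feed-intake mixed model to weekly records
#'
#' Fits, by restricted maximum likelihood, the linear mixed model for weekly
#' dry-matter intake
#'
#' \deqn{y = \mu + YSC + ParAge + \beta_1 dim + \beta_2 MilkE + \beta_3 MBW
#'   + ration + e,}
#'
#' with fixed year-season-of-calving and parity-age class effects
#' (sum-to-zero parameterization with explicit intercept), three fixed
#' covariate slopes, a random ration-cohort effect `ration ~ N(0, I sigma_r^2)`
#' and residual `e ~ N(0, I sigma_e^2)`. Weekly residuals from this model are
#' the weekly RFI estimates; see [weekly_residuals()] and [aggregate_rfi()].
#'
#' The restricted likelihood is profiled over the single variance ratio
#' `gamma = sigma_r^2 / sigma_e^2` and maximized by bounded one-dimensional
#' search on `gamma` in `[0, 1e3]` (convergence tolerance 1e-8), which is
#' robust for a one-random-effect model; because the cohort incidence matrix
#' has orthogonal columns the profiled quantities are available in closed
#' form via rank-q downdates. Fixed effects are then solved from the
#' generalized-least-squares equations at the REML variances and cohort
#' effects are returned as BLUPs, which shrink toward zero as `sigma_r^2`
#' approaches zero.
#'
#' @param records Data frame of weekly records with columns `animal_id, week,
#'   dim, dmi, milk_e, mbw, ysc, par_age, ration` (see
#'   [read_weekly_records()]).
#' @param gamma Optional non-negative value fixing the variance ratio
#'   `sigma_r^2 / sigma_e^2` instead of estimating it; `gamma = 0` reduces the
#'   fit to ordinary least squares on the fixed effects.
#' @param gamma_upper Upper search bound for the variance ratio.
#' @return An `rfi_model_fit` object with elements `mu`, `ysc_effects`,
#'   `par_age_effects` (full per-level values on the sum-to-zero scale),
#'   `beta1`, `beta2`, `beta3`, `sigma2_ration`, `sigma2_resid`,
#'   `ration_blups`, `log_likelihood` (restricted), `converged`, plus the
#'   design metadata needed by [weekly_residuals()].
#' @export
fit_rfi_model <- function(records, gamma = NULL, gamma_upper = 1e3) {
  records <- validate_records(records)
  if (length(unique(records$ration)) < 2) {
    stop_selfgp("At least 2 ration cohorts are required to separate cohort and residual variance.",
                "selfgp_error_rfi")
  }
  des <- build_rfi_design(records)
  X <- des$X
  y <- records$dmi
  n <- length(y)
  p <- ncol(X)

  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop_selfgp(sprintf("Fixed-effect design is rank deficient; confounded column(s): %s.",
                        paste(dropped, collapse = ", ")), "selfgp_error_rfi")
  }

  # cohort incidence: Z'Z is diagonal with cohort sizes, so H^{-1} with
  # H = I + gamma Z Z' is available by a diagonal Woodbury downdate
  ration <- des$ration
  q <- nlevels(ration)
  counts <- as.numeric(table(ration))
  Zt_y <- as.numeric(rowsum_matrix(matrix(y), ration)) # q vector, level order
  Zt_X <- rowsum_matrix(X, ration)                      # q x p
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)

  reml_pieces <- function(g) {
    # profiled restricted log-likelihood at variance ratio g (sigma_e^2 profiled out)
    if (g <= 0) {
      M <- XtX
      Xhy <- Xty
      yhy <- yty
      logdetH <- 0
    } else {
      d <- g / (1 + g * counts)                      # (Z'Z + I/g)^{-1} diagonal
      M <- XtX - crossprod(Zt_X, Zt_X * d)
      Xhy <- Xty - crossprod(Zt_X, Zt_y * d)
      yhy <- yty - sum(d * Zt_y^2)
      logdetH <- sum(log1p(g * counts))
    }
    cholM <- chol(M)
    beta <- backsolve(cholM, forwardsolve(t(cholM), Xhy))
    ypy <- yhy - sum(Xhy * beta)
    sigma2 <- ypy / (n - p)
    ll <- -0.5 * (logdetH + 2 * sum(log(diag(cholM))) +
                    (n - p) * log(sigma2) + (n - p) + (n - p) * log(2 * pi))
    list(ll = ll, beta = as.numeric(beta), sigma2 = sigma2)
  }

  converged <- TRUE
  if (is.null(gamma)) {
    opt <- optimize(function(g) reml_pieces(g)$ll, c(0, gamma_upper),
                    maximum = TRUE, tol = 1e-8)
    gamma_hat <- opt$maximum
    # the interior optimum can miss the gamma = 0 boundary; take the better
    if (reml_pieces(0)$ll >= opt$objective) gamma_hat <- 0
    if (gamma_hat > 0.999 * gamma_upper) {
      warn("REML variance ratio hit the upper search bound; fit flagged as not converged.")
      converged <- FALSE
    }
  } else {
    if (!is.numeric(gamma) || gamma < 0) {
      stop_selfgp("`gamma` must be a single non-negative number.", "selfgp_error_rfi")
    }
    gamma_hat <- gamma
  }

  at <- reml_pieces(gamma_hat)
  beta <- setNames(at$beta, colnames(X))
  sigma2_e <- at$sigma2
  sigma2_r <- gamma_hat * sigma2_e

  # BLUPs: u = (Z'Z + I/gamma)^{-1} Z'(y - X beta); zero when gamma = 0
  resid_fixed <- y - as.numeric(X %*% beta)
  if (gamma_hat > 0) {
    d <- gamma_hat / (1 + gamma_hat * counts)
    u <- d * as.numeric(rowsum_matrix(matrix(resid_fixed), ration))
  } else {
    u <- numeric(q)
  }
  names(u) <- levels(ration)

  fe <- expand_sum_to_zero(beta, des)
  structure(list(
    mu = unname(beta["(Intercept)"]),
    ysc_effects = fe$ysc, par_age_effects = fe$par_age,
    beta1 = unname(beta["dim"]), beta2 = unname(beta["milk_e"]),
    beta3 = unname(beta["mbw"]),
    sigma2_ration = sigma2_r, sigma2_resid = sigma2_e,
    gamma = gamma_hat, ration_blups = u,
    log_likelihood = at$ll, converged = converged,
    beta = beta, levels = des$levels, n_obs = n, n_fixed = p),
    class = "rfi_model_fit")
}

# rowsum() for a matrix grouped by factor, returning group x col matrix
rowsum_matrix <- function(X, f) {
  out <- rowsum(X, f)
  out[levels(f), , drop = FALSE]
}

validate_records <- function(records) {
  required <- c("animal_id", "dim", "dmi", "milk_e", "mbw", "ysc", "par_age", "ration")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop_selfgp(sprintf("Weekly records lack column(s): %s.",
                        paste(missing, collapse = ", ")), "selfgp_error_rfi")
  }
  num <- c("dim", "dmi", "milk_e", "mbw")
  bad <- !complete.cases(records[num]) |
    !apply(is.finite(as.matrix(records[num])), 1, all)
  if (any(bad)) {
    stop_selfgp(sprintf("%d weekly record(s) have missing or non-finite numeric values.",
                        sum(bad)), "selfgp_error_rfi")
  }
  if (any(records$dmi <= 0) || any(records$mbw <= 0)) {
    stop_selfgp("dmi and mbw must be positive.", "selfgp_error_rfi")
  }
  records
}

# sum-to-zero design for ysc + par_age + covariates, with level bookkeeping
build_rfi_design <- function(records, levels = NULL) {
  if (is.null(levels)) {
    levels <- list(ysc = sort(unique(as.character(records$ysc))),
                   par_age = sort(unique(as.character(records$par_age))),
                   ration = sort(unique(as.character(records$ration))))
  } else {
    for (nm in c("ysc", "par_age", "ration")) {
      unseen <- setdiff(unique(as.character(records[[nm]])), levels[[nm]])
      if (length(unseen) > 0) {
        stop_selfgp(sprintf("Unseen %s level(s) not present in the fitted model: %s.",
                            nm, paste(unseen, collapse = ", ")),
                    "selfgp_error_rfi_levels")
      }
    }
  }
  ysc <- factor(records$ysc, levels = levels$ysc)
  par_age <- factor(records$par_age, levels = levels$par_age)
  ration <- factor(records$ration, levels = levels$ration)
  df <- data.frame(dim = records$dim, milk_e = records$milk_e, mbw = records$mbw)
  terms <- c(
    if (nlevels(ysc) > 1) "ysc",
    if (nlevels(par_age) > 1) "par_age",
    "dim", "milk_e", "mbw")
  df$ysc <- ysc
  df$par_age <- par_age
  contrasts_arg <- list()
  if (nlevels(ysc) > 1) contrasts_arg$ysc <- "contr.sum"
  if (nlevels(par_age) > 1) contrasts_arg$par_age <- "contr.sum"
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- if (length(contrasts_arg) > 0) {
    model.matrix(fml, df, contrasts.arg = contrasts_arg)
  } else {
    model.matrix(fml, df)
  }
  list(X = X, ration = ration, levels = levels)
}

# recover full per-level sum-to-zero effects from the contrast coefficients
expand_sum_to_zero <- function(beta, des) {
  expand_one <- function(prefix, lev) {
    if (length(lev) < 2) return(setNames(numeric(length(lev)), lev))
    cf <- beta[paste0(prefix, seq_len(length(lev) - 1))]
    setNames(c(cf, -sum(cf)), lev)
  }
  list(ysc = expand_one("ysc", des$levels$ysc),
       par_age = expand_one("par_age", des$levels$par_age))
}

#' @export
print.rfi_model_fit <- function(x, ...) {
  cat(sprintf(paste0("<rfi_model_fit> %d records, %d fixed effects\n",
                     "  mu = %.3f, beta(dim, milk_e, mbw) = (%.4f, %.4f, %.4f)\n",
                     "  sigma2_ration = %.4f, sigma2_resid = %.4f (gamma = %.4f)\n",
                     "  restricted logLik = %.2f, converged = %s\n"),
              x$n_obs, x$n_fixed, x$mu, x$beta1, x$beta2, x$beta3,
              x$sigma2_ration, x$sigma2_resid, x$gamma,
              x$log_likelihood, x$converged))
  invisible(x)
}

#' @rdname fit_rfi_model
#' @param x An `rfi_model_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rfi_model_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(Intercept)", level = NA_character_, estimate = x$mu),
    tibble(term = "ysc", level = names(x$ysc_effects),
           estimate = unname(x$ysc_effects)),
    tibble(term = "par_age", level = names(x$par_age_effects),
           estimate = unname(x$par_age_effects)),
    tibble(term = c("dim", "milk_e", "mbw"), level = NA_character_,
           estimate = c(x$beta1, x$beta2, x$beta3)),
    tibble(term = "ration_blup", level = names(x$ration_blups),
           estimate = unname(x$ration_blups)))
}

#' @rdname fit_rfi_model
#' @exportS3Method generics::glance
glance.rfi_model_fit <- function(x, ...) {
  tibble(sigma2_ration = x$sigma2_ration, sigma2_resid = x$sigma2_resid,
         gamma = x$gamma, log_likelihood = x$log_likelihood,
         nobs = x$n_obs, n_fixed = x$n_fixed, converged = x$converged)
}

#' Weekly RFI estimates: residuals of the fitted intake model
#'
#' For each weekly record, subtracts the fitted mean structure — intercept,
#' year-season and parity-age effects, the three covariate contributions and
#' the ration-cohort BLUP — from observed dry-matter intake. The residual is
#' that week's RFI estimate. Records with factor levels unseen at fit time
#' raise an error; they are never silently given a zero effect.
#'
#' @param fit An `rfi_model_fit` from [fit_rfi_model()].
#' @param records Weekly records (same columns as for [fit_rfi_model()]).
#' @return The `records` tibble with an added `residual` column.
#' @export
weekly_residuals <- function(fit, records) {
  stopifnot(inherits(fit, "rfi_model_fit"))
  records <- validate_records(records)
  des <- build_rfi_design(records, levels = fit$levels)
  keep <- intersect(names(fit$beta), colnames(des$X))
  fitted_fixed <- as.numeric(des$X[, keep, drop = FALSE] %*% fit$beta[keep])
  fitted <- fitted_fixed + unname(fit$ration_blups[as.character(records$ration)])
  dplyr::mutate(as_tibble(records), residual = .data$dmi - fitted)
}

#' Aggregate weekly residuals into per-animal RFI phenotypes
#'
#' The RFI phenotype of an animal is the arithmetic mean of its weekly RFI
#' estimates (unweighted), with the number of contributing weeks recorded.
#'
#' @param residuals Tibble with columns `animal_id` and `residual`, e.g. from
#'   [weekly_residuals()].
#' @return A tibble `animal_id, rfi, n_weeks`, one row per animal with at
#'   least one record.
#' @export
aggregate_rfi <- function(residuals) {
  if (!all(c("animal_id", "residual") %in% names(residuals))) {
    stop_selfgp("`residuals` must have columns animal_id and residual.", "selfgp_error_rfi")
  }
  residuals |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(rfi = mean(.data$residual), n_weeks = dplyr::n(),
                     .groups = "drop")
}

#' Derive per-animal RFI phenotypes from weekly records in one call
#'
#' Convenience pipeline: [fit_rfi_model()], [weekly_residuals()],
#' [aggregate_rfi()].
#'
#' @inheritParams fit_rfi_model
#' @return A list with `fit` (the `rfi_model_fit`) and `phenotypes` (tibble
#'   `animal_id, rfi, n_weeks`).
#' @export
derive_rfi <- function(records, gamma = NULL) {
  fit <- fit_rfi_model(records, gamma = gamma)
  res <- weekly_residuals(fit, records)
  list(fit = fit, phenotypes = aggregate_rfi(res))
}
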