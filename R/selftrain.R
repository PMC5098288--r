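#' Specify the base genomic predictor
#'
#' Describes the base learner wrapped by the self-training algorithm. The
#' shipped learner is epsilon-insensitive support-vector regression with a
#' radial-basis-function kernel `k(u, v) = exp(-gamma * ||u - v||^2)` (via
#' \pkg{e1071}); defaults mirror that implementation's documented defaults
#' (`cost = 1`, `gamma = 1/n_markers`, `epsilon = 0.1`). Hyperparameter
#' tuning is off by default for reproducibility; `tuning = "grid"` enables a
#' seeded k-fold cross-validated grid search within the training set only.
#'
#' @param kind Predictor kind; `"svm_rbf"` is the only shipped learner. Any
#'   object implementing the fit/predict contract of [train_base()] can stand
#'   in externally.
#' @param cost SVR cost parameter `C > 0`.
#' @param gamma RBF kernel width; `NULL` means `1 / n_markers` at fit time.
#' @param epsilon Width of the epsilon-insensitive tube.
#' @param tuning `"none"` or `"grid"`.
#' @param grid Named list with `cost` (absolute values) and `gamma_mult`
#'   (multipliers of `1/n_markers`) defining the search grid.
#' @param folds Number of cross-validation folds for grid tuning.
#' @param standardize_features Center and scale each marker column by
#'   training-set statistics (zero-variance columns are set to 0 so that
#'   marker sets stay aligned across matrices).
#' @param seed Integer seed driving fold assignment (the SVR fit itself is
#'   deterministic).
#' @return A validated `predictor_spec` list.
#' @export
predictor_spec <- function(kind = "svm_rbf", cost = 1, gamma = NULL,
                           epsilon = 0.1, tuning = c("none", "grid"),
                           grid = list(cost = c(0.25, 1, 4),
                                       gamma_mult = c(0.25, 1, 4)),
                           folds = 5, standardize_features = TRUE, seed = 1) {
  tuning <- match.arg(tuning)
  if (kind != "svm_rbf") {
    stop_selfgp("Only kind = 'svm_rbf' ships with the package.", "selfgp_error_config")
  }
  if (cost <= 0 || epsilon <= 0 || (!is.null(gamma) && gamma <= 0)) {
    stop_selfgp("`cost`, `gamma` and `epsilon` must be positive.", "selfgp_error_config")
  }
  if (tuning == "grid" &&
      (length(grid$cost) == 0 || length(grid$gamma_mult) == 0)) {
    stop_selfgp("Tuning grid must be non-empty when tuning = 'grid'.", "selfgp_error_config")
  }
  structure(list(kind = kind, cost = cost, gamma = gamma, epsilon = epsilon,
                 tuning = tuning, grid = grid, folds = as.integer(folds),
                 standardize_features = isTRUE(standardize_features),
                 seed = as.integer(seed)),
            class = "predictor_spec")
}

std_stats <- function(X) {
  list(center = colMeans(X), scale = apply(X, 2, sd))
}

apply_std <- function(X, st) {
  Xs <- sweep(X, 2, st$center)
  sc <- ifelse(st$scale > 0, st$scale, 1)
  Xs <- sweep(Xs, 2, sc, "/")
  if (any(st$scale == 0)) Xs[, st$scale == 0] <- 0
  Xs
}

fit_svr <- function(X, y, cost, gamma, epsilon) {
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             cost = cost, gamma = gamma, epsilon = epsilon, scale = FALSE,
             fitted = FALSE)
}

# predict that tolerates the zero-support-vector solution (e.g. a constant
# target leaves every point inside the epsilon tube): f(x) = -rho there
predict_svr <- function(model, X) {
  if (model$tot.nSV == 0) return(rep(-model$rho, nrow(X)))
  as.numeric(predict(model, X))
}

cv_tune <- function(X, y, spec, gamma_default) {
  folds <- min(spec$folds, length(y))
  assign <- withr::with_seed(stream_seed(spec$seed, "cv_folds"),
                             sample(rep_len(seq_len(folds), length(y))))
  grid <- expand.grid(cost = spec$grid$cost,
                      gamma = spec$grid$gamma_mult * gamma_default)
  cv_mse <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(folds), function(k) {
      tr <- assign != k
      if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
      m <- fit_svr(X[tr, , drop = FALSE], y[tr], grid$cost[i], grid$gamma[i],
                   spec$epsilon)
      mean((predict_svr(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(cv_mse) # ties resolve to the first (smallest cost) entry
  list(cost = grid$cost[best], gamma = grid$gamma[best])
}

#' Train the base genomic predictor
#'
#' Fits the predictor described by a [predictor_spec()] on a fully imputed
#' genotype matrix and aligned phenotypes: marker columns are standardized by
#' training-set statistics (when enabled), hyperparameters optionally tuned by
#' seeded k-fold cross-validation within the training data, and an RBF-kernel
#' support-vector regression fitted.
#'
#' @param G A fully imputed [genotype_matrix()] (no missing entries).
#' @param phenotypes Per-animal phenotypes: a tibble with `animal_id` plus a
#'   numeric column, or a (named) numeric vector aligned with `G`.
#' @param spec A [predictor_spec()].
#' @return A `trained_predictor` carrying the fitted SVR, the training
#'   standardization statistics and the marker set it was trained on.
#' @export
train_base <- function(G, phenotypes, spec = predictor_spec()) {
  stopifnot(is_geno_matrix(G))
  if (anyNA(G)) {
    stop_selfgp("Genotype matrix contains missing entries; run impute_missing() first.",
                "selfgp_error_predictor")
  }
  y <- align_phenotypes(phenotypes, animal_ids(G))
  if (length(y) < 2) {
    stop_selfgp("At least 2 training animals are required.", "selfgp_error_predictor")
  }
  if (!all(is.finite(y))) {
    stop_selfgp("Phenotypes must be finite.", "selfgp_error_predictor")
  }
  X <- gm_values(G)
  storage.mode(X) <- "double"
  st <- if (spec$standardize_features) std_stats(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- apply_std(X, st)
  gamma_default <- if (is.null(spec$gamma)) 1 / ncol(X) else spec$gamma
  hp <- list(cost = spec$cost, gamma = gamma_default)
  if (spec$tuning == "grid") {
    hp <- cv_tune(Xs, y, spec, gamma_default)
  }
  model <- fit_svr(Xs, y, hp$cost, hp$gamma, spec$epsilon)
  structure(list(model = model, spec = spec, hyperparameters = hp,
                 center = st$center, scale = st$scale,
                 marker_ids = marker_ids(G), animal_ids = animal_ids(G),
                 n_train = length(y)),
            class = "trained_predictor")
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("<trained_predictor> svm_rbf on %d animals x %d markers (C = %g, gamma = %g, epsilon = %g)\n",
              x$n_train, length(x$marker_ids), x$hyperparameters$cost,
              x$hyperparameters$gamma, x$spec$epsilon))
  invisible(x)
}

#' @rdname train_base
#' @param x A `trained_predictor`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.trained_predictor <- function(x, ...) {
  tibble(kind = x$spec$kind, n_train = x$n_train,
         n_markers = length(x$marker_ids),
         cost = x$hyperparameters$cost, gamma = x$hyperparameters$gamma,
         epsilon = x$spec$epsilon, tuning = x$spec$tuning,
         n_support_vectors = x$model$tot.nSV)
}

#' Predict phenotypes for genotyped animals
#'
#' Applies a trained predictor to a genotype matrix over the same marker set
#' (column order is normalized to the training order, so permuted input
#' columns give identical predictions). Training-set standardization
#' statistics are re-applied.
#'
#' @param f A `trained_predictor` from [train_base()].
#' @param G A fully imputed [genotype_matrix()] whose marker set equals the
#'   training marker set.
#' @return A tibble `animal_id, prediction`; empty input gives an empty
#'   tibble.
#' @export
predict_phenotypes <- function(f, G) {
  stopifnot(inherits(f, "trained_predictor"), is_geno_matrix(G))
  check_same_markers(f$marker_ids, marker_ids(G))
  if (nrow(G) == 0) {
    return(tibble(animal_id = character(0), prediction = numeric(0)))
  }
  if (anyNA(G)) {
    stop_selfgp("Genotype matrix contains missing entries; run impute_missing() first.",
                "selfgp_error_predictor")
  }
  X <- gm_values(G)[, f$marker_ids, drop = FALSE]
  storage.mode(X) <- "double"
  Xs <- apply_std(X, list(center = f$center, scale = f$scale))
  tibble(animal_id = animal_ids(G),
         prediction = predict_svr(f$model, Xs))
}

#' Self-training: semi-supervised genomic prediction
#'
#' The three-step self-training wrapper:
#'
#' 1. train the base predictor `f` on labeled animals (`G1`, `P1`);
#' 2. predict self-trained phenotypes `P2_hat` for the unlabeled animals `G2`;
#' 3. retrain on the row-concatenation (`G1 || G2`, `P1 || P2_hat`) — plain
#'    concatenation with equal weight per animal and no confidence filtering
#'    — to obtain the augmented predictor `f*`.
#'
#' The identical predictor specification (including tuning mode) is re-run at
#' step 3, and standardization statistics for `f*` are recomputed on the
#' combined set. With no unlabeled animals the procedure reduces exactly to
#' supervised learning: `f*` and `f` give identical predictions.
#'
#' @param G1 Labeled animals' [genotype_matrix()] (fully imputed).
#' @param P1 Their measured phenotypes (tibble or numeric, see
#'   [train_base()]).
#' @param G2 Unlabeled animals' [genotype_matrix()] over the same markers,
#'   with animal IDs disjoint from `G1`; may have zero rows.
#' @param spec A [predictor_spec()].
#' @return A `self_train_result` with elements `base` (`f`), `augmented`
#'   (`f*`), `self_trained` (tibble `animal_id, prediction` = `P2_hat`),
#'   `n_labeled`, `n_unlabeled`.
#' @export
self_train <- function(G1, P1, G2, spec = predictor_spec()) {
  stopifnot(is_geno_matrix(G1), is_geno_matrix(G2))
  if (nrow(G2) > 0) check_same_markers(marker_ids(G1), marker_ids(G2))
  f <- train_base(G1, P1, spec)
  p1 <- align_phenotypes(P1, animal_ids(G1), arg = "P1")
  if (nrow(G2) == 0) {
    f_star <- train_base(G1, p1, spec)
    p2 <- tibble(animal_id = character(0), prediction = numeric(0))
  } else {
    p2 <- predict_phenotypes(f, G2)
    G_comb <- gm_rbind(G1, G2) # errors on animal-ID collision
    y_comb <- c(setNames(p1, animal_ids(G1)),
                setNames(p2$prediction, p2$animal_id))
    f_star <- train_base(G_comb, y_comb, spec)
  }
  structure(list(base = f, augmented = f_star, self_trained = p2,
                 n_labeled = nrow(G1), n_unlabeled = nrow(G2)),
            class = "self_train_result")
}

#' @export
print.self_train_result <- function(x, ...) {
  cat(sprintf("<self_train_result> %d labeled + %d self-trained animals\n",
              x$n_labeled, x$n_unlabeled))
  invisible(x)
}

#' @rdname self_train
#' @param x A `self_train_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.self_train_result <- function(x, ...) {
  tibble(n_labeled = x$n_labeled, n_unlabeled = x$n_unlabeled,
         cost = x$base$hyperparameters$cost,
         gamma = x$base$hyperparameters$gamma)
}
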