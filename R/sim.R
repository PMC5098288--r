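#' Simulation parameters for a synthetic reference population
#'
#' Bundles and validates every knob of the quantitative-genetics simulator.
#' Defaults emulate the shape of a dairy-cattle feed-efficiency study: 792
#' phenotyped cows, a purely additive trait with heritability 0.15, weekly
#' dry-matter-intake records over one lactation (20 weeks in the 50-200
#' days-in-milk window), 81 ration cohorts carrying 10% of the phenotypic
#' variance, 19 year-season and 20 parity-age fixed-effect levels, and ~2%
#' missing genotypes. The marker panel defaults to 2000 independent loci — a
#' desk-scale stand-in for a ~50k SNP array. The genetic architecture
#' (`n_qtl`, effect-size distribution) is a placeholder: nothing is known
#' about the true architecture of residual feed intake, so these defaults are
#' conventional, not estimates.
#'
#' Variance is partitioned on the per-animal RFI scale: with total deviation
#' variance `V` (default 1 (kg/day)^2), breeding values carry
#' `heritability * V`, ration cohorts `cohort_variance_fraction * V`, and the
#' per-animal residual the remainder. The residual is split into a permanent
#' animal deviation and week-to-week noise (`week_noise_fraction` of the
#' residual variance at the weekly level) such that averaging an animal's
#' weekly residuals recovers exactly the configured per-animal partition.
#'
#' @param n_animals,n_markers,n_qtl Population and panel sizes; `n_qtl <=
#'   n_markers` loci carry nonzero additive effects.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-locus allele
#'   frequencies are drawn uniformly from this interval.
#' @param heritability Fraction of per-animal deviation variance that is
#'   additive-genetic, in (0, 1]; default 0.15.
#' @param n_weeks_per_animal Weekly records per animal (one lactation).
#' @param n_cohorts Number of ration cohorts (random effects).
#' @param cohort_variance_fraction Fraction of deviation variance from ration
#'   cohorts, in `[0, 1)`; `heritability + cohort_variance_fraction <= 1`.
#' @param fixed_effect_magnitudes Named list: `ysc` and `par_age` are the
#'   standard deviations of the corresponding fixed-effect level values;
#'   `dim`, `milk_e` and `mbw` are the regression slopes themselves.
#' @param missing_rate Fraction of genotype entries set missing, in `[0, 1)`.
#' @param birth_year_range Length-2 integer vector of birth years.
#' @param split_date Date separating the training pool from the test set.
#' @param test_fraction Fraction of animals born on/after `split_date`
#'   (default 252/792).
#' @param week_noise_fraction Fraction of the weekly residual variance that is
#'   week-to-week noise rather than a permanent animal deviation, in `[0, 1]`.
#' @param n_ysc_levels,n_par_age_levels Numbers of year-season-of-calving and
#'   parity-age fixed-effect levels.
#' @param mean_dmi Population mean dry-matter intake (kg/day).
#' @param total_deviation_variance Total per-animal deviation variance `V`
#'   ((kg/day)^2).
#' @param seed Integer seed; identical parameters give identical populations.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_animals = 792, n_markers = 2000, n_qtl = 200,
                       maf_range = c(0.05, 0.5), heritability = 0.15,
                       n_weeks_per_animal = 20, n_cohorts = 81,
                       cohort_variance_fraction = 0.10,
                       fixed_effect_magnitudes = list(ysc = 0.5, par_age = 0.5,
                                                      dim = 0.005, milk_e = 0.35,
                                                      mbw = 0.01),
                       missing_rate = 0.02,
                       birth_year_range = c(2007, 2013),
                       split_date = as.Date("2010-01-01"),
                       test_fraction = 252 / 792,
                       week_noise_fraction = 0.5,
                       n_ysc_levels = 19, n_par_age_levels = 20,
                       mean_dmi = 23, total_deviation_variance = 1.0,
                       seed = 1) {
  check_pos_int <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 || x != floor(x)) {
      stop_selfgp(sprintf("`%s` must be a positive integer.", nm), "selfgp_error_config")
    }
  }
  check_pos_int(n_animals, "n_animals")
  check_pos_int(n_markers, "n_markers")
  check_pos_int(n_qtl, "n_qtl")
  check_pos_int(n_weeks_per_animal, "n_weeks_per_animal")
  check_pos_int(n_cohorts, "n_cohorts")
  check_pos_int(n_ysc_levels, "n_ysc_levels")
  check_pos_int(n_par_age_levels, "n_par_age_levels")
  if (n_qtl > n_markers) {
    stop_selfgp("`n_qtl` must not exceed `n_markers`.", "selfgp_error_config")
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop_selfgp("`maf_range` must be an increasing pair within (0, 0.5].", "selfgp_error_config")
  }
  if (!is.numeric(heritability) || heritability <= 0 || heritability > 1) {
    stop_selfgp("`heritability` must lie in (0, 1].", "selfgp_error_config")
  }
  if (cohort_variance_fraction < 0 || cohort_variance_fraction >= 1) {
    stop_selfgp("`cohort_variance_fraction` must lie in [0, 1).", "selfgp_error_config")
  }
  if (heritability + cohort_variance_fraction > 1) {
    stop_selfgp("`heritability` + `cohort_variance_fraction` must not exceed 1.", "selfgp_error_config")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_selfgp("`missing_rate` must lie in [0, 1).", "selfgp_error_config")
  }
  if (week_noise_fraction < 0 || week_noise_fraction > 1) {
    stop_selfgp("`week_noise_fraction` must lie in [0, 1].", "selfgp_error_config")
  }
  if (test_fraction < 0 || test_fraction >= 1) {
    stop_selfgp("`test_fraction` must lie in [0, 1).", "selfgp_error_config")
  }
  needed <- c("ysc", "par_age", "dim", "milk_e", "mbw")
  if (!all(needed %in% names(fixed_effect_magnitudes))) {
    stop_selfgp(sprintf("`fixed_effect_magnitudes` must name: %s.",
                        paste(needed, collapse = ", ")), "selfgp_error_config")
  }
  split_date <- as.Date(split_date)
  if (length(birth_year_range) != 2 || birth_year_range[1] > birth_year_range[2]) {
    stop_selfgp("`birth_year_range` must be an increasing pair of years.", "selfgp_error_config")
  }
  structure(list(
    n_animals = as.integer(n_animals), n_markers = as.integer(n_markers),
    n_qtl = as.integer(n_qtl), maf_range = as.numeric(maf_range),
    heritability = heritability, n_weeks_per_animal = as.integer(n_weeks_per_animal),
    n_cohorts = as.integer(n_cohorts),
    cohort_variance_fraction = cohort_variance_fraction,
    fixed_effect_magnitudes = fixed_effect_magnitudes,
    missing_rate = missing_rate,
    birth_year_range = as.integer(birth_year_range), split_date = split_date,
    test_fraction = test_fraction, week_noise_fraction = week_noise_fraction,
    n_ysc_levels = as.integer(n_ysc_levels),
    n_par_age_levels = as.integer(n_par_age_levels),
    mean_dmi = mean_dmi, total_deviation_variance = total_deviation_variance,
    seed = as.integer(seed)), class = "sim_params")
}

#' Simulate a genotype matrix of independent biallelic loci
#'
#' Each marker *j* gets an allele frequency `p_j ~ Uniform(maf_range)`; the
#' genotype of each animal at that marker is Binomial(2, p_j) — two
#' independent allele draws, i.e. Hardy-Weinberg proportions with no linkage
#' disequilibrium. A fraction `missing_rate` of entries, chosen uniformly at
#' random, is set missing. Deterministic given `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return An unoriented [genotype_matrix()].
#' @export
simulate_genotypes <- function(params) {
  if (!inherits(params, "sim_params")) {
    stop_selfgp("`params` must come from sim_params().", "selfgp_error_config")
  }
  withr::with_seed(params$seed, {
    n <- params$n_animals
    m <- params$n_markers
    p <- runif(m, params$maf_range[1], params$maf_range[2])
    vals <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    if (params$missing_rate > 0) {
      vals[runif(n * m) < params$missing_rate] <- NA_integer_
    }
    genotype_matrix(vals,
                    animal_ids = sprintf("A%05d", seq_len(n)),
                    marker_ids = sprintf("M%06d", seq_len(m)))
  })
}

# expected-allele-count imputation + column centering used for true breeding
# values (round-half-up of 2p, matching impute_missing, then mean-centering)
impute_center <- function(v) {
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0)) {
    stop_selfgp("Cannot impute markers with all genotypes missing.", "selfgp_error_config")
  }
  p <- colSums(v, na.rm = TRUE) / (2 * n_obs)
  fill <- round_half_up(2 * p)
  for (j in which(colSums(is.na(v)) > 0)) {
    v[is.na(v[, j]), j] <- fill[j]
  }
  sweep(v, 2, colMeans(v))
}

#' True additive breeding values of a genotype matrix
#'
#' Multiplies the imputed, column-centered allele counts by per-marker
#' additive effects. This is the definition used for the simulator's ground
#' truth, exposed so tests and users can verify it independently.
#'
#' @param G A [genotype_matrix()].
#' @param effects Numeric vector of per-marker additive effects (length
#'   `ncol(G)`).
#' @return Named numeric vector of breeding values, one per animal.
#' @export
breeding_values <- function(G, effects) {
  stopifnot(is_geno_matrix(G), length(effects) == ncol(G))
  Z <- impute_center(gm_values(G))
  setNames(as.numeric(Z %*% effects), animal_ids(G))
}

#' Simulate phenotypes, covariates and birth dates for a genotyped population
#'
#' Draws `n_qtl` additive QTL effects from a zero-mean Gaussian and rescales
#' them so the sample variance of breeding values is exactly
#' `heritability * total_deviation_variance`. Each animal gets a year-season
#' and parity-age level, a ration cohort, a permanent residual deviation and
#' a birth date; each animal-week gets days-in-milk, milk-energy and
#' metabolic-body-weight covariates plus week-to-week noise. Weekly
#' dry-matter intake is then
#' `mean + YSC + ParAge + b1*dim + b2*milk_e + b3*mbw + breeding value +
#' cohort effect + week residual`. The per-animal ground-truth RFI is the
#' genetic plus residual deviation (cohort effects excluded, as they are
#' absorbed by the mixed model's random effect).
#'
#' @param genotypes A [genotype_matrix()] with `nrow == params$n_animals`.
#' @param params A [sim_params()] object.
#' @return A `sim_population` list: `genotypes`, `true_effects`,
#'   `true_breeding_values`, `weekly_records` (tibble), `true_rfi` (tibble
#'   `animal_id, rfi`), `birth_dates` (tibble), `params`.
#' @export
simulate_phenotypes <- function(genotypes, params) {
  if (!inherits(params, "sim_params")) {
    stop_selfgp("`params` must come from sim_params().", "selfgp_error_config")
  }
  stopifnot(is_geno_matrix(genotypes))
  if (nrow(genotypes) != params$n_animals) {
    stop_selfgp(sprintf("Genotype matrix has %d animals but params$n_animals = %d.",
                        nrow(genotypes), params$n_animals), "selfgp_error_config")
  }
  n <- params$n_animals
  nw <- params$n_weeks_per_animal
  V <- params$total_deviation_variance
  h2 <- params$heritability
  cf <- params$cohort_variance_fraction
  rf <- max(0, 1 - h2 - cf) # residual fraction of the per-animal deviation variance
  mags <- params$fixed_effect_magnitudes

  withr::with_seed(params$seed + 1L, {
    m <- ncol(genotypes)
    qtl <- sort(sample.int(m, params$n_qtl))
    effects <- numeric(m)
    effects[qtl] <- rnorm(params$n_qtl)
    bv_raw <- breeding_values(genotypes, effects)
    s_raw <- sd(bv_raw)
    if (s_raw == 0) {
      stop_selfgp("Breeding values are constant (monomorphic QTL); increase n_qtl or MAF.",
                  "selfgp_error_config")
    }
    scale_f <- sqrt(h2 * V) / s_raw
    effects <- effects * scale_f
    bv <- bv_raw * scale_f

    # animal-level structure
    ysc_levels <- sprintf("YSC%02d", seq_len(params$n_ysc_levels))
    par_levels <- sprintf("PA%02d", seq_len(params$n_par_age_levels))
    ration_levels <- sprintf("R%03d", seq_len(params$n_cohorts))
    ysc_eff <- rnorm(params$n_ysc_levels, 0, mags$ysc)
    par_eff <- rnorm(params$n_par_age_levels, 0, mags$par_age)
    cohort_eff <- rnorm(params$n_cohorts, 0, sqrt(cf * V))
    a_ysc <- sample(params$n_ysc_levels, n, replace = TRUE)
    a_par <- sample(params$n_par_age_levels, n, replace = TRUE)
    a_ration <- sample(params$n_cohorts, n, replace = TRUE)

    # residual split: permanent animal deviation + weekly noise, chosen so the
    # variance of the per-animal mean residual is exactly rf * V
    sigma2_week <- params$week_noise_fraction * rf * V
    sigma2_perm <- rf * V - sigma2_week / nw
    d_animal <- rnorm(n, 0, sqrt(sigma2_perm))
    eta <- matrix(rnorm(n * nw, 0, sqrt(sigma2_week)), n, nw)

    # birth dates: test_fraction of animals born on/after the split date
    n_test <- round(params$test_fraction * n)
    idx_test <- if (n_test > 0) sample.int(n, n_test) else integer(0)
    start <- as.Date(sprintf("%d-01-01", params$birth_year_range[1]))
    end <- as.Date(sprintf("%d-12-31", params$birth_year_range[2]))
    split <- params$split_date
    pre_span <- max(1L, as.integer(split - start))
    post_span <- max(1L, as.integer(end - split) + 1L)
    birth <- split - 1L - floor(runif(n) * pre_span)
    if (n_test > 0) {
      birth[idx_test] <- split + floor(runif(n_test) * post_span)
    }
    birth <- as.Date(birth, origin = "1970-01-01")

    # weekly covariates: dim midpoints over the 50-200 d window, animal-level
    # production baselines with weekly wobble
    week <- seq_len(nw)
    dim_base <- 50 + 7 * (week - 1) + 3
    milk_base <- rnorm(n, 30, 3)
    mbw_base <- rnorm(n, 128, 8)
    ids <- animal_ids(genotypes)
    rec <- tidyr::expand_grid(animal = seq_len(n), week = week)
    rec_dim <- dim_base[rec$week]
    rec_milk <- milk_base[rec$animal] + rnorm(nrow(rec), 0, 1)
    rec_mbw <- mbw_base[rec$animal] + rnorm(nrow(rec), 0, 1.5)
    dmi <- params$mean_dmi +
      ysc_eff[a_ysc[rec$animal]] + par_eff[a_par[rec$animal]] +
      mags$dim * rec_dim + mags$milk_e * rec_milk + mags$mbw * rec_mbw +
      bv[rec$animal] + cohort_eff[a_ration[rec$animal]] +
      d_animal[rec$animal] + eta[cbind(rec$animal, rec$week)]

    weekly_records <- tibble(
      animal_id = ids[rec$animal], week = as.integer(rec$week),
      dim = rec_dim, dmi = dmi, milk_e = rec_milk, mbw = rec_mbw,
      ysc = ysc_levels[a_ysc[rec$animal]],
      par_age = par_levels[a_par[rec$animal]],
      ration = ration_levels[a_ration[rec$animal]],
      birth_date = birth[rec$animal])

    true_rfi <- bv + d_animal + rowMeans(eta)

    structure(list(
      genotypes = genotypes,
      true_effects = setNames(effects, marker_ids(genotypes)),
      true_breeding_values = setNames(bv, ids),
      weekly_records = weekly_records,
      true_rfi = tibble(animal_id = ids, rfi = unname(true_rfi)),
      birth_dates = tibble(animal_id = ids, birth_date = birth),
      params = params), class = "sim_population")
  })
}

#' Simulate a complete population in one call
#'
#' Runs [simulate_genotypes()] then [simulate_phenotypes()].
#'
#' @param params A [sim_params()] object.
#' @return A `sim_population`; see [simulate_phenotypes()].
#' @export
simulate_population <- function(params) {
  simulate_phenotypes(simulate_genotypes(params), params)
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d animals, %d markers, h2 = %.2f, %d weekly records\n",
              nrow(x$genotypes), ncol(x$genotypes), x$params$heritability,
              nrow(x$weekly_records)))
  invisible(x)
}

#' Bundle genotypes and phenotypes for prediction
#'
#' A `prediction_set` pairs a fully imputed genotype matrix with a per-animal
#' phenotype table; it is the unit the experiment drivers sample from.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes Tibble with columns `animal_id` and `rfi` covering every
#'   animal in `genotypes` (extra animals are dropped).
#' @return A `prediction_set` list with aligned `genotypes` and `phenotypes`.
#' @export
prediction_set <- function(genotypes, phenotypes) {
  stopifnot(is_geno_matrix(genotypes), is.data.frame(phenotypes))
  v <- align_phenotypes(phenotypes, animal_ids(genotypes))
  structure(list(genotypes = genotypes,
                 phenotypes = tibble(animal_id = animal_ids(genotypes), rfi = v)),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d animals x %d markers\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

#' Split a simulated population by birth date
#'
#' Animals born strictly before `split_date` form the training pool; animals
#' born on or after it form the test set — the standard forward-prediction
#' design where historical animals predict younger selection candidates. The
#' partition is exhaustive and disjoint, and both sides must be non-empty.
#' Phenotypes attached to each side are the simulator's per-animal RFI ground
#' truth; substitute mixed-model-derived phenotypes (see [fit_rfi_model()])
#' to exercise the full pipeline.
#'
#' @param population A `sim_population` from [simulate_phenotypes()].
#' @param split_date Date; defaults to the population's configured split.
#' @return A list with `train` and `test` [prediction_set()] objects.
#' @export
make_split <- function(population, split_date = population$params$split_date) {
  stopifnot(inherits(population, "sim_population"))
  split_date <- as.Date(split_date)
  bd <- population$birth_dates
  train_ids <- bd$animal_id[bd$birth_date < split_date]
  test_ids <- bd$animal_id[bd$birth_date >= split_date]
  if (length(train_ids) == 0) {
    stop_selfgp("Empty training pool: no animal born before the split date.",
                "selfgp_error_split")
  }
  if (length(test_ids) == 0) {
    stop_selfgp("Empty test set: no animal born on/after the split date.",
                "selfgp_error_split")
  }
  phen <- population$true_rfi
  list(
    train = prediction_set(gm_subset(population$genotypes, animals = train_ids),
                           phen[phen$animal_id %in% train_ids, ]),
    test = prediction_set(gm_subset(population$genotypes, animals = test_ids),
                          phen[phen$animal_id %in% test_ids, ]))
}
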