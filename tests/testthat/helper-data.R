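# shared fixtures built in code

# small fully-typed genotype matrix from explicit entries (animals x markers)
gm_from <- function(entries, n_animals, oriented = FALSE) {
  m <- matrix(as.integer(entries), nrow = n_animals)
  genotype_matrix(m,
                  animal_ids = sprintf("a%02d", seq_len(n_animals)),
                  marker_ids = sprintf("m%02d", seq_len(ncol(m))),
                  oriented_minor = oriented)
}

# a small simulated population without missing genotypes
quick_pop <- function(n = 120, m = 80, seed = 1, h2 = 0.15, ...) {
  simulate_population(sim_params(n_animals = n, n_markers = m,
                                 n_qtl = min(30, m), heritability = h2,
                                 missing_rate = 0, seed = seed, ...))
}

# weekly records drawn directly under the RFI mixed model (independent
# records, unlike the population simulator where cohorts follow animals);
# used for variance-component recovery oracles
simulate_mm_records <- function(n_cohorts = 80, per_cohort = 10,
                                sigma2_r = 0.25, sigma2_e = 1,
                                beta = c(dim = 0.01, milk_e = 0.4, mbw = 0.02),
                                n_ysc = 4, n_par = 4, mu = 20, seed = 1) {
  withr::with_seed(seed, {
    n <- n_cohorts * per_cohort
    ration <- rep(sprintf("R%03d", seq_len(n_cohorts)), each = per_cohort)
    u <- rep(rnorm(n_cohorts, 0, sqrt(sigma2_r)), each = per_cohort)
    ysc_lev <- sprintf("Y%02d", seq_len(n_ysc))
    par_lev <- sprintf("P%02d", seq_len(n_par))
    ysc <- sample(ysc_lev, n, replace = TRUE)
    par_age <- sample(par_lev, n, replace = TRUE)
    ysc_eff <- setNames(rnorm(n_ysc, 0, 0.5), ysc_lev)
    par_eff <- setNames(rnorm(n_par, 0, 0.5), par_lev)
    dim <- runif(n, 50, 200)
    milk_e <- rnorm(n, 30, 3)
    mbw <- rnorm(n, 128, 8)
    dmi <- mu + ysc_eff[ysc] + par_eff[par_age] +
      beta["dim"] * dim + beta["milk_e"] * milk_e + beta["mbw"] * mbw +
      u + rnorm(n, 0, sqrt(sigma2_e))
    tibble::tibble(animal_id = sprintf("an%05d", seq_len(n)),
                   week = 1L, dim = dim, dmi = as.numeric(dmi),
                   milk_e = milk_e, mbw = mbw, ysc = ysc,
                   par_age = par_age, ration = ration)
  })
}

# brute-force per-column QC oracle used by the acceptance suite: frequency
# counting, strict <, round-half-up imputation, written independently of the
# package's vectorized implementations
qc_oracle <- function(vals, threshold) {
  n_col <- ncol(vals)
  freq <- numeric(n_col)
  oriented <- vals
  for (j in seq_len(n_col)) {
    col <- vals[, j]
    obs <- col[!is.na(col)]
    f <- if (length(obs) == 0) NA_real_ else sum(obs) / (2 * length(obs))
    if (!is.na(f) && f > 0.5) {
      col[!is.na(col)] <- 2 - col[!is.na(col)]
      f <- 1 - f
    }
    oriented[, j] <- col
    freq[j] <- f
  }
  keep <- !is.na(freq) & freq >= threshold
  out <- oriented[, keep, drop = FALSE]
  fk <- freq[keep]
  for (j in seq_len(ncol(out))) {
    miss <- is.na(out[, j])
    if (any(miss)) out[miss, j] <- as.integer(floor(2 * fk[j] + 0.5))
  }
  storage.mode(out) <- "integer"
  list(kept = which(keep), imputed = out)
}
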