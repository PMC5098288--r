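#' Per-marker allele frequencies
#'
#' Computes, for every marker, the frequency of the counted allele over the
#' non-missing genotypes: `sum(genotypes) / (2 * n_obs)`. Markers with no
#' non-missing entries get `freq = NA` and are flagged rather than silently
#' assigned a value; downstream filters treat them as removable.
#'
#' @param G A [genotype_matrix()].
#' @return A tibble with columns `marker_id`, `n_obs` (non-missing count),
#'   `freq` (counted-allele frequency, `NA` when `n_obs == 0`) and
#'   `all_missing`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L), 4, 1,
#'                      dimnames = list(paste0("a", 1:4), "m1")))
#' compute_allele_frequencies(g) # freq = 5/8
#' @export
compute_allele_frequencies <- function(G) {
  stopifnot(is_geno_matrix(G))
  v <- gm_values(G)
  n_obs <- colSums(!is.na(v))
  total <- colSums(v, na.rm = TRUE)
  freq <- ifelse(n_obs > 0, total / (2 * n_obs), NA_real_)
  tibble(marker_id = colnames(v), n_obs = as.integer(n_obs),
         freq = as.numeric(freq), all_missing = n_obs == 0L)
}

#' Re-orient genotypes to count the minor allele
#'
#' For every marker whose counted-allele frequency exceeds 0.5, genotypes are
#' flipped `g -> 2 - g` (missing entries stay missing) so that each marker
#' counts copies of its minor allele. A frequency of exactly 0.5 is left
#' unflipped. The per-marker heterozygote count is unchanged by construction.
#'
#' @param G A [genotype_matrix()].
#' @return The re-oriented [genotype_matrix()] with `oriented_minor = TRUE`.
#' @export
recode_minor_allele <- function(G) {
  stopifnot(is_geno_matrix(G))
  v <- gm_values(G)
  af <- compute_allele_frequencies(G)
  flip <- !is.na(af$freq) & af$freq > 0.5
  if (any(flip)) {
    v[, flip] <- 2L - v[, flip, drop = FALSE]
  }
  genotype_matrix(v, oriented_minor = TRUE)
}

#' Remove markers with low minor-allele frequency
#'
#' Drops every marker whose minor-allele frequency is strictly below
#' `threshold` (the conventional 5% cut by default), plus any marker with all
#' genotypes missing. Frequencies are computed over non-missing entries, i.e.
#' before any imputation, so imputed values cannot feed back into the filter.
#' Survivor order is preserved and the removal count is reported via a
#' message.
#'
#' @param G A minor-allele-oriented [genotype_matrix()] (run
#'   [recode_minor_allele()] first).
#' @param threshold Minimum minor-allele frequency in `[0, 0.5]`; markers with
#'   `freq < threshold` are removed (strict inequality, so a marker exactly at
#'   the threshold is retained).
#' @return The filtered [genotype_matrix()].
#' @export
filter_maf <- function(G, threshold = 0.05) {
  stopifnot(is_geno_matrix(G))
  if (!is_oriented_minor(G)) {
    stop_selfgp("filter_maf() requires a minor-allele-oriented matrix; run recode_minor_allele() first.",
                "selfgp_error_qc")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 0.5) {
    stop_selfgp("`threshold` must be a single value in [0, 0.5].", "selfgp_error_qc")
  }
  af <- compute_allele_frequencies(G)
  drop <- af$all_missing | (!is.na(af$freq) & af$freq < threshold)
  message(sprintf("filter_maf: removed %d of %d markers (MAF < %g or all missing); %d retained.",
                  sum(drop), nrow(af), threshold, sum(!drop)))
  gm_subsetted <- gm_subset(G, markers = which(!drop))
  gm_subsetted
}

#' Impute missing genotypes from rounded allele frequencies
#'
#' Replaces every missing genotype at marker *j* with `round(2 * p_j)` where
#' `p_j` is the minor-allele frequency — the expected allele count rounded to
#' the nearest integer, with halves (2p = 0.5 or 1.5) rounding up. By default
#' frequencies are computed within the matrix itself; a frequency table from
#' an external reference population may be supplied instead.
#'
#' @param G A minor-allele-oriented [genotype_matrix()].
#' @param frequencies Optional tibble with columns `marker_id` and `freq`
#'   (e.g. from [compute_allele_frequencies()] on a reference panel). When
#'   `NULL`, frequencies are computed within `G`.
#' @return A [genotype_matrix()] with no missing entries; non-missing entries
#'   are untouched, and a matrix with no missing entries is returned
#'   unchanged.
#' @export
impute_missing <- function(G, frequencies = NULL) {
  stopifnot(is_geno_matrix(G))
  if (!is_oriented_minor(G)) {
    stop_selfgp("impute_missing() requires a minor-allele-oriented matrix; run recode_minor_allele() first.",
                "selfgp_error_qc")
  }
  v <- gm_values(G)
  if (!anyNA(v)) return(G)
  if (is.null(frequencies)) {
    af <- compute_allele_frequencies(G)
    if (any(af$all_missing)) {
      stop_selfgp(sprintf(
        "%d marker(s) have all genotypes missing and no external frequency was supplied; run filter_maf() first or provide `frequencies`.",
        sum(af$all_missing)), "selfgp_error_qc")
    }
    p <- setNames(af$freq, af$marker_id)
  } else {
    if (!all(c("marker_id", "freq") %in% names(frequencies))) {
      stop_selfgp("`frequencies` must have columns marker_id and freq.", "selfgp_error_qc")
    }
    missing_markers <- setdiff(colnames(v), frequencies$marker_id)
    if (length(missing_markers) > 0) {
      stop_selfgp(sprintf("`frequencies` lacks %d marker(s), e.g. %s.",
                          length(missing_markers),
                          paste(head(missing_markers, 3), collapse = ", ")),
                  "selfgp_error_qc")
    }
    p <- setNames(frequencies$freq, frequencies$marker_id)[colnames(v)]
  }
  fill <- as.integer(round_half_up(2 * p))
  for (j in which(colSums(is.na(v)) > 0)) {
    v[is.na(v[, j]), j] <- fill[j]
  }
  genotype_matrix(v, oriented_minor = TRUE)
}

#' Full genotype quality control pipeline
#'
#' Convenience wrapper running the fixed QC order: orient to the minor allele,
#' remove low-MAF and all-missing markers, then impute the remaining missing
#' genotypes from rounded allele frequencies.
#'
#' @inheritParams filter_maf
#' @inheritParams impute_missing
#' @return A list with `genotypes` (the clean [genotype_matrix()], fully
#'   imputed and minor-allele oriented) and `report` (a one-row tibble:
#'   markers in/out, missing rate before QC, number of imputed entries).
#' @export
qc_genotypes <- function(G, threshold = 0.05, frequencies = NULL) {
  stopifnot(is_geno_matrix(G))
  n_in <- ncol(G)
  missing_rate <- mean(is.na(gm_values(G)))
  G1 <- recode_minor_allele(G)
  G2 <- filter_maf(G1, threshold)
  n_imputed <- sum(is.na(gm_values(G2)))
  G3 <- impute_missing(G2, frequencies = frequencies)
  list(genotypes = G3,
       report = tibble(markers_in = n_in, markers_out = ncol(G3),
                       markers_removed = n_in - ncol(G3),
                       missing_rate = missing_rate,
                       n_imputed = as.integer(n_imputed)))
}
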