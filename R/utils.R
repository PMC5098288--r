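#' Deterministic per-replicate random seed streams
#'
#' Derives an independent, reproducible seed for a named unit of work (for
#' example one replicate of one experimental setting) from a master seed and a
#' string label. Every sampling step in the experiment drivers draws its seed
#' through this function, so any single replicate of any setting can be
#' re-executed in isolation and bit-identically.
#'
#' @param master_seed Integer master seed for the whole run.
#' @param label Character scalar naming the unit of work, e.g.
#'   `"learning_curve:n=100:rep=7"`.
#' @return A single integer seed in `[1, 2^31 - 20]`.
#' @examples
#' stream_seed(42, "learning_curve:n=100:rep=7")
#' @export
stream_seed <- function(master_seed, label) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed), length(label) == 1)
  m <- 2147483629 # largest prime < 2^31; keeps products < 2^53
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% m
  }
  # two extra mixing rounds so labels differing in a trailing digit decorrelate
  h <- (h * 69069 + 1) %% m
  h <- (h * 69069 + 1) %% m
  as.integer(h %% (m - 1)) + 1L
}

# round-half-up to the nearest integer (0.5 -> 1, 1.5 -> 2)
round_half_up <- function(x) floor(x + 0.5)

# abort with a class so callers/tests can match on condition type
stop_selfgp <- function(message, class) {
  abort(message, class = c(class, "selfgp_error"))
}

# coerce a phenotype argument (tibble with animal_id + one numeric column, or
# a numeric vector, optionally named) into a numeric vector aligned with
# `animal_ids`. Errors if animals are missing.
align_phenotypes <- function(phenotypes, animal_ids, arg = "phenotypes") {
  if (is.data.frame(phenotypes)) {
    if (!"animal_id" %in% names(phenotypes)) {
      stop_selfgp(sprintf("`%s` data frame must have an `animal_id` column.", arg),
                  "selfgp_error_phenotypes")
    }
    value_cols <- setdiff(names(phenotypes), "animal_id")
    num <- value_cols[vapply(phenotypes[value_cols], is.numeric, logical(1))]
    if (length(num) < 1) {
      stop_selfgp(sprintf("`%s` must contain a numeric phenotype column.", arg),
                  "selfgp_error_phenotypes")
    }
    v <- setNames(phenotypes[[num[1]]], phenotypes$animal_id)
    missing <- setdiff(animal_ids, names(v))
    if (length(missing) > 0) {
      stop_selfgp(sprintf("`%s` lacks phenotypes for %d animal(s): %s",
                          arg, length(missing),
                          paste(head(missing, 5), collapse = ", ")),
                  "selfgp_error_phenotypes")
    }
    return(unname(v[animal_ids]))
  }
  v <- phenotypes
  if (!is.numeric(v)) {
    stop_selfgp(sprintf("`%s` must be numeric or a data frame.", arg),
                "selfgp_error_phenotypes")
  }
  if (!is.null(names(v))) {
    missing <- setdiff(animal_ids, names(v))
    if (length(missing) > 0) {
      stop_selfgp(sprintf("`%s` lacks phenotypes for %d animal(s).", arg, length(missing)),
                  "selfgp_error_phenotypes")
    }
    return(unname(v[animal_ids]))
  }
  if (length(v) != length(animal_ids)) {
    stop_selfgp(sprintf("`%s` has length %d but there are %d animals.",
                        arg, length(v), length(animal_ids)),
                "selfgp_error_phenotypes")
  }
  v
}
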