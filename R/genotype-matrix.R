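#' Construct a genotype matrix
#'
#' The central marker-data container: an animals-by-markers matrix of allele
#' counts coded 0/1/2 (number of copies of the counted allele) with `NA` for
#' missing genotypes. After [recode_minor_allele()] the counted allele is the
#' minor allele at every marker and the object carries `oriented_minor = TRUE`.
#'
#' @param values Integer or numeric matrix; entries must be 0, 1, 2, or `NA`.
#' @param animal_ids Character vector of unique animal identifiers (defaults to
#'   the matrix rownames).
#' @param marker_ids Character vector of unique marker identifiers (defaults to
#'   the matrix colnames).
#' @param oriented_minor Logical; `TRUE` only if every marker already counts
#'   its minor allele (set by [recode_minor_allele()]).
#' @return A `geno_matrix` object: an integer matrix with animal row names,
#'   marker column names and an `oriented_minor` attribute.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                      animal_ids = c("a1", "a2"),
#'                      marker_ids = c("m1", "m2"))
#' dim(g)
#' @export
genotype_matrix <- function(values, animal_ids = rownames(values),
                            marker_ids = colnames(values),
                            oriented_minor = FALSE) {
  if (!is.matrix(values)) {
    stop_selfgp("`values` must be a matrix.", "selfgp_error_genotype")
  }
  if (is.null(animal_ids) && nrow(values) == 0) animal_ids <- character(0)
  if (is.null(marker_ids) && ncol(values) == 0) marker_ids <- character(0)
  if (is.null(animal_ids) || is.null(marker_ids)) {
    stop_selfgp("animal_ids and marker_ids are required (dimnames or arguments).",
                "selfgp_error_genotype")
  }
  animal_ids <- as.character(animal_ids)
  marker_ids <- as.character(marker_ids)
  if (length(animal_ids) != nrow(values) || length(marker_ids) != ncol(values)) {
    stop_selfgp("ID lengths do not match matrix dimensions.", "selfgp_error_genotype")
  }
  if (anyDuplicated(animal_ids)) {
    stop_selfgp("Duplicate animal_ids are not allowed.", "selfgp_error_genotype")
  }
  if (anyDuplicated(marker_ids)) {
    stop_selfgp("Duplicate marker_ids are not allowed.", "selfgp_error_genotype")
  }
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_selfgp(sprintf("Invalid genotype value %s at row %d (animal %s), column %d (marker %s); entries must be 0, 1, 2 or NA.",
                        format(values[bad][1]), idx[1], animal_ids[idx[1]],
                        idx[2], marker_ids[idx[2]]),
                "selfgp_error_genotype")
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(animal_ids, marker_ids)
  structure(values, class = c("geno_matrix", "matrix", "array"),
            oriented_minor = isTRUE(oriented_minor))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d markers (%.1f%% missing, %s)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x)),
              if (is_oriented_minor(x)) "minor-allele oriented" else "unoriented"))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x,G A `geno_matrix`.
#' @export
is_geno_matrix <- function(x) inherits(x, "geno_matrix")

#' @rdname genotype_matrix
#' @export
is_oriented_minor <- function(G) isTRUE(attr(G, "oriented_minor"))

#' @rdname genotype_matrix
#' @export
animal_ids <- function(G) rownames(G)

#' @rdname genotype_matrix
#' @export
marker_ids <- function(G) colnames(G)

# raw integer matrix without the class/attribute baggage
gm_values <- function(G) {
  v <- unclass(G)
  attr(v, "oriented_minor") <- NULL
  v
}

#' Subset a genotype matrix by animal and/or marker identifiers
#'
#' @param G A `geno_matrix`.
#' @param animals,markers Character vectors of identifiers (or integer
#'   indices) to keep, in the requested order; `NULL` keeps all.
#' @return A `geno_matrix` with the same `oriented_minor` flag.
#' @export
gm_subset <- function(G, animals = NULL, markers = NULL) {
  stopifnot(is_geno_matrix(G))
  v <- gm_values(G)
  if (!is.null(animals)) {
    if (is.character(animals) && !all(animals %in% rownames(v))) {
      stop_selfgp("Unknown animal_ids in subset.", "selfgp_error_genotype")
    }
    v <- v[animals, , drop = FALSE]
  }
  if (!is.null(markers)) {
    if (is.character(markers) && !all(markers %in% colnames(v))) {
      stop_selfgp("Unknown marker_ids in subset.", "selfgp_error_genotype")
    }
    v <- v[, markers, drop = FALSE]
  }
  genotype_matrix(v, oriented_minor = is_oriented_minor(G))
}

#' Stack two genotype matrices over the same markers
#'
#' Row-binds the animals of `G1` and `G2` after normalising `G2`'s marker
#' order to `G1`'s. Animal identifiers must be disjoint and marker sets equal.
#'
#' @param G1,G2 `geno_matrix` objects over identical marker sets.
#' @return A `geno_matrix`; oriented-minor only if both inputs are.
#' @export
gm_rbind <- function(G1, G2) {
  stopifnot(is_geno_matrix(G1), is_geno_matrix(G2))
  if (nrow(G2) == 0) return(G1)
  if (nrow(G1) == 0) return(G2)
  check_same_markers(marker_ids(G1), marker_ids(G2))
  overlap <- intersect(animal_ids(G1), animal_ids(G2))
  if (length(overlap) > 0) {
    stop_selfgp(sprintf("Animal IDs occur in both matrices: %s",
                        paste(head(overlap, 5), collapse = ", ")),
                "selfgp_error_genotype")
  }
  v <- rbind(gm_values(G1), gm_values(G2)[, marker_ids(G1), drop = FALSE])
  genotype_matrix(v, oriented_minor = is_oriented_minor(G1) && is_oriented_minor(G2))
}

check_same_markers <- function(ref, new) {
  missing <- setdiff(ref, new)
  extra <- setdiff(new, ref)
  if (length(missing) > 0 || length(extra) > 0) {
    stop_selfgp(sprintf(
      "Marker sets differ: %d missing (%s), %d extra (%s).",
      length(missing), paste(head(missing, 5), collapse = ", "),
      length(extra), paste(head(extra, 5), collapse = ", ")),
      "selfgp_error_markers")
  }
  invisible(TRUE)
}
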