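#' Read a genotype matrix from TSV or VCF
#'
#' Two on-disk formats are supported:
#'
#' * **tsv** — the package's genotype dialect: UTF-8, tab-separated, Unix
#'   newlines, header `animal_id<TAB><marker>...`, one row per animal and one
#'   column per marker with entries `0`, `1`, `2` or `NA`.
#' * **vcf** — standard VCF 4.x. Only biallelic SNP records are used; the GT
#'   field is converted to an ALT-allele count (`0/0 -> 0`, `0/1` or `1/0 ->
#'   1`, `1/1 -> 2`, `./.` -> missing). Multi-allelic records are skipped with
#'   a warning reporting their count. The counted allele is the ALT allele
#'   until [recode_minor_allele()] re-orients the matrix.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()] with `oriented_minor = FALSE`.
#' @seealso [write_genotypes()] for the inverse of the TSV reader.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_selfgp(sprintf("File not found: %s", path), "selfgp_error_io")
  }
  switch(format, tsv = read_genotypes_tsv(path), vcf = read_genotypes_vcf(path))
}

read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  if (names(df)[1] != "animal_id") {
    stop_selfgp("First column of a genotype TSV must be `animal_id`.", "selfgp_error_io")
  }
  ids <- df$animal_id
  markers <- names(df)[-1]
  raw <- as.matrix(df[, -1, drop = FALSE])
  ok <- raw %in% c("0", "1", "2", "NA")
  if (!all(ok)) {
    idx <- which(matrix(!ok, nrow(raw)), arr.ind = TRUE)[1, ]
    stop_selfgp(sprintf("Malformed genotype entry '%s' at data row %d, marker %s (expected 0/1/2/NA).",
                        raw[!ok][1], idx[1], markers[idx[2]]),
                "selfgp_error_io")
  }
  vals <- matrix(suppressWarnings(as.integer(raw)), nrow(raw), ncol(raw))
  genotype_matrix(vals, animal_ids = ids, marker_ids = markers)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  n_skip <- sum(!bi)
  if (n_skip > 0) {
    warn(sprintf("Skipped %d multi-allelic VCF record(s); only biallelic SNPs are used.", n_skip))
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  fallback <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  ids <- ifelse(is.na(ids) | ids == ".", fallback, ids)
  # normalise phased separators and count ALT alleles
  core <- sub(":.*$", "", gt)
  core <- gsub("|", "/", core, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(core), ncol(core))
  code[core %in% c("0/0")] <- 0L
  code[core %in% c("0/1", "1/0")] <- 1L
  code[core %in% c("1/1")] <- 2L
  unknown <- !is.na(core) & !(core %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(unknown)) {
    stop_selfgp(sprintf("Unsupported GT value '%s' in VCF (biallelic 0/1 calls only).",
                        core[unknown][1]),
                "selfgp_error_io")
  }
  genotype_matrix(t(code), animal_ids = colnames(gt), marker_ids = ids)
}

#' Write a genotype matrix in the TSV dialect
#'
#' Writes the exact dialect [read_genotypes()] reads: tab-separated, header
#' `animal_id` then one column per marker, entries `0|1|2|NA`, Unix newlines.
#' A write/read round trip reproduces the matrix bit-identically (up to the
#' `oriented_minor` flag, which is not stored on disk).
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(is_geno_matrix(G))
  v <- gm_values(G)
  chr <- matrix(as.character(v), nrow(v))
  chr[is.na(chr)] <- "NA"
  lines <- c(paste(c("animal_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)),
                    function(i) paste(c(rownames(v)[i], chr[i, ]), collapse = "\t"),
                    character(1)))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read weekly feed-intake records
#'
#' Reads the weekly-record CSV consumed by [fit_rfi_model()]: columns
#' `animal_id, week, dim, dmi, milk_e, mbw, ysc, par_age, ration, birth_date`
#' (birth_date optional; it is carried through for train/test splitting only).
#'
#' @param path Path to the CSV file.
#' @return A tibble of weekly records.
#' @export
read_weekly_records <- function(path) {
  if (!file.exists(path)) {
    stop_selfgp(sprintf("File not found: %s", path), "selfgp_error_io")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    week = readr::col_integer(),
    dim = readr::col_double(),
    dmi = readr::col_double(),
    milk_e = readr::col_double(),
    mbw = readr::col_double(),
    ysc = readr::col_character(),
    par_age = readr::col_character(),
    ration = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  required <- c("animal_id", "week", "dim", "dmi", "milk_e", "mbw", "ysc", "par_age", "ration")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_selfgp(sprintf("Weekly-record file lacks column(s): %s",
                        paste(missing, collapse = ", ")), "selfgp_error_io")
  }
  df
}
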