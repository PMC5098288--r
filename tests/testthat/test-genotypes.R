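test_that("genotype matrices validate entries, ids and dimensions", {
  expect_s3_class(gm_from(c(0, 1, 2, NA, 0, 2), 2), "geno_matrix")
  expect_error(gm_from(c(0, 3, 1, 2), 2), class = "selfgp_error_genotype")
  expect_error(
    genotype_matrix(matrix(0L, 2, 2), animal_ids = c("a", "a"),
                    marker_ids = c("m1", "m2")),
    class = "selfgp_error_genotype")
  expect_error(
    genotype_matrix(matrix(0L, 2, 2), animal_ids = c("a", "b"),
                    marker_ids = c("m", "m")),
    class = "selfgp_error_genotype")
})

test_that("TSV round trip is bit-exact and malformed entries are located", {
  g <- gm_from(c(0, 1, 2, NA, 0, 2), 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, "tsv")
  expect_identical(gm_values(g2), gm_values(g))
  expect_equal(sum(is.na(g2)), 1)

  # round trip of a larger simulated matrix with missing entries
  G <- simulate_genotypes(sim_params(n_animals = 25, n_markers = 40,
                                     n_qtl = 10, missing_rate = 0.1, seed = 2))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(G, p2)
  expect_identical(gm_values(read_genotypes(p2, "tsv")), gm_values(G))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("animal_id\tm1\tm2", "a1\t0\t5"), bad)
  expect_error(read_genotypes(bad, "tsv"), "m2", class = "selfgp_error_io")
})

test_that("VCF genotypes map to ALT-allele counts and multi-allelics are skipped", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tcow1\tcow2",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.",
    "1\t300\tsnp3\tG\tA\t.\tPASS\t.\tGT\t1|0\t0|0",
    "1\t400\tsnp4\tT\tA,C\t.\tPASS\t.\tGT\t1/2\t0/0"), vcf)
  expect_warning(g <- read_genotypes(vcf, "vcf"), "multi-allelic")
  expect_equal(marker_ids(g), c("snp1", "snp2", "snp3"))
  expect_equal(animal_ids(g), c("cow1", "cow2"))
  expect_equal(unname(gm_values(g)["cow1", ]), c(0L, 2L, 1L))
  expect_equal(unname(gm_values(g)["cow2", ]), c(1L, NA, 0L))
})

test_that("allele frequencies are counted over non-missing entries", {
  g <- gm_from(c(0, 0, 0, 0,   0, 1, 2, 2,   1, NA, 1, NA), 4)
  af <- compute_allele_frequencies(g)
  expect_equal(af$freq, c(0, 5 / 8, 0.5))
  expect_equal(af$n_obs, c(4L, 4L, 2L))
  g_allmiss <- gm_from(c(NA, NA, 0, 1), 2)
  af2 <- compute_allele_frequencies(g_allmiss)
  expect_true(af2$all_missing[1])
  expect_true(is.na(af2$freq[1]))
})

test_that("minor-allele recoding flips high-frequency markers and is an involution", {
  g <- gm_from(c(2, 2, 2, 1,   0, 1, 0, 0), 4)
  r <- recode_minor_allele(g)
  expect_true(is_oriented_minor(r))
  expect_equal(unname(gm_values(r)[, 1]), c(0L, 0L, 0L, 1L)) # freq 7/8 flipped
  expect_equal(unname(gm_values(r)[, 2]), c(0L, 1L, 0L, 0L)) # already minor
  expect_identical(gm_values(recode_minor_allele(r)), gm_values(r))
  # heterozygote counts are preserved per marker
  expect_equal(colSums(gm_values(r) == 1, na.rm = TRUE),
               colSums(gm_values(g) == 1, na.rm = TRUE))
  # exact 0.5 left unflipped
  g5 <- gm_from(c(0, 2, 1, 1), 4)
  expect_identical(gm_values(recode_minor_allele(g5)), gm_values(g5))
  # after orientation every column mean is at most 1
  G <- recode_minor_allele(simulate_genotypes(
    sim_params(n_animals = 60, n_markers = 50, n_qtl = 10,
               maf_range = c(0.2, 0.5), missing_rate = 0.05, seed = 5)))
  expect_true(all(colMeans(gm_values(G), na.rm = TRUE) <= 1 + 1e-12))
})

test_that("MAF filter removes strictly-below-threshold and all-missing markers", {
  # freqs: 0.04 (removed), 0.05 (retained, strict <), 0.5, all-missing
  vals <- cbind(c(rep(0L, 46), rep(1L, 4)),
                c(rep(0L, 45), rep(1L, 5)),
                rep(1L, 50),
                rep(NA_integer_, 50))
  g <- genotype_matrix(vals, animal_ids = sprintf("a%02d", 1:50),
                       marker_ids = c("low", "at", "high", "gone"),
                       oriented_minor = TRUE)
  expect_message(f <- filter_maf(g, 0.05), "removed 2 of 4")
  expect_equal(marker_ids(f), c("at", "high"))
  # threshold 0 removes only the all-missing marker
  expect_message(f0 <- filter_maf(g, 0), "removed 1 of 4")
  expect_equal(marker_ids(f0), c("low", "at", "high"))
  expect_error(filter_maf(g, 0.6), class = "selfgp_error_qc")
  expect_error(filter_maf(gm_from(c(0, 1), 2), 0.05), class = "selfgp_error_qc")
  # survivors all have freq >= threshold
  af <- compute_allele_frequencies(f)
  expect_true(all(af$freq >= 0.05))
})

test_that("imputation fills round(2p) with halves rounding up", {
  # p = 0.10 -> 0; p = 0.40 -> 1; p = 0.25 (2p = 0.5, tie) -> 1
  vals <- cbind(c(0L, 0L, 0L, 0L, 1L, rep(0L, 4), NA),
                c(1L, 1L, 1L, 1L, 0L, rep(1L, 4), NA),
                c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, NA, NA))
  g <- genotype_matrix(vals, animal_ids = sprintf("a%02d", 1:10),
                       marker_ids = c("p10", "p40", "p25"),
                       oriented_minor = TRUE)
  imp <- impute_missing(g)
  expect_equal(unname(gm_values(imp)[10, c("p10", "p40")]), c(0L, 1L))
  expect_equal(unname(gm_values(imp)[9:10, "p25"]), c(1L, 1L))
  expect_false(anyNA(imp))
  # non-missing entries untouched
  expect_identical(gm_values(imp)[!is.na(vals)], vals[!is.na(vals)])
  # complete matrix returned unchanged
  cm <- gm_from(c(0, 1, 2, 0), 2, oriented = TRUE)
  expect_identical(impute_missing(cm), cm)
  # all-missing marker without external frequencies is an error
  gm_bad <- genotype_matrix(cbind(c(0L, 1L), c(NA, NA)),
                            animal_ids = c("a", "b"), marker_ids = c("m", "x"),
                            oriented_minor = TRUE)
  expect_error(impute_missing(gm_bad), "filter", class = "selfgp_error_qc")
  # external reference frequencies override within-data frequencies
  ext <- tibble::tibble(marker_id = c("p10", "p40", "p25"), freq = c(0.45, 0.45, 0.45))
  imp2 <- impute_missing(g, frequencies = ext)
  expect_equal(unname(gm_values(imp2)[10, "p10"]), 1L)
})

test_that("the QC pipeline is idempotent", {
  G <- simulate_genotypes(sim_params(n_animals = 80, n_markers = 120, n_qtl = 10,
                                     maf_range = c(0.02, 0.5),
                                     missing_rate = 0.1, seed = 7))
  once <- suppressMessages(qc_genotypes(G))$genotypes
  twice <- suppressMessages(qc_genotypes(once))$genotypes
  expect_identical(gm_values(twice), gm_values(once))
  expect_false(anyNA(once))
  expect_true(all(gm_values(once) %in% 0:2))
})
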