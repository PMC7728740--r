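test_that("delimited genotype tables parse, flag missing cells, and reject bad dosages", {
  f <- write_genotype_table_file(matrix(c(0, 1, 2, 2, 1, 0), 2, 3,
                                        dimnames = list(NULL, c("m1", "m2", "m3"))))
  g <- read_genotypes(f, "table")
  expect_s3_class(g, "GenotypeMatrix")
  expect_equal(dim(g), c(2L, 3L))
  expect_equal(g$marker_ids, c("m1", "m2", "m3"))

  m <- matrix(c(0, 1, NA, 2, 1, 0), 2, 3,
              dimnames = list(NULL, c("m1", "m2", "m3")))
  g2 <- read_genotypes(write_genotype_table_file(m), "table")
  expect_true(is.na(g2$dosage[1, 2]))
  # allele_freq from the remaining entry (dosage 2) of column 2 only
  expect_equal(unname(g2$allele_freq[2]), 1)

  mbad <- matrix(c(0, 1, 3, 2, 1, 0), 2, 3,
                 dimnames = list(NULL, c("m1", "m2", "m3")))
  expect_error(read_genotypes(write_genotype_table_file(mbad), "table"),
               "outside")
})

test_that("genotype table write -> read round-trip is exact", {
  G <- small_panel(15, 12, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_genotypes(G, f)
  G2 <- read_genotypes(f, "table")
  expect_identical(G2$dosage, G$dosage)
  expect_identical(G2$sample_ids, G$sample_ids)
  expect_equal(G2$allele_freq, G$allele_freq)
})

test_that("PLINK .raw input skips the six metadata columns", {
  G <- small_panel(8, 5, seed = 4)
  f <- tempfile(fileext = ".raw")
  df <- data.frame(FID = paste0("F", 1:8), IID = G$sample_ids,
                   PAT = 0, MAT = 0, SEX = 1, PHENOTYPE = -9,
                   G$dosage, check.names = FALSE)
  utils::write.table(df, f, sep = " ", quote = FALSE, row.names = FALSE)
  g <- read_genotypes(f, "plink_raw")
  expect_equal(unname(g$dosage), unname(G$dosage))
  expect_identical(g$sample_ids, G$sample_ids)
})

test_that("VCF genotypes map to ALT dosage with coordinates; non-biallelic records error", {
  g <- read_genotypes(write_vcf_file(), "vcf")
  expect_equal(unname(g$dosage["S1", ]), c(0, 2, 1))
  expect_equal(unname(g$dosage["S3", ]), c(2, 0, 0))
  expect_true(is.na(g$dosage["S2", "rs2"]))
  expect_equal(g$chrom, c("1", "1", "2"))
  expect_equal(g$pos, c(100L, 250L, 300L))
  expect_error(read_genotypes(write_multiallelic_vcf_file(), "vcf"),
               "non-biallelic")
})

test_that("phenotype reading splits trait columns, handles non-numeric cells, rejects duplicates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\theight\tyield", "A\t1.5\t10", "B\t2.5\tlow", "C\t3.5\t30"), f)
  ph <- read_phenotypes(f)
  expect_named(ph, c("height", "yield"))
  expect_equal(nrow(ph$height), 3)
  expect_equal(ph$height$value, c(1.5, 2.5, 3.5))
  expect_true(is.na(ph$yield$value[2]))

  f2 <- tempfile(fileext = ".tsv")
  y <- phenotype_table(c("A", "B", "C"), c(0.13579, -2.5, 3.25), trait = "t1")
  write_phenotypes(y, f2)
  back <- read_phenotypes(f2)$t1
  expect_identical(back$value, y$value)

  fdup <- tempfile(fileext = ".tsv")
  writeLines(c("id\tt", "A\t1", "A\t2"), fdup)
  expect_error(read_phenotypes(fdup), "duplicated")
})

test_that("marker QC removes low-MAF and high-missingness markers and mean-imputes the rest", {
  # marker 1: MAF 0.04 (must go at maf_min = 0.05); marker 2: 12% missing
  n <- 50
  dos <- cbind(m1 = c(rep(1, 4), rep(0, 46)),          # p = 0.04
               m2 = c(rep(NA, 6), rep(1, 44)),         # 12% missing
               m3 = rep(c(0, 1, 2, 1, 0), 10))
  G <- genotype_matrix(dos)
  Gf <- filter_markers(G, maf_min = 0.05, missing_max = 0.10)
  expect_identical(Gf$marker_ids, "m3")

  # identity pass-through (after imputation) at maf_min = 0, missing_max = 1
  Gi <- filter_markers(G, maf_min = 0, missing_max = 1)
  expect_identical(Gi$marker_ids, c("m1", "m2", "m3"))
  expect_false(anyNA(Gi$dosage))
  expect_equal(unname(Gi$dosage[1, "m2"]), 1)  # column mean of the observed 1s

  # filtering is idempotent once missing values are imputed
  Gff <- filter_markers(Gf, maf_min = 0.05, missing_max = 0.10)
  expect_equal(Gff$dosage, Gf$dosage)

  expect_error(filter_markers(G, subsample = 10), "exceeds")
  Gs <- filter_markers(G, maf_min = 0, missing_max = 1, subsample = 2, seed = 9)
  expect_equal(ncol(Gs$dosage), 2L)
  Gs2 <- filter_markers(G, maf_min = 0, missing_max = 1, subsample = 2, seed = 9)
  expect_identical(Gs$marker_ids, Gs2$marker_ids)
})

test_that("allele frequencies follow the dosage coding", {
  G <- genotype_matrix(cbind(a = c(0, 1, 2), b = c(2, 2, 2)))
  expect_equal(unname(G$allele_freq), c(0.5, 1.0))
  expect_error(genotype_matrix(cbind(c(0, 1), c(1, 2)),
                               sample_ids = c("X", "X")), "duplicated")
})
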