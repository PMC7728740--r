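# small in-code fixtures shared across tests

small_panel <- function(n = 60, p = 40, seed = 7) {
  simulate_genotypes(n, p, seed = seed)
}

write_genotype_table_file <- function(mat, ids = NULL) {
  f <- tempfile(fileext = ".tsv")
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(mat)))
  df <- data.frame(sample_id = ids, mat, check.names = FALSE)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

write_vcf_file <- function() {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>", "##contig=<ID=2>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t250\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.\t0/0",
    "2\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t0|1\t1|1\t0/0"), f)
  f
}

write_multiallelic_vcf_file <- function() {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), f)
  f
}

# VarianceComponents stand-in with known values, for plug-in BLUP tests
fixed_vc <- function(sigma2, kinds = "additive") {
  nm <- c(vapply(kinds, function(k)
    switch(k, additive = "sigma2_a", dominance = "sigma2_d",
           gaussian = "sigma2_g", paste0("sigma2_", k)), character(1)),
    "sigma2_e")
  names(sigma2) <- nm
  structure(list(sigma2 = sigma2,
                 sigma2_a = unname(sigma2[1]),
                 sigma2_e = unname(sigma2[length(sigma2)]),
                 sigma2_d = NA_real_, se = sigma2 * NA, cov = NULL,
                 loglik = NA_real_, n_used = NA_integer_, converged = TRUE),
            class = "VarianceComponents")
}
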