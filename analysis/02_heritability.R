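#!/usr/bin/env Rscript
# Marker QC and REML heritability. The eucalypt-style filter (MAF >= 0.05,
# missingness <= 10%) is applied, additive (and dominance) relationship
# matrices are built, and the four heritability ratios are estimated with
# delta-method standard errors.
suppressMessages(library(gpdeep))
G <- read_genotypes("results/data/genotypes.tsv", "table")
G <- filter_markers(G, maf_min = 0.05, missing_max = 0.10)
ph <- read_phenotypes("results/data/phenotypes.tsv")

A <- additive_relationship(G)
D <- dominance_relationship(G)

rows <- list()
for (trait in names(ph)) {
  vc_a <- fit_reml(ph[[trait]], A)
  h2 <- heritability_ratios(vc_a, "narrow")
  rows[[length(rows) + 1L]] <- data.frame(trait = trait, model = "additive",
                                          ratio = h2$ratio,
                                          estimate = h2$estimate, se = h2$se)
  vc_ad <- tryCatch(fit_reml(ph[[trait]], list(A, D)), error = function(e) NULL)
  if (!is.null(vc_ad)) {
    r <- heritability_ratios(vc_ad, "broad_with_ratios")
    rows[[length(rows) + 1L]] <- data.frame(trait = trait,
                                            model = "additive+dominance",
                                            ratio = r$ratio,
                                            estimate = r$estimate, se = r$se)
  }
}
out <- do.call(rbind, rows)
write.table(out, "results/heritability.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(paste(capture.output(print(out, digits = 3)), collapse = "\n"))
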