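#!/usr/bin/env Rscript
# Simulate the study's synthetic world: a filtered SNP panel of 400
# individuals x 1500 markers on 10 chromosomes, plus three trait
# architectures -- a heritable additive trait (h2a = 0.5, 10 QTL), an
# additive + dominance trait, and a null trait. Writes the panel, the
# phenotypes and the per-marker truth as delimited tables for the
# downstream steps.
suppressMessages(library(gpdeep))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260918L %% 100000L

G <- simulate_genotypes(400, 1500, maf_range = c(0.02, 0.5), seed = seed)
signal <- simulate_trait(G, n_qtl = 10, h2a = 0.5, seed = seed + 1L,
                         trait = "signal")
domtr <- simulate_trait(G, n_qtl = 10, h2a = 0.4, h2d = 0.2,
                        seed = seed + 2L, trait = "dominant")
null <- simulate_trait(G, n_qtl = 10, h2a = 0, seed = seed + 3L,
                       trait = "null")

write_genotypes(G, "results/data/genotypes.tsv")
write_phenotypes(list(signal$phenotypes, domtr$phenotypes, null$phenotypes),
                 "results/data/phenotypes.tsv")
write_truth(signal$truth, G, "results/data/truth_signal.tsv")
write_truth(domtr$truth, G, "results/data/truth_dominant.tsv")

message(sprintf("Panel: %d x %d, mean MAF %.3f", nrow(G$dosage),
                ncol(G$dosage),
                mean(pmin(G$allele_freq, 1 - G$allele_freq))))
message(sprintf("signal trait: realized h2a = %.3f",
                var(signal$truth$breeding_values) /
                  var(signal$phenotypes$value)))
message(sprintf("dominant trait: realized h2a = %.3f, h2d = %.3f",
                var(domtr$truth$breeding_values) / var(domtr$phenotypes$value),
                var(domtr$truth$genotypic_values -
                      domtr$truth$breeding_values) /
                  var(domtr$phenotypes$value)))
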