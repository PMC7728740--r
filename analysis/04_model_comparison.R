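#!/usr/bin/env Rscript
# Tukey-Kramer comparison of per-cycle predictive abilities with a compact
# letter display, formatted the way genomic-prediction studies tabulate
# model contrasts (mean PA with a letter superscript).
suppressMessages(library(gpdeep))
cv <- read.table("results/cv_results.tsv", header = TRUE, sep = "\t")
summ <- cv_summary(cv, alpha = 0.05)
write.table(summ, "results/cv_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(paste(capture.output(
  print(summ[, c("trait", "model", "display")], row.names = FALSE)),
  collapse = "\n"))
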