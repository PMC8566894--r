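#!/usr/bin/env Rscript
# Fit the Sloan neutral community model to the neutral-regime dataset:
# immigration probability m, R^2, and the partition of taxa against the 95%
# prediction band.

library(ecoassembly)

m <- read_otu_table("results/datasets/neutral/otu_table.tsv")
fit <- fit_ncm(m)
print(fit)

write.table(fit$taxa, "results/ncm_taxa.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("estimated m = %.3f (true 0.5), R^2 = %.3f; %.0f%% of taxa within the band",
                fit$m, fit$r_squared,
                100 * mean(fit$taxa$partition == "within")))
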