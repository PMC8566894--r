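#!/usr/bin/env Rscript
# Alpha-diversity indices per sample and the between-group community
# difference (PERMANOVA on Bray-Curtis), on the two-optima selection
# dataset where a group contrast exists.

library(ecoassembly)

ds_dir <- "results/datasets/selection"
m <- read_otu_table(file.path(ds_dir, "otu_table.tsv"))
env <- read_sample_metadata(file.path(ds_dir, "metadata.csv"))

alpha <- alpha_diversity(m)
write.table(alpha, "results/alpha_diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("alpha diversity: mean richness ",
        round(mean(alpha$richness), 1), ", mean Shannon ",
        round(mean(alpha$shannon), 2))

bray <- dissimilarity(m, "bray")
groups <- env$group[match(attr(bray, "Labels"), env$sample_id)]
pm <- permanova(bray, groups, n_perm = 9999, seed = 2)
message(sprintf("PERMANOVA cold vs warm: pseudo-F = %.2f, R2 = %.2f, p = %.4g",
                pm$F, pm$R2, pm$p_value))

kw <- kruskal.test(alpha$shannon ~ factor(groups))
message(sprintf("Kruskal-Wallis on Shannon between groups: p = %.3g",
                kw$p.value))
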