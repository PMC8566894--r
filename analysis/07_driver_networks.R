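#!/usr/bin/env Rscript
# Deterministic-driver statistics: Mantel tests of community dissimilarity
# against each environmental variable, and the thresholded Spearman
# co-occurrence network with node topology and a taxa-only subnetwork.

library(ecoassembly)

d <- "results/datasets/selection"
m <- read_otu_table(file.path(d, "otu_table.tsv"))
env <- read_sample_metadata(file.path(d, "metadata.csv"))

bray <- dissimilarity(m, "bray")
ord <- match(attr(bray, "Labels"), env$sample_id)
for (v in c("temperature", "salinity", "dsb", "nitrate")) {
  dv <- dist(env[[v]][ord])
  attr(dv, "Labels") <- attr(bray, "Labels")
  mt <- mantel_test(bray, dv, n_perm = 999, seed = 3)
  message(sprintf("Mantel %-12s R = %6.3f, p = %.4g", v, mt$statistic,
                  mt$p_value))
}

net <- suppressWarnings(correlation_network(m, env, r_threshold = 0.5,
                                            p_threshold = 0.05,
                                            min_reads = 10))
print(net)
write_network(net, "results/network_edges.tsv", "results/network.graphml")

topo <- node_topology(net)
write.table(topo, "results/node_topology.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hubs <- topo[order(-topo$degree), ][1:5, ]
message("top-degree nodes:")
print(hubs, row.names = FALSE)

taxa_only <- subnetwork(net, net$nodes$node[net$nodes$type == "taxon"])
message(sprintf("taxa-only subnetwork: %d of %d edges are taxon-taxon",
                nrow(taxa_only$edges), nrow(net$edges)))
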