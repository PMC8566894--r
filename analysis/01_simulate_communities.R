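#!/usr/bin/env Rscript
# Generate the synthetic community datasets every downstream analysis
# consumes: one neutral regime at survey scale, one high-immigration neutral
# regime, one two-optima selection regime, and one mixed regime, each with
# its phylogeny, metadata and ground-truth sidecar.

library(ecoassembly)

out <- "results/datasets"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

datasets <- list(
  # N = depth here: the Sloan m is estimated as Nm / mean reads, so it is
  # only on the probability scale when community size and depth coincide
  neutral = simulate_dataset(40, 166, "neutral", m = 0.5, N = 10640,
                             seed = 11),
  high_dispersal = simulate_dataset(20, 166, "neutral", m = 0.9, seed = 12),
  selection = simulate_dataset(20, 100, "variable_selection", m = 0.05,
                               sigma_w = 0.5, N = 1000, depth = 1000,
                               generations = 500, lognormal_sigma = 1,
                               env_jitter_sd = 0.75, seed = 13),
  mixed = simulate_dataset(16, 100, "mixed", m = 0.05, sigma_w = 0.5,
                           N = 1000, depth = 1000, generations = 500,
                           lognormal_sigma = 1, env_jitter_sd = 0.5,
                           seed = 14))

for (nm in names(datasets)) {
  ds <- datasets[[nm]]
  write_dataset(ds, file.path(out, nm))
  message(nm, ": ", nrow(ds$community), " samples x ", ncol(ds$community),
          " taxa, regime = ", ds$regime,
          ", mean depth = ", round(mean(rowSums(ds$community))))
}
message("wrote ", length(datasets), " datasets under ", out)
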