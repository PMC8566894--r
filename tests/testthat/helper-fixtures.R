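# Shared fixtures, built in code.

# The documented 3-sample x 4-taxon matrix used for the hand-computed
# dissimilarity and alpha-diversity oracles.
toy_matrix <- function() {
  m <- rbind(s1 = c(5L, 1L, 1L, 2L),
             s2 = c(1L, 2L, 0L, 3L),
             s3 = c(0L, 0L, 4L, 4L))
  colnames(m) <- paste0("t", 1:4)
  m
}

# The documented 3-tip tree: ((A:1,B:1):1,C:2);
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Reshuffle a vector reproducibly (breaks any tip-trait association).
with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(unname(x))
}

# A small neutral dataset reused by several module tests.
small_neutral <- function(seed = 42, n_samples = 12, n_taxa = 40) {
  simulate_dataset(n_samples, n_taxa, "neutral", m = 0.5, N = 2000,
                   depth = 1000, generations = 20, lognormal_sigma = 1,
                   seed = seed)
}
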