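# Synthetic communities with known assembly regimes.
#
# The generator produces the full fixture triplet the inference stages consume
# (counts + tree + environment) together with the ground-truth regime, so that
# NCM, betaNTI/RC, NST and phylogenetic-signal estimates can be validated by
# parameter recovery instead of against unavailable field data.

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Rooted binary tree grown by exponential waiting times between speciation
#' events; tips are labeled `OTU_1..OTU_n`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed.
#' @param birth speciation rate (default 1; only rescales branch lengths).
#' @return an [ape] `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, seed = NULL, birth = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = 0))
  tree$tip.label <- paste0("OTU_", seq_len(n_tips))
  validate_phylogeny(tree)
}

#' Evolve a niche trait by Brownian motion along a tree
#'
#' Trait at each tip is `root` plus the sum of independent Gaussian increments
#' with variance `sigma2 * branch length` along its root-to-tip path, i.e. the
#' model Blomberg's K is calibrated against (K = 1 in expectation).
#'
#' @param tree `phylo` with branch lengths.
#' @param sigma2 BM rate (trait variance per unit branch length), > 0.
#' @param root trait value at the root.
#' @param seed optional integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_bm_trait <- function(tree, sigma2, root = 0, seed = NULL) {
  validate_phylogeny(tree)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  with_seed(seed, {
    val <- numeric(n_tip + n_node)
    val[n_tip + 1] <- root # root node index in ape numbering
    # preorder traversal: parents before children
    ord <- ape::reorder.phylo(tree, "cladewise")
    inc <- stats::rnorm(nrow(ord$edge), 0, sqrt(sigma2 * ord$edge.length))
    for (e in seq_len(nrow(ord$edge)))
      val[ord$edge[e, 2]] <- val[ord$edge[e, 1]] + inc[e]
    traits <- val[seq_len(n_tip)]
  })
  names(traits) <- tree$tip.label
  traits
}

#' Draw a skewed metacommunity abundance distribution
#'
#' Lognormal relative abundances, normalized to sum to one. Larger
#' `lognormal_sigma` gives a more uneven (higher-Gini) community.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param lognormal_sigma sd of log abundances (>= 0; 0 gives an even
#'   community).
#' @param seed optional integer seed.
#' @return named numeric vector of relative abundances summing to 1.
#' @export
build_metacommunity <- function(n_taxa, lognormal_sigma = 1, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (lognormal_sigma < 0) stop("lognormal_sigma must be >= 0")
  gam <- with_seed(seed, stats::rlnorm(n_taxa, meanlog = 0, sdlog = lognormal_sigma))
  gam <- gam / sum(gam)
  names(gam) <- paste0("OTU_", seq_len(n_taxa))
  gam
}

#' Simulate one local community under immigration-limited neutral drift
#'
#' Moran scheme: initialize by a multinomial draw of `N` individuals from the
#' metacommunity; then for `generations * N` steps remove one uniformly chosen
#' individual and replace it, with probability `m`, by an immigrant drawn from
#' the metacommunity (the dispersal event the Sloan model parameterizes),
#' otherwise by a local birth proportional to current local abundance.
#'
#' @param meta metacommunity relative abundances (sums to 1).
#' @param N local community size (>= 10).
#' @param m immigration probability in `[0, 1]`.
#' @param generations number of complete turnovers (default 50).
#' @param seed optional integer seed.
#' @return integer count vector summing to `N`, named like `meta`.
#' @export
simulate_neutral_community <- function(meta, N, m, generations = 50, seed = NULL) {
  if (m < 0 || m > 1) stop("m must be in [0, 1]")
  if (N < 10) stop("N must be >= 10")
  stopifnot(abs(sum(meta) - 1) < 1e-8)
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, N, prob = meta))
    counts <- moran_step_cpp(counts, as.numeric(meta), m, generations * N)
  })
  names(counts) <- names(meta)
  counts
}

#' Simulate one local community under Gaussian environmental filtering
#'
#' Deterministic (niche) assembly: each taxon's sampling weight is its
#' metacommunity abundance times a Gaussian fitness kernel centred on the
#' local environment, `w_i = gamma_i * exp(-(t_i - env)^2 / (2 sigma_w^2))`;
#' the community is a multinomial draw of `N` individuals from the normalized
#' weights. Small `sigma_w` means strong selection.
#'
#' @param meta metacommunity relative abundances.
#' @param traits per-taxon niche optima, aligned with `meta`.
#' @param env local environmental value (same units as `traits`).
#' @param sigma_w niche breadth (> 0).
#' @param N community size.
#' @param seed optional integer seed.
#' @return integer count vector summing to `N`.
#' @export
simulate_selected_community <- function(meta, traits, env, sigma_w, N, seed = NULL) {
  if (sigma_w <= 0) stop("sigma_w must be > 0")
  stopifnot(length(traits) == length(meta))
  w <- meta * exp(-(traits - env)^2 / (2 * sigma_w^2))
  if (sum(w) <= 0 || !any(is.finite(w) & w > 0))
    stop("all selection weights underflowed to zero; increase sigma_w")
  counts <- with_seed(seed, as.vector(stats::rmultinom(1, N, prob = w / sum(w))))
  names(counts) <- names(meta)
  counts
}

#' Simulate a full community dataset with known assembly regime
#'
#' Assembles `n_samples` local communities from one shared metacommunity under
#' a chosen regime, evolves a Brownian niche trait on a Yule phylogeny, applies
#' multinomial subsampling to a fixed sequencing depth, and records the ground
#' truth. Regimes:
#' \describe{
#'   \item{neutral}{every sample from [simulate_neutral_community()] with the
#'     given `m`; the environment plays no role in assembly.}
#'   \item{homogeneous_selection}{all samples filtered toward a single
#'     environmental optimum (mean tip trait).}
#'   \item{variable_selection}{two equal groups filtered toward optima at
#'     the trait mean +/- 2 sd of the tip traits.}
#'   \item{mixed}{first half neutral, second half filtered at one optimum.}
#' }
#'
#' @param n_samples number of local communities.
#' @param n_taxa number of taxa in the metacommunity / tree tips.
#' @param regime one of `"neutral"`, `"homogeneous_selection"`,
#'   `"variable_selection"`, `"mixed"`.
#' @param m immigration probability for neutral assembly.
#' @param sigma_w niche breadth for selection regimes.
#' @param N local community size before sequencing.
#' @param depth sequencing depth (multinomial subsample of the community).
#' @param generations Moran turnovers for the neutral regime.
#' @param lognormal_sigma metacommunity evenness parameter.
#' @param sigma2_bm BM rate for the niche trait.
#' @param trait_root root value of the niche trait (environment units, e.g.
#'   degrees C).
#' @param env_jitter_sd sd of per-sample environmental deviation around the
#'   group optimum (same units as the trait; 0 = identical environments).
#'   Small jitter emulates within-habitat heterogeneity, which drives
#'   turnover among ecologically similar relatives.
#' @param seed integer seed governing every stochastic step.
#' @return an object of class `synthetic_dataset`: list with `community`
#'   (samples x taxa counts), `tree`, `env` (metadata data.frame with
#'   `temperature` and `group`), `regime`, `traits`, `meta` and `params`.
#' @export
simulate_dataset <- function(n_samples, n_taxa = 166, regime = c("neutral",
                             "homogeneous_selection", "variable_selection",
                             "mixed"),
                             m = 0.5, sigma_w = 1, N = 53200, depth = 10640,
                             generations = 50, lognormal_sigma = 2,
                             sigma2_bm = 1, trait_root = 25,
                             env_jitter_sd = 0, seed = 1) {
  regime <- match.arg(regime)
  if (n_samples < 2) stop("n_samples must be >= 2")
  params <- list(n_samples = n_samples, n_taxa = n_taxa, regime = regime,
                 m = m, sigma_w = sigma_w, N = N, depth = depth,
                 generations = generations, lognormal_sigma = lognormal_sigma,
                 sigma2_bm = sigma2_bm, trait_root = trait_root,
                 env_jitter_sd = env_jitter_sd, seed = seed)

  tree <- simulate_yule_tree(n_taxa, seed = stage_seed(seed, "tree"))
  traits <- simulate_bm_trait(tree, sigma2 = sigma2_bm, root = trait_root,
                              seed = stage_seed(seed, "trait"))
  meta <- build_metacommunity(n_taxa, lognormal_sigma,
                              seed = stage_seed(seed, "meta"))

  spread <- stats::sd(traits)
  if (regime != "neutral" && spread == 0)
    stop("selection regimes need trait variation; increase sigma2_bm")
  mid <- mean(traits)
  # single-optimum regimes filter toward a trait extreme: under BM, extreme
  # trait values are phylogenetically clumped while mean values are reached
  # convergently all over the tree
  env_of <- switch(regime,
    neutral = rep(mid, n_samples),
    homogeneous_selection = rep(mid + 2 * spread, n_samples),
    variable_selection = rep(c(mid - 2 * spread, mid + 2 * spread),
                             length.out = n_samples),
    mixed = rep(mid + 2 * spread, n_samples))
  if (env_jitter_sd > 0)
    env_of <- env_of + with_seed(stage_seed(seed, "jitter"),
                                 stats::rnorm(n_samples, 0, env_jitter_sd))
  group <- switch(regime,
    variable_selection = rep(c("cold", "warm"), length.out = n_samples),
    mixed = rep(c("neutral", "selected"), each = ceiling(n_samples / 2))[seq_len(n_samples)],
    rep("all", n_samples))
  neutral_sample <- switch(regime,
    neutral = rep(TRUE, n_samples),
    mixed = group == "neutral",
    rep(FALSE, n_samples))

  community <- with_seed(stage_seed(seed, "assembly"), {
    t(vapply(seq_len(n_samples), function(s) {
      local <- if (neutral_sample[s]) {
        simulate_neutral_community(meta, N = N, m = m, generations = generations)
      } else {
        # selection regimes: environmental filtering of the immigrant pool,
        # with the same drift dynamics acting within the filtered pool, so
        # samples vary realistically inside the favored clade
        w <- meta * exp(-(traits - env_of[s])^2 / (2 * sigma_w^2))
        if (sum(w) <= 0) stop("all selection weights underflowed; increase sigma_w")
        simulate_neutral_community(w / sum(w), N = N, m = m,
                                   generations = generations)
      }
      # sequencing: reads are a with-replacement draw from the community
      as.vector(stats::rmultinom(1, depth, prob = local / sum(local)))
    }, integer(n_taxa)))
  })
  rownames(community) <- sprintf("S%03d", seq_len(n_samples))
  colnames(community) <- names(meta)
  storage.mode(community) <- "integer"

  env <- with_seed(stage_seed(seed, "env"), data.frame(
    sample_id = rownames(community),
    temperature = env_of + stats::rnorm(n_samples, 0, 0.1 * max(spread, 1e-6)),
    salinity = stats::rnorm(n_samples, 34, 0.5),
    dsb = stats::rlnorm(n_samples, log(1000), 0.5),
    nitrate = stats::rlnorm(n_samples, 0, 0.6),
    group = group,
    stringsAsFactors = FALSE))

  structure(list(community = community, tree = tree, env = env,
                 regime = regime, traits = traits, meta = meta,
                 params = params),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$community), "samples x",
      ncol(x$community), "taxa; regime =", x$regime,
      sprintf("(m = %s, sigma_w = %s, depth = %s, seed = %s)\n",
              x$params$m, x$params$sigma_w, x$params$depth, x$params$seed))
  invisible(x)
}

#' Write a synthetic dataset as the standard fixture triplet
#'
#' Emits `otu_table.tsv` (taxa rows), `tree.nwk`, `metadata.csv` and a
#' `truth.json` sidecar holding the regime and generating parameters.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(ds$community, file.path(dir, "otu_table.tsv"))
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  write_sample_metadata(ds$env, file.path(dir, "metadata.csv"))
  truth <- c(ds$params, list(regime_per_sample = stats::setNames(
    rep(ds$regime, nrow(ds$community)), rownames(ds$community))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
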