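---
title: "Inferring community assembly processes: models, null models, and design choices"
author: "ecoassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Marine microbial surveys — the motivating case is nifH-amplicon profiling of
the symbiotic cyanobacterium UCYN-A across tropical seas — repeatedly find
communities whose composition varies between stations without an obvious
environmental explanation. The question this package addresses is *how much
of that variation is stochastic* (drift, random dispersal, ecologically
neutral turnover) *and how much is deterministic* (niche-based selection by
temperature, salinity, nutrients). Three complementary instruments answer
it:

1. the **Sloan neutral community model (NCM)**, which fits a taxon's
   occurrence frequency against its regional mean relative abundance with a
   single immigration parameter;
2. **phylogenetic and taxonomic null models** — betaMNTD/betaNTI and
   Raup-Crick on Bray-Curtis (RC-Bray) — which classify each sample pair
   into variable selection, homogeneous selection, dispersal limitation,
   homogenizing dispersal, or "undominated";
3. the **normalized stochasticity ratio (NST)**, which rescales the
   departure of observed dissimilarity from its null expectation onto
   [0, 1], with 0.5 the conventional stochastic/deterministic boundary.

Because the field data behind any one survey cannot validate the machinery
(their truth is unknown), everything here is calibrated against a
**synthetic community generator** whose assembly regime is known exactly.

# The synthetic generator defines the test bed

`simulate_dataset()` builds a metacommunity, a phylogeny, an environment and
local communities:

* **Phylogeny**: a pure-birth (Yule) tree, tips `OTU_1..OTU_n`.
* **Niche trait**: Brownian motion along the tree (`simulate_bm_trait()`),
  so Blomberg's K has expectation 1 on the generated trait. The root value
  (default 25) puts the trait on a sea-surface-temperature-like scale in
  degrees C.
* **Metacommunity**: lognormal relative abundances; the default
  `lognormal_sigma = 2` reproduces the strong dominance skew of nifH
  libraries (a few OTUs holding most reads).
* **Local assembly**: a Moran death-birth process (`moran_step_cpp`,
  compiled): each event removes one individual uniformly and replaces it by
  an immigrant with probability `m` (drawn from the metacommunity) or by a
  local birth. The Moran scheme matches the NCM's own
  "loss replaced by dispersal" framing; `generations = 50` full turnovers is
  the default burn-in.
* **Selection regimes** filter the immigrant pool by a Gaussian kernel
  `exp(-(t_i - env)^2 / (2 sigma_w^2))` on the BM trait, and the same Moran
  dynamics then run inside the filtered pool, so selected communities still
  drift. `variable_selection` places two sample groups at optima +/- 2 trait
  standard deviations from the trait mean; single-optimum regimes
  (`homogeneous_selection`, the selected half of `mixed`) filter toward the
  trait mean **plus** 2 sd. The extreme is deliberate: under Brownian
  motion, intermediate trait values are reached convergently all over the
  tree, so filtering at the trait mean selects a phylogenetically scattered
  set and *no* method could recover a phylogenetic signature of selection
  from it; extreme values are reached by one or few clades.
* **Environmental jitter** (`env_jitter_sd`) adds per-sample deviation
  around the group optimum — within-habitat heterogeneity. With a narrow
  niche (`sigma_w` small) this makes slightly different clade members win in
  different samples, which is what gives homogeneous selection its
  among-relatives turnover.
* **Sequencing** is a multinomial draw of `depth` reads from the local
  community — with replacement, distinct from rarefaction (without
  replacement, `rarefy_even_depth()`).

Scale defaults mirror a rarefied nifH survey: 166 taxa, 10,640 reads per
sample, and a true community size of `N = 53200` (5x the read depth —
natural communities dwarf sequencing depth, and this inequality is exactly
what makes high-immigration replicate communities near-identical relative to
read noise).

What the generator does **not** emulate: PCR/primer bias, chimeras and
sequencing error (the upstream OTU pipeline is out of scope), spatial
autocorrelation and ocean-current transport, temporal dynamics, and
interaction-driven (biotic) selection. Passing calibration therefore shows
the inference machinery is correct and well calibrated *given* clean count
data of realistic shape — not that any particular field estimate is right.

# Sloan neutral community model

`ncm_expected_frequency(p, Nm, d)` is the stationary-beta detection
probability `1 - I_d(Nm p, Nm (1 - p))`. `fit_ncm()` computes per-taxon
`(p_i, freq_i)` from the count matrix and estimates `Nm` by nonlinear least
squares on that curve (bounded search on `log Nm`, `optimize()`), the
standard approach of the widely used fitting scripts; `m = Nm / N_mean` with
`N_mean` the mean reads per sample; `R^2 = 1 - SSE/SST`. The detection limit
defaults to one read (`d = 1/N_mean`).

Two caveats the fit makes explicit:

* `m` is on the probability scale only when read depth ~ community size; if
  true `N` exceeds depth, `Nm/N_mean` can exceed 1. The analysis scripts use
  `N = depth` for NCM datasets for this reason.
* The 95% band around the fitted curve uses **exact binomial prediction
  quantiles** (`qbinom` at the predicted frequency with n = number of
  samples), not a Wilson confidence interval. The banded quantity is a
  *future observed frequency*, a prediction problem: the binomial band
  covers a truly neutral taxon's observed frequency at >= the nominal level
  (measured ~0.96-0.97 on realistic frequency spectra), while the Wilson CI
  under-covers observations (~0.89-0.90). Wilson remains available via
  `partition_taxa(fit, method = "wilson")`.

Calibration (acceptance suite): occupancy generated from the curve itself
(Nm = 500, 150 samples, 500 taxa, binomial noise) returns Nm within a few
percent and band coverage within [0.91, 0.99]; the Moran mechanism with
`m = 0.5`, `N = depth = 1000`, 150 samples returns `m` in [0.35, 0.65] with
`R^2 > 0.9`.

# betaMNTD, betaNTI, and where homogeneous selection is detectable

`beta_mntd()` computes, per pair, the abundance-weighted mean distance from
each taxon to its nearest relative in the other sample (averaged over both
directions). Abundance weighting is the default — turnover of dominant taxa
is what the downstream inference weighs — with an unweighted flag. Note the
unweighted value averages the two directional means; implementations that
pool both directions into one mean differ when richness differs.

`beta_nti()` standardizes observed betaMNTD against a null that permutes
taxon identities across the tip-distance matrix of the **whole regional
pool** (all taxa present in the matrix; taxa with zero total are dropped
first). Pairs whose null distribution has zero variance — e.g. two samples
with identical taxon sets, where every shuffled betaMNTD equals the observed
one — are reported as `NaN`, warned about, and excluded from downstream
fractions.

A structural property worth understanding before interpreting betaNTI on
small or homogeneous surveys: **the null pool is the data's own taxa.** If
every sample is filtered toward one optimum, the observed pool collapses to
the selected clade, the shuffle only permutes positions within that clade,
and the clustering signature is invisible — not a bug, a pool-breadth
limitation shared with any tip-shuffling null. The calibration suite
therefore exercises homogeneous selection the way it occurs in real surveys:
as *pairs that experienced the same optimum inside a heterogeneous region*
(within-group pairs of the two-optima regime, and selected-selected pairs of
the `mixed` regime, where neutral samples supply pool breadth). Under that
design, pairs under different optima shift strongly positive (typically
> +2) and same-optimum pairs shift negative relative to neutral controls;
the calibration pools four replicate datasets so the conclusion does not
hinge on one tree realization.

# RC-Bray and the process classification

`rc_bray()` rebuilds each sample `n_null` times from the regional pool:
observed richness is kept (taxa drawn without replacement, probability
proportional to occurrence frequency), observed total reads are kept (one
read per drawn taxon — preserving realized richness, the standard Raup-Crick
convention — and the remainder multinomial proportional to regional relative
abundance). `RC = 2[(#null < obs) + (#null = obs)/2]/n_null - 1`, ties at
half weight, equality judged at 1e-12.

`classify_processes()` applies the canonical two-stage rule: betaNTI > +2
variable selection; < -2 homogeneous selection; otherwise RC > +0.95
dispersal limitation, RC < -0.95 homogenizing dispersal, else undominated.
Thresholds are arguments, defaults as published. Fractions are taken over
pairs with defined betaNTI; undefined pairs are counted separately.

# NST

`nst()` compares observed dissimilarity `D_ij` (any of the bounded metrics
below) with the mean null dissimilarity `E_ij` over `n_null` randomized
communities, via the normalized selection strength

```
NSS_ij = (D_ij - E_ij) / (1 - E_ij)   if D_ij >= E_ij
         (E_ij - D_ij) / E_ij         otherwise
NST    = 1 - mean(NSS),   clamped to [0, 1].
```

`E = 0` or `1` degenerate pairs resolve their 0/0 limit to 0. The quoted
"mean +/- sd" spread is a *permutation distribution*: one NST value per
randomization, using that single randomization's dissimilarities as the
expectation — a convention, flagged as such, chosen to match the
999-permutation table format of stochasticity surveys.

Two null algorithms mirror the incidence/abundance metric blocks:
`incidence_prop_fixed` (richness fixed, presences proportional to occupancy)
pairs with incidence metrics; `abundance_prop_prop` (additionally reads
proportional to regional abundance) with abundance metrics.

Calibration notes. NST -> 1 on data generated by the null algorithm itself
only when the template community has near-complete occupancy and modest
dominance; under strongly skewed abundances, the lumpy inclusion/exclusion
of mid-abundance taxa keeps single-realization dissimilarities ~30-40% away
from their expectation and NST plateaus near 0.7-0.8 even for purely
stochastic data — the self-null acceptance check uses an even,
high-occupancy template for exactly this reason, and empirical NST values
should be read comparatively, not absolutely. Identical samples give NST = 0
exactly. `nst_panova()` permutes group labels with a **shared null seed**
across all relabelings, so the statistic reflects membership alone (two
identical groups give exactly 0, and the test attains p = 1 there); its
type-I rate at alpha = 0.05 measures 0.05-0.07.

# Phylogenetic signal

`taxon_niche_values()` computes each taxon's abundance-weighted mean
environment — the field-standard construction of "environmental response"
when only survey data exist. Because these values inherit co-occurrence
structure, variables correlated with the true driver pick up residual
signal; interpret the *ranking* of K across variables. `blomberg_k()`
implements the K ratio from the BM covariance matrix (`ape::vcv()`), K = 1
under BM; `k_significance()` tests the variance of phylogenetically
independent contrasts (`ape::pic()`) against tip reshuffles, one-sided
(signal = contrasts less variable than null), `p = (1 + #{null <= obs}) /
(1 + n_perm)`. K is invariant to affine trait maps and global branch-length
rescaling (tested), and matches `picante::Kcalc` to 1e-10 on shared input.

# Drivers

Mantel and PERMANOVA delegate to `vegan::mantel()` / `vegan::adonis2()`
(the tools a practitioner would use, and whose permutation-p conventions
match the `1/(n_perm + 1)` floor asserted in tests) behind validating
wrappers. The co-occurrence network computes all pairwise Spearman
correlations in one rank-transform + `cor()` pass; p-values use the
two-sided t approximation; edges need `|r| > 0.5` **and** `p < 0.05` on raw
p-values — the published convention — with Benjamini-Hochberg available via
`adjust = "BH"` (with ~5,000 candidate pairs and no correction, expect some
spurious edges; the calibration test quantifies the rate). Taxa with <= 10
total reads are excluded by default. Topology metrics (degree, betweenness,
closeness, eigenvector) run per connected component on the unweighted graph;
the eigenvector uses a dense symmetric eigensolver so repeated runs are
byte-identical.

# Orchestration, seeds, and numerical conventions

`run_pipeline()` executes data -> (rarefy) -> diversity -> NCM -> betaNTI/RC
-> NST -> signal -> drivers from a validated config (unknown keys rejected
by name). One global seed fans out per stage through `stage_seed()` (a
fixed affine hash of the stage name, kept below 2^31), so any stage can be
re-run in isolation and the whole pipeline is byte-identical across runs.
Defaults follow the published conventions: 999 nulls for betaNTI, RC, NST
and the trait-reshuffling test; 9,999 PERMANOVA permutations; |betaNTI|
threshold 2; RC threshold 0.95; NST boundary 0.5; network |r| > 0.5,
p < 0.05, > 10 reads.

Numerical conventions: dissimilarity ties and RC equalities at 1e-12;
constant traits detected at relative 1e-12 (K = 0 with a warning); NSS
clamped to [0, 1]; "Simpson diversity" means Gini-Simpson `1 - sum p^2`;
Shannon in nats so Pielou `J = H / ln S` is coherent; Chao1 in the
bias-corrected form `S + F1(F1 - 1) / (2(F2 + 1))`; ACE with rare cutoff 10;
Gower and Manhattan are range-/maximum-standardized so every metric NST
consumes is bounded in [0, 1]; the abundance-variant Jaccard is Ruzicka.

# Problem sizes used by the test and acceptance suites

Calibrations run at sizes a laptop handles in minutes, chosen as the
smallest that leave the assertions comfortably away from their Monte-Carlo
noise floor: NCM self-consistency at 150 samples x 500 taxa; mechanism
recovery at 150 samples, N = depth = 1000; betaNTI calibration at 16-20
samples x 100 taxa with 299-999 nulls and four pooled replicate datasets for
the selection contrasts; RC/process classification at 20 samples x 166 taxa
with 999 nulls; NST panel at 14-16 samples with 199-299 nulls and the ANOVA
type-I at 200 replicates of 8 + 8 samples; Blomberg's K at 64 tips x 200 BM
replicates; Mantel/PERMANOVA size at 500 replicates of 10 samples.

# Known limitations

* betaNTI cannot flag homogeneous selection when the survey's own taxon pool
  collapses to the selected clade (discussed above).
* NST's absolute level depends on the template's occupancy and dominance
  structure; use it comparatively.
* The NCM immigration estimate is conditional on read depth standing in for
  community size.
* Niche-value phylogenetic signal inherits co-occurrence structure; K
  rankings across variables are more trustworthy than any single K.
* The generator's environments are i.i.d. per sample; spatially structured
  dispersal (distance decay) is not modeled, so the Mantel distance-decay
  hook is exercised only for sign-free computability.
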