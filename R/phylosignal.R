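# Phylogenetic signal of taxon environmental responses: abundance-weighted
# niche values, Blomberg's K, and a trait-reshuffling significance test on
# the variance of phylogenetically independent contrasts.

#' Abundance-weighted taxon niche values
#'
#' Each taxon's realized niche value for an environmental variable is its
#' abundance-weighted mean environment across samples:
#' `t_i = sum_s (x_is / sum_s' x_is') env_s`. Taxa with zero total count are
#' excluded; samples with a missing value of the variable are dropped with a
#' warning.
#'
#' @param m samples x taxa count matrix.
#' @param env metadata data.frame with a `sample_id` column matching the rows
#'   of `m`.
#' @param variable name of a numeric column of `env`.
#' @return named numeric vector of niche values (one per retained taxon).
#' @export
taxon_niche_values <- function(m, env, variable) {
  check_community(m, integer_counts = FALSE)
  if (!variable %in% colnames(env)) stop("variable not in metadata: ", variable)
  v <- env[[variable]][match(rownames(m), env$sample_id)]
  if (all(is.na(v))) stop("variable is entirely missing: ", variable)
  if (anyNA(v)) {
    warning(sum(is.na(v)), " sample(s) with missing ", variable, " dropped")
    m <- m[!is.na(v), , drop = FALSE]
    v <- v[!is.na(v)]
  }
  if (length(v) < 3) stop("fewer than 3 samples with non-missing ", variable)
  tot <- colSums(m)
  keep <- tot > 0
  w <- t(m[, keep, drop = FALSE]) / tot[keep] # taxa x samples weights
  drop(w %*% v)
}

#' Blomberg's K
#'
#' Ratio of the observed trait mean squared error (about the phylogenetic
#' mean) to the error under the tree's Brownian-motion covariance, scaled by
#' its BM expectation, so K = 1 matches BM evolution and K near 0 means no
#' signal. With `V` the tip covariance matrix of shared branch lengths and
#' `a = (1'V^-1 1)^-1 (1'V^-1 y)`:
#' `K = (MSE0/MSE) * (n - 1) / (tr(V) - n / (1'V^-1 1))`,
#' `MSE0 = (y - a)'(y - a)/(n - 1)`, `MSE = (y - a)'V^-1(y - a)/(n - 1)`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param traits named numeric vector; names must match tip labels (>= 4
#'   tips). Tips without a trait are pruned; trait entries not on the tree
#'   are dropped with a warning.
#' @return K (non-negative scalar). A constant trait gives K = 0 with a
#'   warning.
#' @export
blomberg_k <- function(tree, traits) {
  prep <- .match_tree_traits(tree, traits)
  y <- prep$traits
  n <- length(y)
  V <- ape::vcv(prep$tree)[names(y), names(y)]
  Vi <- solve(V)
  one <- rep(1, n)
  a <- sum(Vi %*% y) / sum(Vi)
  r <- y - a
  mse0 <- sum(r^2) / (n - 1)
  if (mse0 <= 1e-12 * (abs(a) + 1)^2) { # constant up to rounding
    warning("constant trait; K = 0")
    return(0)
  }
  mse <- drop(t(r) %*% Vi %*% r) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  (mse0 / mse) / expected
}

.match_tree_traits <- function(tree, traits) {
  validate_phylogeny(tree)
  if (is.null(names(traits))) stop("traits must be named by tip label")
  off_tree <- setdiff(names(traits), tree$tip.label)
  if (length(off_tree)) {
    warning(length(off_tree), " trait value(s) not on the tree dropped")
    traits <- traits[names(traits) %in% tree$tip.label]
  }
  if (length(traits) < 4) stop("need >= 4 tips with trait values")
  if (anyNA(traits)) stop("missing trait values")
  tree <- ape::keep.tip(tree, names(traits))
  list(tree = tree, traits = traits[tree$tip.label])
}

#' Significance test for phylogenetic signal
#'
#' One-sided permutation test on the variance of phylogenetically independent
#' contrasts (PICs): real signal makes contrasts less variable than expected,
#' so the null reshuffles trait values across tips `n_perm` times and
#' `p = (1 + #{null variance <= observed}) / (1 + n_perm)`. K is reported
#' alongside.
#'
#' @inheritParams blomberg_k
#' @param n_perm number of trait reshuffles (default 999).
#' @param seed optional integer seed.
#' @param trait_name label carried into the result.
#' @return object of class `signal_result`: list with `K`, `p_value`,
#'   `pic_variance`, `n_perm`, `n_tips`, `trait`.
#' @export
k_significance <- function(tree, traits, n_perm = 999, seed = NULL,
                           trait_name = deparse(substitute(traits))) {
  prep <- .match_tree_traits(tree, traits)
  y <- prep$traits
  tr <- prep$tree
  K <- blomberg_k(tr, y)
  obs <- stats::var(ape::pic(y, tr))
  nulls <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    ys <- stats::setNames(sample(y), names(y))
    stats::var(ape::pic(ys, tr))
  }, numeric(1)))
  structure(list(K = K,
                 p_value = (1 + sum(nulls <= obs + 1e-15)) / (1 + n_perm),
                 pic_variance = obs, n_perm = n_perm, n_tips = length(y),
                 trait = trait_name),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("phylogenetic signal (%s): K = %.3f, p = %.4g (%d tips, %d reshuffles)\n",
              x$trait, x$K, x$p_value, x$n_tips, x$n_perm))
  invisible(x)
}

#' Phylogenetic signal for several environmental variables
#'
#' Convenience wrapper running [taxon_niche_values()] + [k_significance()]
#' per variable.
#'
#' @param m samples x taxa count matrix.
#' @param env metadata data.frame.
#' @param tree `phylo`.
#' @param variables character vector of numeric metadata columns.
#' @inheritParams k_significance
#' @return data.frame with `variable`, `K`, `p_value`, `n_tips`.
#' @export
phylo_signal_table <- function(m, env, tree, variables, n_perm = 999,
                               seed = NULL) {
  rows <- lapply(seq_along(variables), function(i) {
    tv <- taxon_niche_values(m, env, variables[i])
    sig <- k_significance(tree, tv, n_perm = n_perm,
                          seed = if (is.null(seed)) NULL else seed + i,
                          trait_name = variables[i])
    data.frame(variable = variables[i], K = sig$K, p_value = sig$p_value,
               n_tips = sig$n_tips, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
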