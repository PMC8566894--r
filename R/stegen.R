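# Phylogenetic turnover null models and the five-way assembly-process
# classification: betaMNTD -> betaNTI (tip-shuffling null) for selection,
# RC-Bray (probabilistic community null) for dispersal, thresholds +-2 and
# +-0.95.

# min over the columns `cols` of D, for every row; avoids matrixStats.
.row_min_cols <- function(D, cols) {
  if (length(cols) == 1L) return(D[, cols])
  do.call(pmin, lapply(cols, function(j) D[, j]))
}

# betaMNTD for all sample pairs given a taxon distance matrix.
# f: samples x taxa weight matrix (rows sum to 1), pres: logical presence.
.bmntd_all_pairs <- function(f, pres, D) {
  n <- nrow(f)
  Dmin <- vapply(seq_len(n),
                 function(l) .row_min_cols(D, which(pres[l, ])),
                 numeric(ncol(f))) # taxa x samples
  M <- f %*% Dmin # M[k, l] = sum_i f_ik min_{j in l} d_ij
  (M + t(M)) / 2
}

#' Between-sample mean nearest-taxon distance (betaMNTD)
#'
#' For each sample pair, the abundance-weighted mean of the phylogenetic
#' distance from every taxon in one sample to its closest relative in the
#' other, averaged over both directions:
#' `0.5 * (sum_i f_ik min_j d_ij + sum_j f_jl min_i d_ij)`.
#' With `abundance_weighted = FALSE` each present taxon gets equal weight.
#' Taxa shared by both samples contribute distance 0.
#'
#' @param m samples x taxa count matrix; every taxon with nonzero total must
#'   be a tip of `tree` (all-zero taxa are dropped).
#' @param tree rooted `phylo` with branch lengths.
#' @param abundance_weighted weight by relative abundance (default `TRUE`).
#' @return a [stats::dist] of betaMNTD values.
#' @export
beta_mntd <- function(m, tree, abundance_weighted = TRUE) {
  check_community(m, integer_counts = FALSE)
  validate_phylogeny(tree)
  m <- m[, colSums(m) > 0, drop = FALSE]
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  if (any(rowSums(m) == 0)) stop("sample(s) with no taxa on the tree")
  D <- patristic_distances(tree)[colnames(m), colnames(m), drop = FALSE]
  pres <- m > 0
  f <- if (abundance_weighted) m / rowSums(m) else pres / rowSums(pres)
  B <- .bmntd_all_pairs(f, pres, D)
  as_dist_obj(B[lower.tri(B)], rownames(m), method = "betaMNTD")
}

#' beta nearest-taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a null in which taxon labels
#' are shuffled across the tips of the regional pool (all taxa in the
#' matrix), severing any link between phylogeny and abundance while keeping
#' both marginal structures:
#' `betaNTI = (obs - mean_null) / sd_null` per pair. `|betaNTI| > 2` is the
#' conventional evidence for selection (variable if > +2, homogeneous if
#' < -2). Pairs whose null has zero variance are reported as `NaN` with a
#' warning and excluded from downstream fractions.
#'
#' @inheritParams beta_mntd
#' @param n_null number of randomizations (>= 99; the field convention
#'   is 999).
#' @param seed optional integer seed.
#' @return object of class `beta_nti`: list with `bmntd` (observed dist),
#'   `bnti` (dist of standardized effect sizes), `n_null`, `n_undefined`,
#'   `seed`.
#' @export
beta_nti <- function(m, tree, abundance_weighted = TRUE, n_null = 999,
                     seed = NULL) {
  if (n_null < 99) stop("n_null must be >= 99")
  check_community(m, integer_counts = FALSE)
  validate_phylogeny(tree)
  m <- m[, colSums(m) > 0, drop = FALSE]
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  D <- patristic_distances(tree)[colnames(m), colnames(m), drop = FALSE]
  pres <- m > 0
  f <- if (abundance_weighted) m / rowSums(m) else pres / rowSums(pres)
  obs <- .bmntd_all_pairs(f, pres, D)

  S <- ncol(m)
  sum1 <- matrix(0, nrow(m), nrow(m))
  sum2 <- matrix(0, nrow(m), nrow(m))
  with_seed(seed, {
    for (k in seq_len(n_null)) {
      perm <- sample.int(S)
      Bk <- .bmntd_all_pairs(f, pres, D[perm, perm])
      sum1 <- sum1 + Bk
      sum2 <- sum2 + Bk^2
    }
  })
  mu <- sum1 / n_null
  sdv <- sqrt(pmax(sum2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NaN
  lab <- rownames(m)
  bnti <- as_dist_obj(z[lower.tri(z)], lab, method = "betaNTI")
  n_undef <- sum(!is.finite(bnti))
  if (n_undef > 0)
    warning(n_undef, " pair(s) with zero null variance; betaNTI undefined (NaN)")
  structure(list(bmntd = as_dist_obj(obs[lower.tri(obs)], lab, "betaMNTD"),
                 bnti = bnti, n_null = n_null, n_undefined = n_undef,
                 seed = seed),
            class = "beta_nti")
}

#' Abundance-based Raup-Crick (RC-Bray)
#'
#' Compares each pair's observed Bray-Curtis dissimilarity with a null
#' distribution built by probabilistic reassembly from the regional pool:
#' each null community keeps its sample's observed richness (taxa drawn
#' without replacement with probability proportional to regional occurrence
#' frequency) and observed total count (one read per drawn taxon, the
#' remainder allocated multinomially with probability proportional to
#' regional relative abundance renormalized over the drawn taxa). `RC = 2 * [(#null < obs) + 0.5 (#null = obs)] / n_null - 1`,
#' bounded in `[-1, +1]`; ties count half (standard Raup-Crick convention).
#' `RC < -0.95` indicates homogenizing dispersal, `RC > +0.95` dispersal
#' limitation.
#'
#' @param m samples x taxa integer count matrix.
#' @param n_null number of null randomizations (default 999).
#' @param seed optional integer seed.
#' @return object of class `rc_result`: list with `rc` (dist in `[-1, 1]`),
#'   `n_null`, `seed`.
#' @export
rc_bray <- function(m, n_null = 999, seed = NULL) {
  check_community(m)
  m <- m[, colSums(m) > 0, drop = FALSE]
  n <- nrow(m)
  obs <- as.vector(dissimilarity(m, "bray"))
  occ <- colMeans(m > 0)
  gamma <- colSums(m) / sum(m)
  rich <- rowSums(m > 0)
  totals <- rowSums(m)

  less <- numeric(length(obs))
  ties <- numeric(length(obs))
  with_seed(seed, {
    for (k in seq_len(n_null)) {
      null <- .null_abundance_matrix(m, occ, gamma, rich, totals)
      dk <- as.vector(dissimilarity(null, "bray"))
      less <- less + (dk < obs - 1e-12)
      ties <- ties + (abs(dk - obs) <= 1e-12)
    }
  })
  rc <- 2 * (less + 0.5 * ties) / n_null - 1
  structure(list(rc = as_dist_obj(rc, rownames(m), method = "RC-Bray"),
                 n_null = n_null, seed = seed),
            class = "rc_result")
}

# One richness- and total-preserving probabilistic null matrix.
.null_abundance_matrix <- function(m, occ, gamma, rich, totals) {
  S <- ncol(m)
  null <- matrix(0L, nrow(m), S, dimnames = dimnames(m))
  for (s in seq_len(nrow(m))) {
    sel <- sample.int(S, rich[s], prob = occ)
    # one read per selected taxon (richness preserved), remainder
    # proportional to regional relative abundance — Raup-Crick convention
    extra <- totals[s] - rich[s]
    null[s, sel] <- 1L + if (extra > 0)
      as.vector(stats::rmultinom(1, extra, prob = gamma[sel])) else 0L
  }
  null
}

#' Classify assembly processes per sample pair
#'
#' The two-step decision rule: `betaNTI > +2` = variable selection,
#' `betaNTI < -2` = homogeneous selection; otherwise (|betaNTI| <= 2, i.e.
#' selection weak) `RC > +0.95` = dispersal limitation, `RC < -0.95` =
#' homogenizing dispersal, and any remaining pair is "undominated" (weak
#' selection, weak dispersal, drift, diversification). Pairs with undefined
#' betaNTI are excluded from the fractions and counted separately.
#'
#' @param bnti a `beta_nti` object or a dist/matrix of betaNTI values.
#' @param rc an `rc_result` object or a dist/matrix of RC values.
#' @param bnti_threshold selection threshold (default 2).
#' @param rc_threshold dispersal threshold (default 0.95).
#' @return object of class `process_summary`: list with `pairs` (data.frame
#'   sample_i, sample_j, bnti, rc, process), `fractions` (named numeric
#'   summing to 1 over defined pairs), `n_pairs`, `n_undefined`.
#' @export
classify_processes <- function(bnti, rc, bnti_threshold = 2,
                               rc_threshold = 0.95) {
  bn <- if (inherits(bnti, "beta_nti")) bnti$bnti else stats::as.dist(bnti)
  rcv <- if (inherits(rc, "rc_result")) rc$rc else stats::as.dist(rc)
  if (length(bn) != length(rcv))
    stop("betaNTI and RC cover different numbers of sample pairs")
  labels <- attr(bn, "Labels") %||% as.character(seq_len(attr(bn, "Size")))
  pairs <- pair_index(labels)
  b <- as.vector(bn)
  r <- as.vector(rcv)
  proc <- rep(NA_character_, length(b))
  ok <- is.finite(b)
  proc[ok & b > bnti_threshold] <- "variable_selection"
  proc[ok & b < -bnti_threshold] <- "homogeneous_selection"
  weak <- ok & abs(b) <= bnti_threshold
  proc[weak & r > rc_threshold] <- "dispersal_limitation"
  proc[weak & r < -rc_threshold] <- "homogenizing_dispersal"
  proc[weak & abs(r) <= rc_threshold] <- "undominated"
  pairs$bnti <- b
  pairs$rc <- r
  pairs$process <- proc
  lev <- c("variable_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "undominated")
  counts <- table(factor(proc[ok], levels = lev))
  fractions <- if (sum(counts) > 0) as.numeric(counts) / sum(counts)
               else rep(NA_real_, length(lev))
  names(fractions) <- lev
  structure(list(pairs = pairs, fractions = fractions,
                 n_pairs = sum(ok), n_undefined = sum(!ok),
                 bnti_threshold = bnti_threshold, rc_threshold = rc_threshold),
            class = "process_summary")
}

#' @export
print.process_summary <- function(x, ...) {
  cat("assembly processes over", x$n_pairs, "sample pairs",
      if (x$n_undefined) sprintf("(%d undefined excluded)", x$n_undefined),
      "\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-22s %5.1f%%\n", nm, 100 * x$fractions[[nm]]))
  invisible(x)
}
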