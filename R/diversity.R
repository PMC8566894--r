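#' Alpha-diversity indices per sample
#'
#' Computes, at the taxon (OTU) level: richness `S`, Chao1
#' (`S + F1 (F1 - 1) / (2 (F2 + 1))`, the bias-corrected form), the
#' abundance-based coverage estimator ACE (rare-taxon cutoff 10), Shannon `H`
#' in nats, Pielou evenness `J = H / ln S`, and the Gini-Simpson index
#' `1 - sum p^2`. "Simpson diversity" here always means Gini-Simpson, the
#' common default in ecology packages.
#'
#' @param m samples x taxa integer count matrix (Chao1/ACE need true
#'   singleton and doubleton counts, so use unnormalized or rarefied counts,
#'   not relative abundances).
#' @return data.frame with one row per sample: `sample_id`, `richness`,
#'   `chao1`, `ace`, `shannon`, `pielou`, `gini_simpson`.
#' @examples
#' m <- matrix(c(5L, 1L, 1L, 2L), 1, 4,
#'             dimnames = list("s1", paste0("t", 1:4)))
#' alpha_diversity(m)$chao1 # 4.5
#' @export
alpha_diversity <- function(m) {
  check_community(m)
  if (any(rowSums(m) == 0)) stop("empty sample(s): ",
                                 paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  res <- lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    x <- x[x > 0]
    S <- length(x)
    p <- x / sum(x)
    F1 <- sum(x == 1)
    F2 <- sum(x == 2)
    chao1 <- S + F1 * (F1 - 1) / (2 * (F2 + 1))
    H <- -sum(p * log(p))
    data.frame(richness = S, chao1 = chao1, ace = .ace(x),
               shannon = H,
               pielou = if (S >= 2) H / log(S) else NA_real_,
               gini_simpson = 1 - sum(p^2))
  })
  cbind(data.frame(sample_id = rownames(m), stringsAsFactors = FALSE),
        do.call(rbind, res))
}

# ACE with the standard rare-abundance cutoff (<= 10 reads).
.ace <- function(x, cutoff = 10) {
  rare <- x[x <= cutoff]
  S_abund <- sum(x > cutoff)
  S_rare <- length(rare)
  if (S_rare == 0) return(S_abund)
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  C_ace <- 1 - F1 / N_rare
  if (C_ace == 0) return(NA_real_) # all rare taxa are singletons; undefined
  Fi <- tabulate(rare, nbins = cutoff)
  g2 <- max(S_rare / C_ace * sum(seq_len(cutoff) * (seq_len(cutoff) - 1) * Fi) /
              (N_rare * (N_rare - 1)) - 1, 0)
  if (!is.finite(g2)) g2 <- 0
  S_abund + S_rare / C_ace + F1 / C_ace * g2
}

#' Pairwise community dissimilarity
#'
#' The bounded dissimilarities the stochasticity analyses require, in both an
#' abundance variant (raw counts) and an incidence variant (presence/absence).
#' For count vectors x, y over M taxa:
#' \describe{
#'   \item{bray}{`sum |x-y| / sum (x+y)` (on presence/absence this is
#'     Sorensen).}
#'   \item{jaccard}{incidence: `(b+c)/(a+b+c)` with a shared, b/c unique
#'     presences; abundance: Ruzicka, `sum |x-y| / sum max(x,y)`.}
#'   \item{kulczynski}{`1 - (sum min / sum x + sum min / sum y) / 2`.}
#'   \item{gower}{`(1/M) sum |x-y| / R_k`, `R_k` the across-sample range of
#'     taxon k (zero-range terms contribute 0).}
#'   \item{manhattan}{`(1/M) sum |x-y| / max_k`, `max_k` the across-sample
#'     maximum of taxon k (normalized so values stay in `[0,1]`).}
#'   \item{canberra}{`(1/M') sum_{x+y>0} |x-y| / (x+y)`, `M'` the number of
#'     taxa present in at least one of the pair.}
#' }
#' All values lie in `[0, 1]`, as the NST normalization requires.
#'
#' @param m samples x taxa count matrix (>= 2 samples).
#' @param metric one of `"bray"`, `"jaccard"`, `"kulczynski"`, `"gower"`,
#'   `"manhattan"`, `"canberra"`.
#' @param variant `"abundance"` (default) or `"incidence"`.
#' @return a [stats::dist] object with sample labels and attributes `metric`
#'   and `variant`.
#' @examples
#' m <- rbind(s1 = c(1, 2, 0), s2 = c(3, 0, 0))
#' colnames(m) <- paste0("t", 1:3)
#' dissimilarity(m, "bray") # 2/3
#' @export
dissimilarity <- function(m, metric = c("bray", "jaccard", "kulczynski",
                                        "gower", "manhattan", "canberra"),
                          variant = c("abundance", "incidence")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  check_community(m, integer_counts = FALSE)
  if (nrow(m) < 2) stop("need at least 2 samples")
  x <- if (variant == "incidence") (m > 0) * 1 else m
  M <- ncol(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  cmx <- apply(x, 2, max)

  n <- nrow(x)
  vals <- numeric(n * (n - 1) / 2)
  k <- 0L
  warned <- FALSE
  for (j in seq_len(n - 1)) {
    for (i in seq((j + 1), n)) {
      k <- k + 1L
      a <- x[j, ]; b <- x[i, ]
      s <- a + b
      if (all(s == 0)) {
        if (!warned) { warning("all-zero sample pair; dissimilarity set to 0"); warned <- TRUE }
        vals[k] <- 0
        next
      }
      vals[k] <- switch(metric,
        bray = sum(abs(a - b)) / sum(s),
        jaccard = {
          if (variant == "incidence") {
            shared <- sum(a > 0 & b > 0)
            uniq <- sum(xor(a > 0, b > 0))
            uniq / (shared + uniq)
          } else {
            sum(abs(a - b)) / sum(pmax(a, b))
          }
        },
        kulczynski = {
          if (sum(a) == 0 || sum(b) == 0) 1 else {
            smin <- sum(pmin(a, b))
            1 - (smin / sum(a) + smin / sum(b)) / 2
          }
        },
        gower = {
          ok <- rng > 0
          if (!any(ok)) 0 else sum(abs(a[ok] - b[ok]) / rng[ok]) / M
        },
        manhattan = {
          ok <- cmx > 0
          if (!any(ok)) 0 else sum(abs(a[ok] - b[ok]) / cmx[ok]) / M
        },
        canberra = {
          ok <- s > 0
          sum(abs(a[ok] - b[ok]) / s[ok]) / sum(ok)
        })
    }
  }
  d <- as_dist_obj(vals, rownames(x), method = metric)
  attr(d, "metric") <- metric
  attr(d, "variant") <- variant
  stopifnot(all(vals >= -1e-12 & vals <= 1 + 1e-12))
  d
}
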