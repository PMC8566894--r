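# Deterministic-driver statistics: Mantel and PERMANOVA over distance
# matrices, and the thresholded Spearman co-occurrence network with
# node-level topology.

#' Mantel test between two distance matrices
#'
#' Correlation between corresponding off-diagonal entries, with significance
#' from simultaneous row/column permutation of one matrix (delegated to
#' [vegan::mantel()]); `p = (1 + #{r_null >= r_obs}) / (1 + n_perm)`.
#'
#' @param d1,d2 `dist` objects (or symmetric matrices) over the same samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `statistic`, `p_value`, `method`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  d1 <- stats::as.dist(d1)
  d2 <- stats::as.dist(d2)
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2)) stop("sample ids of the two matrices differ")
    d2 <- stats::as.dist(as.matrix(d2)[l1, l1])
  } else if (attr(d1, "Size") != attr(d2, "Size")) {
    stop("distance matrices have different sizes")
  }
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0)
    stop("constant distance matrix; Mantel correlation undefined")
  fit <- with_seed(seed, vegan::mantel(d1, d2, method = method,
                                       permutations = n_perm))
  list(statistic = unname(fit$statistic), p_value = fit$signif,
       method = method, n_perm = n_perm)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F from the
#' between/within-group sums of squared distances with significance by label
#' permutation (delegated to [vegan::adonis2()]).
#'
#' @param d a `dist` over samples.
#' @param groups group label per sample (aligned with the labels of `d`).
#' @param n_perm number of permutations (default 9999, the survey
#'   convention).
#' @param seed optional integer seed.
#' @return list with `F`, `R2`, `p_value`, `n_perm`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size"))
    stop("groups length does not match the distance matrix")
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("singleton group(s): ",
    paste(names(which(table(groups) < 2)), collapse = ", "))
  tab <- with_seed(seed, vegan::adonis2(d ~ groups, permutations = n_perm))
  list(F = tab$F[1], R2 = tab$R2[1], p_value = tab$`Pr(>F)`[1],
       n_perm = n_perm, df = tab$Df[1])
}

#' Thresholded Spearman co-occurrence network
#'
#' Computes pairwise Spearman rank correlations among taxa (filtered to total
#' count > `min_reads`) and, optionally, between taxa and numeric
#' environmental variables, and keeps every edge that is both robust
#' (`|r| > r_threshold`) and significant (`p < p_threshold`, two-sided t
#' approximation on the rank correlation; no multiple-testing correction, by
#' convention — set `adjust = "BH"` to change that). Constant vectors are
#' skipped with a warning.
#'
#' @param m samples x taxa count matrix (>= 5 samples).
#' @param env optional metadata data.frame (`sample_id` column + numeric
#'   variables).
#' @param r_threshold minimum |r| for an edge (default 0.5).
#' @param p_threshold maximum p for an edge (default 0.05).
#' @param min_reads taxa with total count <= this are excluded (default 10).
#' @param adjust p-value adjustment method (default `"none"`).
#' @return object of class `cooccurrence_network`: list with `graph` (an
#'   [igraph] undirected graph; vertex attribute `type` is `"taxon"` or
#'   `"env"`; edge attributes `r`, `p`, `sign`), `edges` (data.frame),
#'   `nodes`, and the thresholds used.
#' @export
correlation_network <- function(m, env = NULL, r_threshold = 0.5,
                                p_threshold = 0.05, min_reads = 10,
                                adjust = "none") {
  check_community(m, integer_counts = FALSE)
  if (nrow(m) < 5) stop("need >= 5 samples")
  keep <- colSums(m) > min_reads
  dat <- m[, keep, drop = FALSE]
  types <- rep("taxon", ncol(dat))
  if (!is.null(env)) {
    stopifnot("sample_id" %in% colnames(env))
    ev <- env[match(rownames(m), env$sample_id), , drop = FALSE]
    num <- vapply(ev, is.numeric, logical(1)) & colnames(ev) != "sample_id"
    if (any(num)) {
      dat <- cbind(dat, as.matrix(ev[, num, drop = FALSE]))
      types <- c(types, rep("env", sum(num)))
    }
  }
  const <- apply(dat, 2, function(x) stats::sd(x) == 0 || anyNA(x))
  if (any(const)) {
    warning("constant or missing columns skipped: ",
            paste(colnames(dat)[const], collapse = ", "))
    dat <- dat[, !const, drop = FALSE]
    types <- types[!const]
  }
  n <- nrow(dat)
  rk <- apply(dat, 2, rank)
  R <- stats::cor(rk)
  # two-sided p from the t approximation; |r| = 1 maps to p = 0
  tstat <- abs(R) * sqrt((n - 2) / pmax(1 - R^2, 1e-300))
  P <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  P[abs(R) >= 1 - 1e-12] <- 0

  idx <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[idx]
  p <- stats::p.adjust(P[idx], method = adjust)
  pass <- abs(r) > r_threshold & p < p_threshold
  edges <- data.frame(source = colnames(dat)[idx[pass, 1]],
                      target = colnames(dat)[idx[pass, 2]],
                      r = r[pass], p = p[pass],
                      sign = ifelse(r[pass] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(node = colnames(dat), type = types,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 min_reads = min_reads),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes (%d taxa, %d env), %d edges (|r| > %s, p < %s)\n",
              nrow(x$nodes), sum(x$nodes$type == "taxon"),
              sum(x$nodes$type == "env"), nrow(x$edges),
              x$r_threshold, x$p_threshold))
  invisible(x)
}

#' Node-level topology metrics
#'
#' Degree, shortest-path betweenness (unnormalized by default), closeness
#' (within each connected component) and eigenvector centrality (principal
#' eigenvector per component), computed on the undirected unweighted graph.
#'
#' @param net a `cooccurrence_network` or an igraph graph.
#' @param normalized_betweenness normalize betweenness (default `FALSE`).
#' @return data.frame: `node`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector`.
#' @export
node_topology <- function(net, normalized_betweenness = FALSE) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  if (igraph::vcount(g) == 0) stop("empty network")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA,
                             normalized = normalized_betweenness)
  comp <- igraph::components(g)$membership
  clo <- rep(NA_real_, igraph::vcount(g))
  eig <- rep(0, igraph::vcount(g))
  for (cid in unique(comp)) {
    vids <- which(comp == cid)
    sub <- igraph::induced_subgraph(g, vids)
    if (length(vids) > 1) {
      clo[vids] <- igraph::closeness(sub, weights = NA)
      # principal eigenvector of the component adjacency, computed with a
      # dense symmetric eigensolver for deterministic output
      A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = FALSE))
      ev <- eigen(A, symmetric = TRUE)$vectors[, 1]
      ev <- abs(ev)
      eig[vids] <- if (max(ev) > 0) ev / max(ev) else 0
    } else {
      clo[vids] <- NA_real_
      eig[vids] <- 0
    }
  }
  data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
             betweenness = unname(btw), closeness = unname(clo),
             eigenvector = unname(eig), stringsAsFactors = FALSE)
}

#' Induced subnetwork
#'
#' Keeps exactly the edges with both endpoints in `nodes` (e.g. the taxa of
#' one sublineage), preserving node and edge attributes.
#'
#' @param net a `cooccurrence_network`.
#' @param nodes character vector of node ids (must all exist).
#' @return a `cooccurrence_network` over the induced subgraph.
#' @export
subnetwork <- function(net, nodes) {
  stopifnot(inherits(net, "cooccurrence_network"))
  unknown <- setdiff(nodes, net$nodes$node)
  if (length(unknown)) stop("unknown node ids: ", paste(unknown, collapse = ", "))
  g <- igraph::induced_subgraph(net$graph, nodes)
  keep_e <- net$edges$source %in% nodes & net$edges$target %in% nodes
  structure(list(graph = g, edges = net$edges[keep_e, , drop = FALSE],
                 nodes = net$nodes[net$nodes$node %in% nodes, , drop = FALSE],
                 r_threshold = net$r_threshold, p_threshold = net$p_threshold,
                 min_reads = net$min_reads),
            class = "cooccurrence_network")
}

#' Write a network as an edge list and GraphML
#'
#' @param net a `cooccurrence_network`.
#' @param edge_path TSV path for the edge list (source, target, r, p, sign).
#' @param graphml_path optional GraphML path.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  invisible(edge_path)
}
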