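test_that("Mantel detects perfect monotone association at the floor", {
  set.seed(3)
  d1 <- stats::dist(matrix(stats::rnorm(30), 10))
  attr(d1, "Labels") <- paste0("s", 1:10)
  r <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 1)
  expect_equal(r$statistic, 1, tolerance = 1e-12)
  expect_equal(r$p_value, 1 / 100) # permutation floor

  const <- d1; const[] <- 0.5
  expect_error(mantel_test(d1, const), "constant")
  expect_error(mantel_test(d1, stats::dist(matrix(stats::rnorm(8), 4))),
               "different")
})

test_that("PERMANOVA separates structured groups and respects the floor", {
  set.seed(4)
  x <- rbind(matrix(stats::rnorm(30, 0), 10), matrix(stats::rnorm(30, 8), 10))
  d <- stats::dist(x)
  g <- rep(c("a", "b"), each = 10)
  r <- permanova(d, g, n_perm = 999, seed = 2)
  expect_gt(r$F, 50)
  expect_equal(r$p_value, 1 / 1000) # 10+10 groups: duplicate partitions negligible
  expect_error(permanova(d, c("a", rep("b", 19))), "singleton")
  expect_error(permanova(d, rep("a", 20)), ">= 2 groups")
})

test_that("Mantel and PERMANOVA type-I errors are calibrated", {
  set.seed(5)
  rej <- replicate(300, {
    d1 <- stats::dist(matrix(stats::rnorm(30), 10))
    d2 <- stats::dist(matrix(stats::rnorm(30), 10))
    attr(d1, "Labels") <- attr(d2, "Labels") <- paste0("s", 1:10)
    c(mantel_test(d1, d2, n_perm = 99)$p_value <= 0.05,
      permanova(d1, rep(1:2, each = 5), n_perm = 99)$p_value <= 0.05)
  })
  expect_gt(mean(rej[1, ]), 0.02); expect_lt(mean(rej[1, ]), 0.09)
  expect_gt(mean(rej[2, ]), 0.02); expect_lt(mean(rej[2, ]), 0.09)
})

test_that("network edges obey both thresholds with correct signs", {
  set.seed(6)
  n <- 30
  base <- sample(n) # distinct ranks
  m <- cbind(t1 = as.integer(base * 3),      # identical ranks to base
             t2 = as.integer(base + 5),      # identical ranks to base
             t3 = as.integer(n - base + 10), # reversed ranks
             t4 = as.integer(stats::rpois(n, 20)),
             t5 = as.integer(stats::rpois(n, 20)))
  rownames(m) <- paste0("s", 1:n)
  net <- correlation_network(m, env = NULL, min_reads = 0)
  e <- net$edges
  key <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
  expect_true("t1 t2" %in% key)
  expect_equal(e$r[key == "t1 t2"], 1)
  expect_equal(e$sign[key == "t1 t3"], "negative")
  expect_true(all(abs(e$r) > net$r_threshold & e$p < net$p_threshold))

  # constant column skipped with warning
  m2 <- cbind(m, t6 = 5L)
  expect_warning(correlation_network(m2, min_reads = 0), "constant")
})

test_that("spurious edge rate among independent taxa matches the thresholds", {
  # null edge probability at n = 30, |r| > 0.5 & p < 0.05 is P(|r| > 0.5)
  # for independent Spearman ranks: ~ 0.005 (normal approx sd = 1/sqrt(29))
  set.seed(7)
  frac <- mean(replicate(60, {
    m <- matrix(as.integer(stats::rpois(30 * 12, 20)), 30, 12,
                dimnames = list(paste0("s", 1:30), paste0("t", 1:12)))
    nrow(correlation_network(m, min_reads = 0)$edges) / choose(12, 2)
  }))
  expect_lt(frac, 0.03)
})

test_that("topology metrics match hand graphs", {
  path_net <- structure(list(
    graph = igraph::make_graph(c("A", "B", "B", "C"), directed = FALSE),
    edges = data.frame(), nodes = data.frame(node = c("A", "B", "C")),
    r_threshold = 0.5, p_threshold = 0.05, min_reads = 10),
    class = "cooccurrence_network")
  tp <- node_topology(path_net)
  expect_equal(tp$degree[tp$node == "B"], 2L)
  expect_equal(tp$betweenness[tp$node == "B"], 1)
  expect_equal(tp$degree[tp$node == "A"], 1L)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  tk <- node_topology(k4)
  expect_true(all(tk$betweenness == 0))
  expect_true(all(tk$degree == 3L))
  expect_equal(tk$eigenvector, rep(1, 4)) # symmetric: all maximal

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:5)
  ts <- node_topology(star)
  expect_equal(ts$node[which.max(ts$eigenvector)], "v1")
})

test_that("subnetworks are induced subgraphs", {
  tri <- structure(list(
    graph = igraph::make_graph(c("A", "B", "B", "C", "A", "C"), directed = FALSE),
    edges = data.frame(source = c("A", "B", "A"), target = c("B", "C", "C"),
                       r = c(0.9, 0.8, 0.7), p = c(0.001, 0.002, 0.003),
                       sign = "positive", stringsAsFactors = FALSE),
    nodes = data.frame(node = c("A", "B", "C"), type = "taxon",
                       stringsAsFactors = FALSE),
    r_threshold = 0.5, p_threshold = 0.05, min_reads = 10),
    class = "cooccurrence_network")
  sub <- subnetwork(tri, c("A", "B"))
  expect_equal(nrow(sub$edges), 1)
  expect_equal(igraph::ecount(sub$graph), 1)
  full <- subnetwork(tri, c("A", "B", "C"))
  expect_equal(igraph::ecount(full$graph), 3)
  empty <- subnetwork(tri, character(0))
  expect_equal(igraph::vcount(empty$graph), 0)
  expect_error(subnetwork(tri, c("A", "Z")), "unknown node")
})
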