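test_that("Yule trees are binary, labeled and reproducible", {
  expect_error(simulate_yule_tree(1), ">= 2")
  t2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  t100 <- simulate_yule_tree(100, seed = 3)
  expect_equal(t100$Nnode, 99) # binary: n-1 internal nodes
  expect_setequal(t100$tip.label, paste0("OTU_", 1:100))
  expect_true(all(t100$edge.length > 0))
  expect_identical(ape::write.tree(simulate_yule_tree(20, seed = 5)),
                   ape::write.tree(simulate_yule_tree(20, seed = 5)))
})

test_that("BM traits have the closed-form cherry variance and BM covariance", {
  tree <- toy_tree() # ((A:1,B:1):1,C:2)
  expect_equal(unname(simulate_bm_trait(tree, 0, root = 3, seed = 1)),
               rep(3, 3)) # zero-variance limit

  diffs <- vapply(1:5000, function(i) {
    tr <- simulate_bm_trait(tree, sigma2 = 2, root = 0, seed = i)
    tr["A"] - tr["B"]
  }, numeric(1))
  # Var(A - B) = 2 * sigma2 * b = 4 on the cherry with b = 1
  expect_equal(stats::var(diffs), 4, tolerance = 0.12)

  # sister tips covary more than distant tips
  reps <- vapply(1:2000, function(i) simulate_bm_trait(tree, 1, 0, seed = 10000 + i),
                 numeric(3))
  expect_gt(stats::cov(reps["A", ], reps["B", ]), stats::cov(reps["A", ], reps["C", ]))
})

test_that("metacommunity abundances are normalized and skew grows with sigma", {
  gam <- build_metacommunity(50, 0, seed = 1)
  expect_equal(unname(gam), rep(1 / 50, 50), tolerance = 1e-12)
  gini <- function(x) {
    n <- length(x); x <- sort(x)
    2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
  }
  g_small <- vapply(1:100, function(i) gini(build_metacommunity(50, 0.5, seed = i)), 1)
  g_big <- vapply(1:100, function(i) gini(build_metacommunity(50, 2, seed = i)), 1)
  expect_equal(sum(build_metacommunity(30, 1.5, seed = 9)), 1, tolerance = 1e-12)
  expect_gt(mean(g_big), mean(g_small))
})

test_that("neutral Moran dynamics conserve N and hit both limits", {
  meta <- build_metacommunity(20, 1, seed = 2)
  x <- simulate_neutral_community(meta, N = 500, m = 0.5, generations = 10, seed = 3)
  expect_equal(sum(x), 500)
  expect_error(simulate_neutral_community(meta, 500, m = 1.5), "m must be")

  # m = 1: stationary counts are multinomial(N, gamma)
  reps <- vapply(1:1000, function(i)
    simulate_neutral_community(meta, N = 100, m = 1, generations = 2, seed = i),
    integer(20))
  expect_equal(unname(rowMeans(reps)), unname(100 * meta), tolerance = 0.12)

  # m = 0, long drift: fixation (monodominance) is the rule
  mono <- mean(vapply(1:60, function(i) {
    x <- simulate_neutral_community(build_metacommunity(5, 0.5, seed = 1),
                                    N = 30, m = 0, generations = 100, seed = i)
    max(x) == sum(x)
  }, logical(1)))
  expect_gt(mono, 0.9)
})

test_that("Gaussian filtering reduces to the right limits", {
  meta <- build_metacommunity(30, 1, seed = 4)
  traits <- stats::setNames(seq(20, 30, length.out = 30), names(meta))

  # sigma_w -> Inf reduces to multinomial(N, gamma)
  wide <- vapply(1:500, function(i)
    simulate_selected_community(meta, traits, env = 25, sigma_w = 1e6,
                                N = 200, seed = i), integer(30))
  expect_equal(unname(rowMeans(wide)), unname(200 * meta), tolerance = 0.15)

  # delta-filter limit: taxon at env takes (almost) everything
  narrow <- simulate_selected_community(meta, traits, env = traits[7],
                                        sigma_w = 1e-3, N = 200, seed = 1)
  expect_equal(unname(narrow[7]), 200)
  expect_error(simulate_selected_community(meta, traits, env = 1e6,
                                           sigma_w = 1e-3, N = 100),
               "sigma_w")
})

test_that("selection separates groups in composition", {
  ds <- simulate_dataset(16, 60, "variable_selection", m = 0.3, sigma_w = 0.5,
                         N = 2000, depth = 1000, generations = 20,
                         lognormal_sigma = 1, seed = 5)
  D <- as.matrix(dissimilarity(ds$community, "bray"))
  g <- ds$env$group
  between <- mean(D[g == "cold", g == "warm"])
  wc <- D[g == "cold", g == "cold"]; ww <- D[g == "warm", g == "warm"]
  within <- mean(c(wc[lower.tri(wc)], ww[lower.tri(ww)]))
  expect_gt(between, within)
})

test_that("datasets are deterministic and structurally complete", {
  a <- simulate_dataset(8, 25, "neutral", m = 0.5, N = 500, depth = 400,
                        generations = 10, lognormal_sigma = 1, seed = 11)
  b <- simulate_dataset(8, 25, "neutral", m = 0.5, N = 500, depth = 400,
                        generations = 10, lognormal_sigma = 1, seed = 11)
  expect_identical(a$community, b$community)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_equal(a$env, b$env)
  expect_true(all(rowSums(a$community) == 400))
  expect_equal(a$regime, "neutral")
  expect_setequal(colnames(a$community), a$tree$tip.label)

  # fixture files byte-identical across regenerations
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(a, d1); write_dataset(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("neutral occupancy increases with metacommunity abundance", {
  ds <- simulate_dataset(30, 80, "neutral", m = 0.5, N = 2000, depth = 1000,
                         generations = 20, lognormal_sigma = 1.5, seed = 13)
  occ <- colMeans(ds$community > 0)
  p <- colMeans(ds$community / rowSums(ds$community))
  expect_gt(stats::cor(log(p[p > 0]), occ[p > 0], method = "spearman"), 0.8)
})
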