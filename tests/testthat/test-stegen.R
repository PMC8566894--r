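test_that("betaMNTD matches hand computation and forced cases", {
  tree <- toy_tree()
  # k = {A}, l = {B, C}, equal weights: 0.5*[min(2,4) + (0.5*2 + 0.5*4)] = 2.5
  cm <- rbind(k = c(A = 1L, B = 0L, C = 0L), l = c(A = 0L, B = 1L, C = 1L))
  expect_equal(as.vector(beta_mntd(cm, tree)), 2.5, tolerance = 1e-12)

  # identical single-taxon communities: zero turnover
  same <- rbind(k = c(A = 3L, B = 0L, C = 0L), l = c(A = 7L, B = 0L, C = 0L))
  expect_equal(as.vector(beta_mntd(same, tree)), 0)

  # star tree with equal branches b: disjoint singletons give 2b... the
  # patristic distance between any two tips is 2b and both directions agree
  star <- ape::read.tree(text = "(A:3,B:3,C:3);")
  disj <- rbind(k = c(A = 1L, B = 0L, C = 0L), l = c(A = 0L, B = 1L, C = 0L))
  expect_equal(as.vector(beta_mntd(disj, star)), 6)

  bad <- rbind(k = c(A = 1L, X = 1L), l = c(A = 1L, X = 0L))
  expect_error(beta_mntd(bad, tree), "absent from the tree")
})

test_that("betaMNTD agrees with picante::comdistnt", {
  skip_if_not_installed("picante")
  ds <- small_neutral(seed = 8)
  D <- patristic_distances(ds$tree)
  mine <- as.matrix(beta_mntd(ds$community, ds$tree, abundance_weighted = TRUE))
  ref <- as.matrix(picante::comdistnt(ds$community, D, abundance.weighted = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10)

  # unweighted variant against a direct oracle (mean of the two directional
  # mean nearest-taxon distances; picante pools both directions instead)
  m <- ds$community[, colSums(ds$community) > 0]
  i <- rownames(m)[1]; j <- rownames(m)[4]
  pk <- colnames(m)[m[i, ] > 0]; pl <- colnames(m)[m[j, ] > 0]
  oracle <- (mean(vapply(pk, function(t) min(D[t, pl]), 1)) +
             mean(vapply(pl, function(t) min(D[t, pk]), 1))) / 2
  mine_u <- as.matrix(beta_mntd(ds$community, ds$tree, abundance_weighted = FALSE))
  expect_equal(mine_u[i, j], oracle, tolerance = 1e-12)
})

test_that("betaNTI flags zero-variance nulls and centers on label-shuffled data", {
  # star tree: every tip pair equidistant, so the null cannot vary
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  cm <- rbind(k = c(A = 1L, B = 1L, C = 0L, D = 0L),
              l = c(A = 0L, B = 0L, C = 1L, D = 1L))
  expect_warning(r <- beta_nti(cm, star, n_null = 99, seed = 1),
                 "zero null variance")
  expect_true(is.nan(as.vector(r$bnti)))
  expect_equal(r$n_undefined, 1)

  # phylogeny-free data: betaNTI roughly standard normal across pairs
  ds <- small_neutral(seed = 12, n_samples = 14, n_taxa = 60)
  r2 <- suppressWarnings(beta_nti(ds$community, ds$tree, n_null = 199, seed = 2))
  v <- as.vector(r2$bnti)
  v <- v[is.finite(v)]
  expect_lt(abs(mean(v)), 0.8)
  expect_gt(stats::sd(v), 0.4)
  expect_lt(stats::sd(v), 2.2)

  # determinism under seed
  r3 <- suppressWarnings(beta_nti(ds$community, ds$tree, n_null = 199, seed = 2))
  expect_identical(as.vector(r2$bnti), as.vector(r3$bnti))
})

test_that("RC-Bray respects bounds and boundary logic", {
  ds <- small_neutral(seed = 4, n_samples = 10, n_taxa = 30)
  r <- rc_bray(ds$community, n_null = 99, seed = 5)
  v <- as.vector(r$rc)
  expect_true(all(v >= -1 & v <= 1))
  expect_identical(as.vector(rc_bray(ds$community, n_null = 99, seed = 5)$rc), v)

  # two identical high-coverage samples: observed Bray (0) below every
  # null draw -> RC = -1
  ident <- rbind(a = c(50L, 30L, 20L, 10L, 5L), b = c(50L, 30L, 20L, 10L, 5L),
                 c = c(30L, 50L, 10L, 20L, 5L))
  colnames(ident) <- paste0("t", 1:5)
  rc <- as.matrix(rc_bray(ident, n_null = 99, seed = 1)$rc)
  expect_equal(rc["a", "b"], -1)
})

test_that("process classification applies the documented thresholds", {
  lab <- function(b, r) {
    bn <- matrix(c(0, b, b, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
    rc <- matrix(c(0, r, r, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
    classify_processes(bn, rc)$pairs$process
  }
  expect_equal(lab(2.5, 0), "variable_selection")
  expect_equal(lab(-2.5, -0.99), "homogeneous_selection")
  expect_equal(lab(-1.0, -0.97), "homogenizing_dispersal")
  expect_equal(lab(1.0, 0.97), "dispersal_limitation")
  expect_equal(lab(0.5, 0.2), "undominated")
  # boundary: |bnti| = 2 is not selection; |rc| = 0.95 is not dispersal
  expect_equal(lab(2, 0.95), "undominated")

  # fractions sum to one and undefined pairs are excluded but counted
  bn <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  bn[1, 2] <- bn[2, 1] <- 2.5; bn[1, 3] <- bn[3, 1] <- NaN
  rc <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cls <- classify_processes(bn, rc)
  expect_equal(sum(cls$fractions), 1, tolerance = 1e-12)
  expect_equal(cls$n_undefined, 1)
  expect_equal(cls$n_pairs, 2)
})
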