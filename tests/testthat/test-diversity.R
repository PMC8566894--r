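# Hand-computed oracles on the documented 3x4 matrix:
#   s1 = (5,1,1,2), s2 = (1,2,0,3), s3 = (0,0,4,4)
# column ranges 5,2,4,2; column maxima 5,2,4,4.

test_that("alpha indices match hand-computed values", {
  a <- alpha_diversity(toy_matrix())
  s1 <- a[a$sample_id == "s1", ]
  expect_equal(s1$richness, 4)
  expect_equal(s1$chao1, 4.5, tolerance = 1e-12) # 4 + 2*1/(2*(1+1))
  expect_equal(s1$ace, 324 / 49, tolerance = 1e-12)
  H <- -(5 / 9 * log(5 / 9) + 2 / 9 * log(1 / 9) + 2 / 9 * log(2 / 9))
  expect_equal(s1$shannon, H, tolerance = 1e-12)
  expect_equal(s1$pielou, H / log(4), tolerance = 1e-12)
  expect_equal(s1$gini_simpson, 50 / 81, tolerance = 1e-12)
})

test_that("alpha indices handle degenerate and even communities", {
  even <- matrix(rep(3L, 5), 1, 5, dimnames = list("s", paste0("t", 1:5)))
  a <- alpha_diversity(even)
  expect_equal(a$pielou, 1)
  expect_equal(a$gini_simpson, 1 - 1 / 5)

  single <- matrix(c(9L, 0L), 1, 2, dimnames = list("s", c("a", "b")))
  a1 <- alpha_diversity(single)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$gini_simpson, 0)
  expect_equal(a1$chao1, a1$richness) # F1 = 0

  expect_error(alpha_diversity(rbind(s = c(a = 0L, b = 0L))), "empty")
})

test_that("dissimilarities match hand-computed values on the toy pair", {
  m <- toy_matrix()
  d12 <- function(metric, variant = "abundance")
    as.matrix(dissimilarity(m, metric, variant))["s1", "s2"]
  expect_equal(d12("bray"), 7 / 15, tolerance = 1e-12)
  expect_equal(d12("jaccard", "incidence"), 1 / 4, tolerance = 1e-12)
  expect_equal(d12("jaccard"), 7 / 11, tolerance = 1e-12) # Ruzicka
  expect_equal(d12("kulczynski"), 4 / 9, tolerance = 1e-12)
  expect_equal(d12("canberra"), 11 / 20, tolerance = 1e-12)
  expect_equal(d12("gower"), 41 / 80, tolerance = 1e-12)
  expect_equal(d12("manhattan"), 9 / 20, tolerance = 1e-12)

  # x=(1,2,0), y=(3,0,0): bray = (2+2+0)/(4+2) = 2/3
  m2 <- rbind(a = c(1, 2, 0), b = c(3, 0, 0))
  colnames(m2) <- paste0("t", 1:3)
  expect_equal(as.vector(dissimilarity(m2, "bray")), 2 / 3, tolerance = 1e-12)
})

test_that("dissimilarity limits: identical, disjoint, all-zero pairs", {
  m <- rbind(a = c(2, 3, 0, 0), b = c(2, 3, 0, 0), c = c(0, 0, 1, 4))
  colnames(m) <- paste0("t", 1:4)
  for (metric in c("bray", "jaccard", "kulczynski", "gower", "manhattan",
                   "canberra")) {
    D <- as.matrix(dissimilarity(m, metric))
    expect_equal(D["a", "b"], 0, info = metric)
  }
  expect_equal(as.matrix(dissimilarity(m, "bray"))["a", "c"], 1)
  expect_equal(as.matrix(dissimilarity(m, "jaccard", "incidence"))["a", "c"], 1)

  z <- rbind(a = c(1, 0), b = c(0, 0), c = c(0, 0))
  colnames(z) <- c("t1", "t2")
  expect_warning(dz <- dissimilarity(z, "bray"), "all-zero")
  expect_equal(as.matrix(dz)["b", "c"], 0)
})

test_that("dissimilarity invariants hold across metrics and variants", {
  ds <- small_neutral()
  m <- ds$community
  for (metric in c("bray", "jaccard", "kulczynski", "gower", "manhattan",
                   "canberra")) {
    for (variant in c("abundance", "incidence")) {
      d <- dissimilarity(m, metric, variant)
      v <- as.vector(d)
      expect_true(all(v >= 0 & v <= 1), info = paste(metric, variant))
      M <- as.matrix(d)
      expect_equal(M, t(M), info = metric)
      expect_true(all(diag(M) == 0))
    }
  }
  # incidence bray is Sorensen; jaccard >= sorensen pairwise
  so <- as.vector(dissimilarity(m, "bray", "incidence"))
  ja <- as.vector(dissimilarity(m, "jaccard", "incidence"))
  expect_true(all(ja >= so - 1e-12))
})

test_that("bray and incidence jaccard agree with vegan", {
  m <- small_neutral(seed = 7)$community
  expect_equal(as.vector(dissimilarity(m, "bray")),
               as.vector(vegan::vegdist(m, "bray")), tolerance = 1e-12)
  expect_equal(as.vector(dissimilarity(m, "jaccard", "incidence")),
               as.vector(vegan::vegdist(m, "jaccard", binary = TRUE)),
               tolerance = 1e-12)
})
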