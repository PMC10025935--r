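test_that("transition distributions shrink other species and inflate self", {
  m <- sourceModel(c(A = 0.5, B = 0.3, C = 0.2), s = 0.77)
  d <- transitionDistribution("A", m)
  expect_equal(d, c(A = 0.615, B = 0.231, C = 0.154))
  expect_equal(sum(d), 1, tolerance = 1e-12)
  # s = 1 recovers the abundance profile for every previous species
  m1 <- sourceModel(c(A = 0.5, B = 0.3, C = 0.2), s = 1)
  for (sp in c("A", "B", "C"))
    expect_equal(transitionDistribution(sp, m1), abundances(m1))
  # degenerate single-species model
  expect_equal(transitionDistribution("A", sourceModel(c(A = 1), s = 0.5)),
               c(A = 1))
  expect_error(transitionDistribution("Z", m), "unknown species")
})

test_that("transition rows are distributions and the chain is stationary at the abundance", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(2:8, 1)
    p <- abundanceProfile(setNames(runif(n, 0.05, 1), paste0("s", 1:n)))
    m <- sourceModel(p, s = runif(1, 0.1, 1))
    P <- transitionMatrix(m)
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, n), tolerance = 1e-12)
    # left eigenvector for eigenvalue 1 equals the abundance profile
    e <- eigen(t(P))
    i <- which.min(abs(e$values - 1))
    pi_ <- Re(e$vectors[, i])
    pi_ <- pi_ / sum(pi_)
    expect_equal(pi_, unname(abundances(p)), tolerance = 1e-9)
  }
})

test_that("the shrinkage estimator reproduces hand-computed values", {
  pairs <- rbind(cbind(rep("A", 100), c(rep("B", 40), rep("A", 60))),
                 cbind(rep("B", 100), c(rep("A", 35), rep("B", 65))))
  # s_A = 0.40/0.5 = 0.8, s_B = 0.35/0.5 = 0.7, mean = 0.75
  expect_equal(learnShrinkage(pairs, c(A = 0.5, B = 0.5)), 0.75)
  est <- learnShrinkage(pairs, c(A = 0.5, B = 0.5), per_species = TRUE)
  expect_equal(est$per_species, c(A = 0.8, B = 0.7))
  expect_error(learnShrinkage(pairs, c(A = 0.5, B = 0.5), min_pairs = 1000),
               "fallback")
  expect_error(learnShrinkage(pairs[0, , drop = FALSE], c(A = 1)),
               "non-empty")
})

test_that("shrinkage recovery is consistent at the homogeneous limit and under s < 1", {
  prof <- log_profile()
  set.seed(33)
  m1 <- sourceModel(prof, s = 1)
  s_hat <- learnShrinkage(sampleSegmentPairs(50000, m1), prof)
  expect_lt(abs(s_hat - 1), 0.02)
  m77 <- sourceModel(prof, s = 0.77)
  s_hat77 <- learnShrinkage(sampleSegmentPairs(50000, m77), prof)
  expect_lt(abs(s_hat77 - 0.77), 0.02)
})

test_that("species chains start from the abundance and gain self-adjacency as s drops", {
  prof <- abundanceProfile(c(A = 0.55, B = 0.3, C = 0.15))
  set.seed(34)
  # start distribution (chi-squared sanity band)
  first <- sampleSegmentPairs(20000, sourceModel(prof, s = 0.8))[, 1]
  tab <- table(factor(first, levels = names(abundances(prof))))
  expect_gt(chisq.test(tab, p = abundances(prof))$p.value, 1e-4)
  # switch rate at s = 1 matches the closed form sum p(1-p)
  p <- abundances(prof)
  pairs1 <- sampleSegmentPairs(50000, sourceModel(prof, s = 1))
  expect_lt(abs(mean(pairs1[, 1] != pairs1[, 2]) - sum(p * (1 - p))), 0.01)
  # s < 1 increases same-species adjacency beyond the s = 1 closed form
  chains <- replicate(4000, sampleSpeciesChain(5, sourceModel(prof, s = 0.77)))
  stay <- mean(chains[-1, ] == chains[-5, ])
  expect_gt(stay, 1 - sum(p * (1 - p)))
  expect_error(sampleSpeciesChain(0, sourceModel(prof)), "k must be >= 1")
})
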