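test_that("Cohen's kappa matches hand-computed contingency tables", {
  # identical vectors with >= 2 labels
  expect_identical(cohenKappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # 2x2 table [[20, 5], [10, 15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  a <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  expect_equal(cohenKappa(a, b), 0.4, tolerance = 1e-12)
  # balanced 5-class cyclic shift: p_o = 0, p_e = 0.2, kappa = -0.25
  x <- rep(letters[1:5], 20)
  y <- rep(letters[c(2:5, 1)], 20)
  expect_equal(cohenKappa(x, y), -0.25, tolerance = 1e-12)
  # contract errors
  expect_error(cohenKappa(c("a", "b"), c("a")), "length")
  expect_error(cohenKappa(rep("a", 5), rep("a", 5)), "undefined")
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(41, {
    a <- sample(letters[1:4], 500, replace = TRUE)
    b <- ifelse(runif(500) < 0.6, a, sample(letters[1:4], 500,
                                            replace = TRUE))
  })
  ref <- e1071::classAgreement(table(a, b))$kappa
  expect_equal(cohenKappa(a, b), ref, tolerance = 1e-12)
})

test_that("pairwise kappa summarises all rater pairs", {
  lab <- matrix(rep(rep(mergedCategories(), 8), 4), ncol = 4,
                dimnames = list(sprintf("i%02d", 1:40), paste0("e", 1:4)))
  rep4 <- pairwiseKappa(annotationTable(lab, merged = TRUE))
  expect_true(all(rep4@kappa == 1))
  expect_identical(rep4@mean, 1)
  expect_identical(rep4@sd, 0)
  # two raters: single pair, SD = 0 by convention
  tab2 <- annotationTable(lab[, 1:2], merged = TRUE)
  rep2 <- pairwiseKappa(tab2)
  expect_identical(rep2@sd, 0)
  expect_error(pairwiseKappa(annotationTable(lab[, 1, drop = FALSE],
                                             merged = TRUE)),
               "2 raters")
})

test_that("pairwise kappa of simulated raters matches the closed form", {
  models <- list(annotatorModel("a", 0.1), annotatorModel("b", 0.3),
                 annotatorModel("c", 0.5))
  truths <- rep(mergedCategories(), 2000)
  tab <- simulateAnnotations(truths, models, seed = 19)
  rep3 <- pairwiseKappa(tab)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(rep3@kappa[i, j],
                 expectedKappa(models[[i]], models[[j]]),
                 tolerance = 0.03)
  }
})

test_that("adjusted Rand index matches its definition", {
  expect_identical(adjustedRand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_identical(adjustedRand(c(1, 1, 2, 2), c(3, 3, 9, 9)), 1)
  # one cluster vs an even split: index equals expectation -> 0
  expect_identical(adjustedRand(c(1, 1, 1, 1), c(1, 1, 2, 2)), 0)
  # independent partitions sit at chance
  withr::with_seed(7, {
    a <- sample(1:5, 10000, replace = TRUE)
    b <- sample(1:5, 10000, replace = TRUE)
  })
  expect_lt(abs(adjustedRand(a, b)), 0.01)
  expect_error(adjustedRand(1, 1), "at least 2")
})

test_that("ARI agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(13, {
    a <- sample(1:4, 300, replace = TRUE)
    b <- ifelse(runif(300) < 0.5, a, sample(1:4, 300, replace = TRUE))
  })
  expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("kappa and ARI are invariant to joint relabeling", {
  withr::with_seed(29, {
    a <- sample(mergedCategories(), 400, replace = TRUE)
    b <- ifelse(runif(400) < 0.5, a,
                sample(mergedCategories(), 400, replace = TRUE))
  })
  perm <- setNames(sample(mergedCategories()), mergedCategories())
  expect_equal(cohenKappa(perm[a], perm[b]), cohenKappa(a, b),
               tolerance = 1e-12)
  expect_equal(adjustedRand(perm[a], b), adjustedRand(a, b),
               tolerance = 1e-12)
})

test_that("optimal label matching recovers permutations and respects chance", {
  withr::with_seed(3, ref <- sample(mergedCategories(), 200,
                                    replace = TRUE))
  perm <- setNames(sample(mergedCategories()), mergedCategories())
  pred <- unname(perm[ref])
  al <- alignLabels(pred, ref)
  expect_identical(al$relabeled, ref)
  expect_identical(unname(al$mapping[perm[mergedCategories()]]),
                   mergedCategories())
  # random predictions stay at chance even after alignment
  withr::with_seed(4, {
    predR <- sample(1:5, 10000, replace = TRUE)
    refR <- sample(mergedCategories(), 10000, replace = TRUE)
  })
  alR <- alignLabels(predR, refR)
  expect_lt(abs(cohenKappa(alR$relabeled, refR)), 0.03)
  # injective 3 -> 5 mapping: unmapped categories never predicted
  withr::with_seed(5, {
    pred3 <- sample(1:3, 300, replace = TRUE)
    ref5 <- sample(mergedCategories(), 300, replace = TRUE)
  })
  al3 <- alignLabels(pred3, ref5)
  expect_identical(length(unique(al3$mapping)), 3L)
  expect_true(all(al3$relabeled %in% al3$mapping))
})

test_that("alignment never does worse than the identity mapping", {
  withr::with_seed(11, {
    ref <- sample(1:4, 300, replace = TRUE)
    pred <- ifelse(runif(300) < 0.4, ref, sample(1:4, 300,
                                                 replace = TRUE))
  })
  al <- alignLabels(as.character(pred), as.character(ref))
  expect_gte(mean(al$relabeled == as.character(ref)),
             mean(pred == ref))
})

test_that("pooled t-test reproduces the hand-computed example", {
  out <- twoSampleT(1:5, 3:7)
  expect_equal(out$t, -2, tolerance = 1e-12)
  expect_identical(out$df, 8)
  # identical samples: t = 0, p = 1
  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  # well-separated Gaussians are detected
  withr::with_seed(2, {
    x <- rnorm(30, 0); y <- rnorm(30, 3)
  })
  expect_lt(twoSampleT(x, y)$p, 0.001)
  expect_error(twoSampleT(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(twoSampleT(1, 2:4), "at least 2")
})
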