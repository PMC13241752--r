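test_that("scene generation is reproducible and well-formed", {
  a <- generateScene("attached", testSceneParams(), seed = 9)
  b <- generateScene("attached", testSceneParams(), seed = 9)
  expect_identical(a@image, b@image)
  expect_identical(a@mask, b@mask)
  expect_identical(a@depth, b@depth)
  # single connected foreground component, shared dimensions
  expect_identical(dim(a@mask), dim(a@depth))
  expect_identical(dim(a@image)[1:2], dim(a@mask))
  expect_identical(sum(largestComponent(a@mask)), sum(a@mask))
  # a different seed gives a different wound
  c <- generateScene("attached", testSceneParams(), seed = 10)
  expect_false(identical(a@mask, c@mask))
})

test_that("a wound too large for the frame is a geometry error", {
  expect_error(generateScene("attached", list(size = 128, r0 = 70),
                             seed = 1),
               "exceeds frame")
})

test_that("unperturbed circular scene is radially symmetric", {
  sc <- generateScene("attached",
                      testSceneParams(amplitudes = rep(0, 4), gx = 0,
                                      gy = 0, sigma = 0, D = 8, wE = 10),
                      seed = 2)
  ct <- extractContour(largestComponent(sc@mask), 180)
  rb <- rectifyBand(sc@depth, ct, 12, 12)
  # all angular profiles identical up to contour digitization
  colSpread <- apply(bandValues(rb), 2, function(v) diff(range(v)))
  expect_lt(max(colSpread) / 8, 0.1)
})

test_that("rolled rim height reads back from the generating function", {
  hR <- 5
  sc <- generateScene("rolled_fibrotic",
                      testSceneParams(amplitudes = rep(0, 4), gx = 0,
                                      gy = 0, sigma = 0, D = 8, hR = hR),
                      seed = 2)
  f <- craterFunction("rolled_fibrotic", list(D = 8, hR = hR))
  analyticMax <- max(f(seq(-12, 12, by = 0.01)))
  bandIdx <- transitionBand(largestComponent(sc@mask), 12, 12)@band > 0
  expect_equal(max(sc@depth[bandIdx]), analyticMax, tolerance = 0.1)
  # the rim rises by ~hR above the far peri-wound baseline
  expect_equal(analyticMax, hR, tolerance = 0.12)
})

test_that("band depth minus the planar term equals the crater function", {
  sc <- generateScene("not_attached",
                      testSceneParams(gx = 0.01, gy = -0.015, sigma = 0.02),
                      seed = 6)
  f <- craterFunction("not_attached",
                      sc@params[c("D", "wE", "hR")])
  mask <- largestComponent(sc@mask)
  n <- nrow(mask)
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  resid <- sc@depth - 0.01 * x + 0.015 * y
  bandIdx <- transitionBand(mask, 12, 12)@band > 0
  s <- periwound:::signedDistance(mask)
  err <- resid[bandIdx] - f(s[bandIdx])
  # within noise sigma plus half-pixel distance quantisation on the step
  expect_lt(stats::median(abs(err)), 3 * 0.02 + 0.05)
})

test_that("annotator models validate and reproduce their confusion", {
  expect_error(annotatorModel("x", confusion = matrix(1, 5, 5)),
               "sum to 1")
  m <- annotatorModel("x", errorRate = 0.2)
  expect_equal(unname(diag(m@confusion)), rep(0.84, 5))
  expect_equal(rowSums(m@confusion), setNames(rep(1, 5),
                                              mergedCategories()))
})

test_that("identity raters agree perfectly; uniform raters agree at chance", {
  truths <- rep(mergedCategories(), 40)
  idA <- annotatorModel("a", 0)
  idB <- annotatorModel("b", 0)
  tab <- simulateAnnotations(truths, list(idA, idB), seed = 3)
  expect_identical(cohenKappa(labelMatrix(tab)[, 1], labelMatrix(tab)[, 2]),
                   1)
  unif <- matrix(1 / 5, 5, 5)
  uA <- annotatorModel("a", confusion = unif)
  uB <- annotatorModel("b", confusion = unif)
  truths <- rep(mergedCategories(), 2000)
  tab <- simulateAnnotations(truths, list(uA, uB), seed = 4)
  expect_lt(abs(cohenKappa(labelMatrix(tab)[, 1],
                           labelMatrix(tab)[, 2])), 0.05)
})

test_that("expected kappa matches hand enumeration of the joint table", {
  idA <- annotatorModel("a", 0)
  expect_identical(expectedKappa(idA, idA), 1)
  # independent uniform rater: p_o = p_e, kappa 0
  uB <- annotatorModel("b", confusion = matrix(1 / 5, 5, 5))
  expect_lt(abs(expectedKappa(idA, uB)), 1e-12)
  # identity with 20% uniform error, both raters, uniform prior:
  # rows have diagonal 0.84, off-diagonal 0.04
  # p_o = 0.84^2 + 4 * 0.04^2 = 0.712; p_e = 5 * 0.2^2 = 0.2
  # kappa = (0.712 - 0.2) / 0.8 = 0.64
  e20 <- annotatorModel("c", 0.2)
  expect_equal(expectedKappa(e20, e20), 0.64, tolerance = 1e-12)
  # degenerate case: both raters constant in the same category
  const <- matrix(0, 5, 5); const[, 1] <- 1
  cA <- annotatorModel("a", confusion = const)
  expect_error(expectedKappa(cA, cA), "undefined")
})

test_that("empirical kappa converges to the closed-form expectation", {
  a <- annotatorModel("a", 0)
  b <- annotatorModel("b", 0.2)
  truths <- rep(mergedCategories(), 2000)   # n = 10000, balanced
  tab <- simulateAnnotations(truths, list(a, b), seed = 11)
  emp <- cohenKappa(labelMatrix(tab)[, 1], labelMatrix(tab)[, 2])
  expect_equal(emp, expectedKappa(a, b), tolerance = 0.03)
})
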