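test_that("aggregation takes the per-column median over valid rows", {
  common <- seq(0, -2, length.out = 21)
  vals <- matrix(rep(common, each = 40), 40, 21)
  rb <- new("RectifiedBand", values = vals,
            valid = matrix(TRUE, 40, 21), dIn = 10, dOut = 10,
            channel = "depth")
  p <- aggregateProfile(rb)
  expect_equal(p@values, common)
  expect_identical(p@validCount, 40L)
  # invalid rows are excluded; coverage below 50% errors
  vals2 <- vals; vals2[1:16, ] <- vals2[1:16, ] + 100
  valid2 <- matrix(TRUE, 40, 21); valid2[1:16, 1] <- FALSE
  rb2 <- new("RectifiedBand", values = vals2, valid = valid2,
             dIn = 10, dOut = 10, channel = "depth")
  p2 <- aggregateProfile(rb2)
  expect_equal(p2@values, common)
  expect_identical(p2@validCount, 24L)
  valid3 <- matrix(TRUE, 40, 21); valid3[1:21, 1] <- FALSE
  rb3 <- new("RectifiedBand", values = vals, valid = valid3,
             dIn = 10, dOut = 10, channel = "depth")
  expect_error(aggregateProfile(rb3), "valid")
})

test_that("median aggregation concentrates around the common profile", {
  withr::with_seed(23, {
    common <- -1 / (1 + exp(seq(10, -10) / 2))
    K <- 200
    vals <- matrix(rep(common, each = K), K, 21) +
      matrix(rnorm(K * 21, 0, 0.3), K, 21)
    rb <- new("RectifiedBand", values = vals,
              valid = matrix(TRUE, K, 21), dIn = 10, dOut = 10,
              channel = "depth")
    p <- aggregateProfile(rb)
    # median concentration: error ~ noise / sqrt(K)
    expect_lt(max(abs(p@values - common)), 0.3 / sqrt(K) * 4)
  })
})

test_that("normalization anchors the outer end and unit robust amplitude", {
  p <- normalizeProfile(edgeProfile(seq(10, 0, length.out = 21), 10, 10))
  expect_identical(p@values[1], 0)
  expect_equal(diff(quantile(p@values, c(0.1, 0.9))), 1,
               tolerance = 1e-12, ignore_attr = TRUE)
  # affine invariance: scale by 3, offset by 5 -> identical output
  base <- -1 / (1 + exp(seq(10, -10) / 3))
  pa <- normalizeProfile(edgeProfile(base, 10, 10))
  pb <- normalizeProfile(edgeProfile(3 * base + 5, 10, 10))
  expect_equal(pa@values, pb@values, tolerance = 1e-12)
  # constant profile: all zeros and degenerate-flat flag
  pc <- normalizeProfile(edgeProfile(rep(7, 21), 10, 10))
  expect_true(pc@degenerate)
  expect_true(all(pc@values == 0))
})

test_that("templates are recovered from their generating trends", {
  delta <- seq(20, -20)
  withr::with_seed(5, {
    flat <- normalizeProfile(edgeProfile(rnorm(41, 0, 0.01), 20, 20))
    ff <- fitTemplates(flat)
    expect_identical(selectedTemplate(ff), "flat")

    lin <- normalizeProfile(
      edgeProfile(-0.5 + 0.025 * delta + rnorm(41, 0, 0.01), 20, 20))
    fl <- fitTemplates(lin)
    expect_identical(selectedTemplate(fl), "linear")
    expect_equal(fl@fits$linear$par$beta * lin@scale, 0.025,
                 tolerance = 0.05)

    step <- -1 / (1 + exp((delta - 3) / 1.5))   # steep step at delta0 = 3
    fa <- fitTemplates(normalizeProfile(
      edgeProfile(step + rnorm(41, 0, 0.01), 20, 20)))
    expect_identical(selectedTemplate(fa), "abrupt")
    expect_lt(abs(fa@fits$abrupt$par$d0 - 3), 2)

    wide <- -1 / (1 + exp((delta + 2) / 6))
    fs <- fitTemplates(normalizeProfile(
      edgeProfile(wide + rnorm(41, 0, 0.01), 20, 20)))
    expect_identical(selectedTemplate(fs), "smooth")
    expect_gt(fs@fits$smooth$par$w, 3)
  })
})

test_that("template RSS values are bit-reproducible across runs", {
  withr::with_seed(3, {
    p <- normalizeProfile(
      edgeProfile(-1 / (1 + exp(seq(20, -20) / 2)) + rnorm(41, 0, 0.05),
                  20, 20))
  })
  f1 <- fitTemplates(p)
  f2 <- fitTemplates(p)
  for (nm in names(f1@fits))
    expect_equal(f1@fits[[nm]]$rss, f2@fits[[nm]]$rss, tolerance = 1e-10)
  expect_identical(selectedTemplate(f1), selectedTemplate(f2))
})

test_that("template selection is invariant to offset and positive scaling", {
  delta <- seq(20, -20)
  base <- -1 / (1 + exp(delta / 1.2))
  withr::with_seed(9, base <- base + rnorm(41, 0, 0.03))
  fA <- fitTemplates(normalizeProfile(edgeProfile(base, 20, 20)))
  fB <- fitTemplates(normalizeProfile(edgeProfile(5 * base - 3, 20, 20)))
  expect_identical(selectedTemplate(fA), selectedTemplate(fB))
  for (nm in names(fA@fits))
    expect_equal(fA@fits[[nm]]$bic, fB@fits[[nm]]$bic, tolerance = 1e-6)
})

test_that("profile features describe steps, rims and flats", {
  delta <- seq(20, -20)
  # unit step centred at the border
  step <- normalizeProfile(
    edgeProfile(-1 / (1 + exp(-(delta) / 0.8)) + 1, 20, 20))
  fs <- fitTemplates(step)
  feat <- profileFeatures(fs, step)
  expect_equal(abs(feat[["profile_inside_minus_outside"]]), 1,
               tolerance = 0.1)
  expect_lt(abs(feat[["profile_grad_location"]]), 1.5)
  # flat: all gradient features near zero
  flat <- normalizeProfile(edgeProfile(rep(2, 41), 20, 20))
  featF <- profileFeatures(fitTemplates(flat), flat)
  expect_identical(featF[["profile_grad_max"]], 0)
  expect_identical(featF[["profile_rim_prominence"]], 0)
  expect_identical(featF[["profile_is_flat"]], 1)
})

test_that("rim prominence round-trips the generator rim height", {
  hR <- 4
  sc <- generateScene("rolled_fibrotic",
                      testSceneParams(sigma = 0, gx = 0, gy = 0,
                                      D = 8, hR = hR),
                      seed = 13)
  res <- sceneFeatures(sc, testConfig())
  prom <- res$features[["profile_rim_prominence"]] * res$profile@scale
  f <- craterFunction("rolled_fibrotic", list(D = 8, hR = hR))
  analytic <- max(f(seq(0, 12, by = 0.01))) -
    median(f(seq(9, 12, by = 0.01)))
  expect_equal(prom, analytic, tolerance = 0.1 * analytic + 0.1)
})
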