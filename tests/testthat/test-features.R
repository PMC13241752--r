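test_that("shape descriptors match analytic limits", {
  mask <- diskMask(128, 50)
  ct <- extractContour(mask, 256)
  g <- geometricFeatures(mask, ct)
  expect_gte(g[["geom_circularity"]], 0.95)
  expect_lte(g[["geom_circularity"]], 1.02)
  expect_gte(g[["geom_solidity"]], 0.98)
  expect_lt(g[["geom_radial_cv"]], 0.01)
  # square: circularity pi/4
  sq <- matrix(0L, 128, 128); sq[40:90, 40:90] <- 1L
  gs <- geometricFeatures(sq, extractContour(sq, 256))
  expect_equal(gs[["geom_circularity"]], pi / 4, tolerance = 0.05)
})

test_that("a star-perturbed contour is more irregular than a circle", {
  n <- 160; ctr <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  r <- sqrt((x - ctr)^2 + (y - ctr)^2)
  theta <- atan2(y - ctr, x - ctr)
  star <- matrix(as.integer(r <= 40 * (1 + 0.25 * cos(6 * theta))), n, n)
  disk <- matrix(as.integer(r <= 40 * sqrt(1 + 0.25^2 / 2)), n, n)
  gStar <- geometricFeatures(star, extractContour(star, 256))
  gDisk <- geometricFeatures(disk, extractContour(disk, 256))
  expect_gt(gStar[["geom_border_irregularity"]],
            gDisk[["geom_border_irregularity"]])
  expect_lt(gStar[["geom_circularity"]], gDisk[["geom_circularity"]])
})

test_that("geometry features are invariant to translation and rotation", {
  sc <- generateScene("attached", testSceneParams(), seed = 33)
  mask <- largestComponent(sc@mask)
  g0 <- geometricFeatures(mask, extractContour(mask, 180))
  # translate by (7, -4)
  tr <- matrix(0L, nrow(mask), ncol(mask))
  tr[(1:nrow(mask))[-(1:7)], 1:(ncol(mask) - 4)] <-
    mask[1:(nrow(mask) - 7), 5:ncol(mask)]
  gT <- geometricFeatures(tr, extractContour(tr, 180))
  expect_equal(g0, gT, tolerance = 0.01)
  # rotate 90 degrees
  rot <- t(mask)[ncol(mask):1, ]
  gR <- geometricFeatures(rot, extractContour(rot, 180))
  expect_equal(g0, gR, tolerance = 0.02)
})

test_that("colour statistics read painted regions correctly", {
  sc <- generateScene("attached", testSceneParams(sigma = 0), seed = 3)
  mask <- largestComponent(sc@mask)
  band <- transitionBand(mask, 12, 12)
  ct <- extractContour(mask, 180)
  # paint bed pure red, everything else mid-gray
  img <- array(0.5, dim = dim(sc@image))
  bedPaint <- periwound:::signedDistance(mask) < -11
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bedPaint] <- if (ch == 1) 1 else 0
    img[, , ch] <- plane
  }
  rectC <- rectifyBand(img, ct, 12, 12)
  v <- visualFeatures(img, mask, band, rectC)
  expect_equal(v[["vis_bed_redness"]], 1, tolerance = 1e-6)
  expect_equal(v[["vis_outer_band_redness"]], 1 / 3, tolerance = 1e-6)

  # uniform gray image: zero SDs, co-occurrence energy 1
  gray <- array(0.5, dim = dim(sc@image))
  vg <- visualFeatures(gray, mask, band, rectifyBand(gray, ct, 12, 12))
  expect_identical(vg[["vis_bed_r_sd"]], 0)
  expect_identical(vg[["vis_glcm_energy"]], 1)
  expect_identical(vg[["vis_glcm_contrast"]], 0)
})

test_that("checkerboard texture has higher co-occurrence contrast", {
  check <- outer(1:40, 1:40, function(i, j) (i + j) %% 2)
  flat <- matrix(0.5, 40, 40)
  gC <- periwound:::glcmFeatures(check)
  gF <- periwound:::glcmFeatures(flat)
  expect_gt(gC[["contrast"]], gF[["contrast"]])
  expect_identical(gF[["energy"]], 1)
  expect_lt(gC[["energy"]], 1)
})

test_that("visual features ignore background beyond the dilated band", {
  sc <- generateScene("hyperkeratotic", testSceneParams(), seed = 12)
  mask <- largestComponent(sc@mask)
  band <- transitionBand(mask, 12, 12)
  ct <- extractContour(mask, 180)
  far <- periwound:::signedDistance(mask) > 20
  img2 <- sc@image
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[far] <- runif(sum(far))
    img2[, , ch] <- plane
  }
  v1 <- visualFeatures(sc@image, mask, band, rectifyBand(sc@image, ct, 12, 12))
  v2 <- visualFeatures(img2, mask, band, rectifyBand(img2, ct, 12, 12))
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("the feature matrix is aligned, finite and order-invariant", {
  set <- makeSceneSet(perClass = 2, seedBase = 500)
  cfg <- testConfig()
  fm <- buildFeatureMatrix(set$scenes, cfg)
  expect_identical(nrow(fm$matrix), 10L)
  expect_true(all(is.finite(fm$matrix)))
  expect_identical(length(fm$groups), ncol(fm$matrix))
  # permuting input order permutes rows only
  perm <- c(7, 2, 9, 4, 1, 10, 3, 6, 5, 8)
  fm2 <- buildFeatureMatrix(set$scenes[perm], cfg)
  expect_identical(fm2$matrix, fm$matrix[perm, ])
  # geometry-only selection picks exactly the geometry-tagged columns
  geo <- colnames(fm$matrix)[fm$groups == "geometry"]
  expect_true(all(grepl("^(geom_|profile_)", geo)))
  expect_false(any(grepl("^vis_", geo)))
  # annotation alignment errors on id mismatch
  lab <- matrix("attached", 10, 1,
                dimnames = list(sprintf("other%02d", 1:10), "e1"))
  expect_error(buildFeatureMatrix(set$scenes, cfg,
                                  annotationTable(lab, merged = TRUE)),
               "do not match")
})
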