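# Geometric and visual wound descriptors, and assembly of the dataset
# feature matrix. The descriptor set covers the three axes relevant to
# wound-edge scoring: wound shape, colour appearance, and surface pattern.

# Gray-level co-occurrence features (symmetric GLCM, `levels` gray levels,
# offset `dy`/`dx` in matrix row/col units). Haralick contrast, homogeneity,
# energy and correlation.
glcmFeatures <- function(gray, levels = 32L, dy = 1L, dx = 0L) {
  v <- gray[is.finite(gray)]
  if (length(v) == 0L || diff(range(v)) == 0) {
    # single gray level: perfectly homogeneous texture
    return(c(contrast = 0, homogeneity = 1, energy = 1, correlation = 0))
  }
  rng <- range(gray, na.rm = TRUE)
  q <- matrix(pmin(levels, 1L + floor((gray - rng[1L]) / diff(rng) * levels)),
              nrow(gray), ncol(gray))
  nr <- nrow(q); nc <- ncol(q)
  r1 <- seq_len(nr - dy); c1 <- seq_len(nc - dx)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dy, c1 + dx, drop = FALSE]
  keep <- is.finite(a) & is.finite(b)
  P <- matrix(0, levels, levels)
  tab <- table(factor(a[keep], levels = seq_len(levels)),
               factor(b[keep], levels = seq_len(levels)))
  P <- (tab + t(tab)) / (2 * sum(tab))   # symmetric, normalized
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  mu <- sum(i * P)
  sg2 <- sum((i - mu)^2 * P)
  corr <- if (sg2 > 0) sum((i - mu) * (j - mu) * P) / sg2 else 0
  c(contrast = sum((i - j)^2 * P),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sum(P^2),
    correlation = corr)
}

# Mean/SD of RGB and HSV (hue circular) over a set of pixels given as an
# n x 3 matrix of channel values in [0, 1].
colourStats <- function(rgb, prefix) {
  if (nrow(rgb) == 0L) {
    out <- rep(0, 13)
  } else {
    hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
    hAng <- hsv[1L, ] * 2 * pi
    hMean <- atan2(mean(sin(hAng)), mean(cos(hAng))) / (2 * pi)
    if (hMean < 0) hMean <- hMean + 1
    hSd <- sqrt(-2 * log(pmax(1e-12, sqrt(mean(sin(hAng))^2 +
                                            mean(cos(hAng))^2))))
    total <- rowSums(rgb)
    redness <- mean(ifelse(total > 0, rgb[, 1L] / total, 1 / 3))
    out <- c(colMeans(rgb), apply(rgb, 2L, stats::sd),
             hMean, hSd, mean(hsv[2L, ]), stats::sd(hsv[2L, ]),
             mean(hsv[3L, ]), stats::sd(hsv[3L, ]), redness)
  }
  names(out) <- paste0(prefix, "_",
                       c("r_mean", "g_mean", "b_mean", "r_sd", "g_sd",
                         "b_sd", "hue_mean", "hue_sd", "sat_mean", "sat_sd",
                         "val_mean", "val_sd", "redness"))
  out
}

#' Geometric edge descriptors of a wound
#'
#' Size and shape of the wound (area, perimeter, circularity `4 pi A / P^2`,
#' solidity, eccentricity), regularity of the border (perimeter over
#' convex-hull perimeter, coefficient of variation of the radial distance),
#' and all depth-profile descriptors from [profileFeatures()].
#'
#' @param mask single-component 0/1 matrix.
#' @param contour the wound [Contour-class].
#' @param profileFeats named vector from [profileFeatures()] (optional;
#'   appended if given).
#' @return Named numeric vector, all tagged group `"geometry"` by
#'   [featureGroups()].
#' @export
geometricFeatures <- function(mask, contour, profileFeats = NULL) {
  pts <- contourPoints(contour)
  if (nrow(pts) < 16L) stop("degenerate contour")
  area <- sum(mask > 0)
  perim <- contour@length
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  hullArea <- abs(polygonArea(hull))
  hullPerim <- polygonPerimeter(hull)
  ctr <- colMeans(pts)
  rad <- sqrt((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2)
  pix <- which(mask > 0, arr.ind = TRUE)
  cv <- stats::cov(cbind(pix[, 2L], pix[, 1L]))
  ev <- eigen(cv, symmetric = TRUE)$values
  ecc <- sqrt(1 - min(ev) / max(ev))
  out <- c(geom_area = area,
           geom_perimeter = perim,
           geom_circularity = 4 * pi * area / perim^2,
           geom_solidity = area / hullArea,
           geom_eccentricity = ecc,
           geom_border_irregularity = perim / hullPerim,
           geom_radial_cv = stats::sd(rad) / mean(rad))
  c(out, profileFeats)
}

#' Visual (colour and texture) descriptors of wound and peri-wound regions
#'
#' For three regions -- wound bed (mask eroded by `dIn`, avoiding
#' edge-mixing pixels), inner band (band inside the wound) and outer band
#' (band outside) -- computes mean/SD of R, G, B and of hue (circular),
#' saturation, value, plus a redness index `R / (R + G + B)`. Surface
#' pattern is summarised on the grayscale rectified band: gray-level
#' co-occurrence contrast, homogeneity, energy and correlation (offset 1 px
#' along the band, 32 levels) and gradient-magnitude mean and entropy.
#' Empty regions yield zero-valued sentinels with a warning.
#'
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param mask single-component 0/1 matrix aligned with `image`.
#' @param band a [TransitionBand-class].
#' @param rectRGB the RGB [RectifiedBand-class] of the same wound.
#' @return Named numeric vector, tagged group `"visual"`.
#' @export
visualFeatures <- function(image, mask, band, rectRGB) {
  stopifnot(length(dim(image)) == 3L, is(band, "TransitionBand"))
  bed <- if (band@dIn >= 1)
    EBImage::erode(mask, diskBrush(band@dIn)) else mask
  regions <- list(bed = bed > 0,
                  inner_band = band@band > 0 & mask > 0,
                  outer_band = band@band > 0 & !(mask > 0))
  out <- numeric(0)
  for (nm in names(regions)) {
    idx <- which(regions[[nm]])
    if (length(idx) == 0L)
      warning("empty region '", nm, "': emitting zero sentinels")
    rgb <- cbind(image[, , 1L][idx], image[, , 2L][idx], image[, , 3L][idx])
    out <- c(out, colourStats(rgb, paste0("vis_", nm)))
  }
  # texture on the grayscale rectified band (arc length x offset)
  vals <- bandValues(rectRGB)
  gray <- 0.299 * vals[, , 1L] + 0.587 * vals[, , 2L] + 0.114 * vals[, , 3L]
  gray[!rectRGB@valid] <- NA_real_
  gl <- glcmFeatures(gray, levels = 32L, dy = 1L, dx = 0L)
  names(gl) <- paste0("vis_glcm_", names(gl))
  gy <- gray[-1L, ] - gray[-nrow(gray), ]
  gx <- gray[, -1L] - gray[, -ncol(gray)]
  gm <- sqrt(gy[, -ncol(gy)]^2 + gx[-nrow(gx), ]^2)
  c(out, gl,
    vis_grad_mean = mean(gm, na.rm = TRUE),
    vis_grad_entropy = histogramEntropy(gm))
}

#' Group tag (geometry / visual) for each feature name
#'
#' @param names character vector of feature names.
#' @return Character vector of `"geometry"` / `"visual"` tags.
#' @export
featureGroups <- function(names) {
  ifelse(grepl("^vis_", names), "visual", "geometry")
}

#' Run the full per-image pipeline on one scene
#'
#' Largest component, transition band, contour, plane detrending of the
#' depth map (over the band by default), rectification of depth and RGB,
#' profile aggregation + normalization + template fitting, and the geometric
#' and visual descriptor sets.
#'
#' @param scene a [SyntheticScene-class], or a list with elements `image`,
#'   `mask`, `depth` (as returned by [readSceneFiles()]).
#' @param config a [RunConfig-class].
#' @return list with `features` (named numeric vector), `groups`, `profile`
#'   (normalized [EdgeProfile-class]), `fit` ([TemplateFit-class]), and
#'   `plane` ([PlaneFit-class]).
#' @export
sceneFeatures <- function(scene, config = periConfig()) {
  if (is(scene, "SyntheticScene"))
    scene <- list(image = scene@image, mask = scene@mask,
                  depth = scene@depth)
  mask <- largestComponent(scene$mask)
  band <- transitionBand(mask, config@dIn, config@dOut)
  contour <- extractContour(mask, config@K)
  region <- if (config@detrendRegion == "band") band@band
            else matrix(1L, nrow(mask), ncol(mask))
  det <- detrendDepth(scene$depth, region)
  rectD <- rectifyBand(det$residual, contour, config@dIn, config@dOut)
  rectC <- rectifyBand(scene$image, contour, config@dIn, config@dOut)
  prof <- normalizeProfile(aggregateProfile(rectD))
  fit <- fitTemplates(prof, wAbrupt = config@wAbrupt)
  pf <- profileFeatures(fit, prof)
  feats <- c(geometricFeatures(mask, contour, pf),
             visualFeatures(scene$image, mask, band, rectC))
  list(features = feats, groups = featureGroups(names(feats)),
       profile = prof, fit = fit, plane = det$fit)
}

#' Assemble the dataset feature matrix
#'
#' Runs [sceneFeatures()] on every scene and stacks the descriptor vectors
#' into an n x p matrix whose rows are aligned with the given image ids.
#' Deterministic given the scenes and config; permuting the input order
#' permutes only the rows.
#'
#' @param scenes named list of scenes (names are image ids; unnamed lists
#'   get `img0001`, ...).
#' @param config a [RunConfig-class].
#' @param annotations optional [AnnotationTable-class]; if given, rows are
#'   reordered to match it and an id mismatch is an error.
#' @return list with `matrix` (n x p numeric), `groups` (per-column tag),
#'   and `details` (per-scene list of profile/fit objects).
#' @export
buildFeatureMatrix <- function(scenes, config = periConfig(),
                               annotations = NULL) {
  if (is.null(names(scenes)))
    names(scenes) <- sprintf("img%04d", seq_along(scenes))
  res <- lapply(scenes, sceneFeatures, config = config)
  mat <- do.call(rbind, lapply(res, function(r) r$features))
  rownames(mat) <- names(scenes)
  if (!all(is.finite(mat)))
    stop("non-finite feature values for image(s): ",
         paste(rownames(mat)[!stats::complete.cases(mat)], collapse = ", "))
  groups <- featureGroups(colnames(mat))
  if (!is.null(annotations)) {
    ids <- imageIds(annotations)
    if (!setequal(ids, rownames(mat)))
      stop("image ids of features and annotations do not match")
    mat <- mat[ids, , drop = FALSE]
  }
  list(matrix = mat, groups = groups,
       details = lapply(res, function(r) r[c("profile", "fit")]))
}

#' Profile-similarity matrix for the unsupervised experiment
#'
#' The clustering feature vector: the normalized aggregated profile values
#' concatenated with the template-fit parameters and residuals (logistic
#' step location/width/amplitude and the four template RSS values).
#'
#' @param details `details` element of [buildFeatureMatrix()] output, or a
#'   list of `list(profile =, fit =)` pairs.
#' @return n x (W + 7) numeric matrix.
#' @export
profileMatrix <- function(details) {
  rows <- lapply(details, function(d) {
    pf <- profileFeatures(d$fit, d$profile)
    c(d$profile@values,
      pf[c("profile_logistic_delta0", "profile_logistic_width",
           "profile_logistic_amplitude", "profile_rss_flat",
           "profile_rss_linear", "profile_rss_abrupt",
           "profile_rss_smooth")])
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(details)
  m
}
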