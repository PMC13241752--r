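#' @import methods
NULL

#' Raw and merged wound-edge category vocabularies
#'
#' Six raw clinical wound-edge categories and the five-category merged
#' vocabulary in which rolled-under and fibrotic edges form a single
#' `rolled_fibrotic` class (the two are visually hard to separate on
#' two-dimensional photographs).
#'
#' @return Character vector of category names.
#' @export
rawCategories <- function() {
  c("indistinct", "attached", "not_attached",
    "rolled_under", "hyperkeratotic", "fibrotic")
}

#' @rdname rawCategories
#' @export
mergedCategories <- function() {
  c("indistinct", "attached", "not_attached",
    "rolled_fibrotic", "hyperkeratotic")
}

#' AnnotationTable: per-image categorical labels from multiple raters
#'
#' Holds one wound-edge category per (image, rater) cell. The table is either
#' in the raw six-category state or the merged five-category state (see
#' [mergeCategories()]); the vocabulary is enforced by the validity method.
#'
#' @slot labels character matrix, rows = images (rownames are image ids),
#'   columns = raters (colnames are rater ids); no missing cells allowed.
#' @slot merged logical scalar; `TRUE` once rolled_under/fibrotic have been
#'   collapsed into `rolled_fibrotic`.
#' @export
setClass("AnnotationTable",
  representation(labels = "matrix", merged = "logical"),
  prototype(labels = matrix(character(0), 0, 0), merged = FALSE))

setValidity("AnnotationTable", function(object) {
  lab <- object@labels
  if (!is.character(lab)) return("labels must be a character matrix")
  if (nrow(lab) < 1L || ncol(lab) < 1L) return("table must be non-empty")
  if (is.null(rownames(lab)) || is.null(colnames(lab)))
    return("labels must carry image ids (rownames) and rater ids (colnames)")
  if (anyDuplicated(rownames(lab)))
    return("duplicate image_id in annotation table")
  if (anyNA(lab) || any(lab == ""))
    return("missing label cell(s): every (image, rater) cell must be filled")
  vocab <- if (isTRUE(object@merged)) mergedCategories() else rawCategories()
  bad <- !(lab %in% vocab)
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1L], dim(lab))[1L, ]
    return(sprintf(
      "unknown category '%s' (image '%s', rater '%s'); allowed: %s",
      lab[idx[1L], idx[2L]], rownames(lab)[idx[1L]], colnames(lab)[idx[2L]],
      paste(vocab, collapse = ", ")))
  }
  TRUE
})

#' AnnotatorModel: a simulated rater defined by a confusion matrix
#'
#' Rows index the true archetype (merged vocabulary), columns the category the
#' rater assigns; each row is a probability vector.
#'
#' @slot raterId single character id.
#' @slot confusion 5 x 5 numeric matrix with rows summing to one.
#' @export
setClass("AnnotatorModel",
  representation(raterId = "character", confusion = "matrix"))

setValidity("AnnotatorModel", function(object) {
  cm <- object@confusion
  k <- length(mergedCategories())
  if (!is.numeric(cm) || !all(dim(cm) == k))
    return(sprintf("confusion must be a %d x %d numeric matrix", k, k))
  if (any(cm < 0)) return("confusion entries must be non-negative")
  if (any(abs(rowSums(cm) - 1) > 1e-12))
    return("every confusion row must sum to 1 (tolerance 1e-12)")
  if (length(object@raterId) != 1L) return("raterId must be a single string")
  TRUE
})

#' SyntheticScene: one generated wound (image + mask + depth + ground truth)
#'
#' @slot image numeric array H x W x 3, RGB in `[0, 1]`.
#' @slot mask integer matrix H x W, 1 = wound.
#' @slot depth numeric matrix H x W, relative elevation (arbitrary units);
#'   wound bed lower than the peri-wound skin plane.
#' @slot truth archetype name from [mergedCategories()].
#' @slot params fully resolved generator parameters (list).
#' @slot seed integer seed the scene was generated from.
#' @export
setClass("SyntheticScene",
  representation(image = "array", mask = "matrix", depth = "matrix",
                 truth = "character", params = "list", seed = "integer"))

setValidity("SyntheticScene", function(object) {
  dm <- dim(object@mask)
  if (!identical(dim(object@depth), dm))
    return("mask and depth dimensions differ")
  if (!identical(dim(object@image)[1:2], dm))
    return("image and mask dimensions differ")
  if (!object@truth %in% mergedCategories())
    return("truth must be a merged-vocabulary archetype")
  TRUE
})

#' Contour: closed, uniformly resampled wound boundary with outward normals
#'
#' @slot points K x 2 matrix of subpixel (x, y) positions, counterclockwise,
#'   uniformly spaced by arc length; (x, y) = (col, row), 1-based pixel
#'   centres.
#' @slot normals K x 2 matrix of outward unit normals.
#' @slot spacing arc-length step between consecutive points (px).
#' @slot length total closed-contour length (px).
#' @export
setClass("Contour",
  representation(points = "matrix", normals = "matrix",
                 spacing = "numeric", length = "numeric"))

setValidity("Contour", function(object) {
  if (ncol(object@points) != 2L || !identical(dim(object@points),
                                              dim(object@normals)))
    return("points and normals must be K x 2 matrices of equal size")
  nrm <- sqrt(rowSums(object@normals^2))
  if (any(abs(nrm - 1) > 1e-6)) return("normals must be unit length")
  TRUE
})

#' TransitionBand: annular peri-wound region built by morphology
#'
#' `band = dilate(mask, dOut) & !erode(mask, dIn)` with disk structuring
#' elements.
#'
#' @slot band integer matrix, 1 inside the band.
#' @slot dIn,dOut inner/outer half-widths in pixels.
#' @export
setClass("TransitionBand",
  representation(band = "matrix", dIn = "numeric", dOut = "numeric"))

#' PlaneFit: least-squares plane fitted to a depth raster
#'
#' Coefficients of z = a*x + b*y + c, fitted over a pixel region.
#'
#' @slot a,b,c plane coefficients.
#' @slot rms root-mean-square residual over the fit region.
#' @slot region short description of the fit region.
#' @export
setClass("PlaneFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 rms = "numeric", region = "character"))

#' RectifiedBand: the peri-wound band resampled into a rectangle
#'
#' Row k follows contour point k; column j holds the sample at signed normal
#' offset `delta = dOut - (j - 1)` so columns run outside -> inside and the
#' wound border sits at column `dOut + 1`.
#'
#' @slot values numeric matrix K x W (depth channel) or array K x W x 3 (RGB).
#' @slot valid logical matrix K x W; `FALSE` where the sample fell outside the
#'   raster.
#' @slot dIn,dOut half-widths in pixels; W = dIn + dOut + 1.
#' @slot channel `"depth"` or `"rgb"`.
#' @export
setClass("RectifiedBand",
  representation(values = "array", valid = "matrix",
                 dIn = "numeric", dOut = "numeric", channel = "character"))

#' EdgeProfile: a 1-D outside-to-inside depth trace across the wound border
#'
#' @slot values numeric vector of length W = dIn + dOut + 1, ordered
#'   outside -> inside.
#' @slot delta signed normal offsets, `dOut, dOut-1, ..., -dIn` (px; positive
#'   outside the wound).
#' @slot offset,scale normalisation record (subtracted offset, amplitude
#'   divisor).
#' @slot degenerate `TRUE` when the profile was too flat to scale.
#' @slot normalized whether [normalizeProfile()] has been applied.
#' @slot validCount number of valid band rows that contributed.
#' @export
setClass("EdgeProfile",
  representation(values = "numeric", delta = "numeric",
                 offset = "numeric", scale = "numeric",
                 degenerate = "logical", normalized = "logical",
                 validCount = "integer"))

#' TemplateFit: trend-template decomposition of an edge profile
#'
#' Each of the four trend templates (flat, linear, abrupt, smooth) is fitted
#' by least squares; the winner minimises BIC. Abrupt and smooth are both
#' logistic steps `A / (1 + exp(-(delta - delta0)/w)) + c`, separated by the
#' fitted transition width `w` relative to `wAbrupt`.
#'
#' @slot fits named list (flat, linear, abrupt, smooth), each a list with
#'   elements `par`, `rss`, `bic`, `ok`.
#' @slot winner name of the selected template.
#' @slot wAbrupt width threshold (px) separating abrupt from smooth.
#' @export
setClass("TemplateFit",
  representation(fits = "list", winner = "character", wAbrupt = "numeric"))

#' AgreementReport: pairwise Cohen's kappa among raters
#'
#' @slot raters rater ids.
#' @slot kappa symmetric matrix of pairwise kappa, diagonal 1.
#' @slot mean,sd mean and sample SD over the C(R,2) off-diagonal pairs
#'   (SD = 0 by convention for a single pair).
#' @export
setClass("AgreementReport",
  representation(raters = "character", kappa = "matrix",
                 mean = "numeric", sd = "numeric"))

#' ClusterResult: unsupervised grouping compared post hoc with raters
#'
#' @slot embedding n x dims reduced matrix.
#' @slot labels integer cluster labels (length n).
#' @slot perRater data.frame with one row per rater: post-alignment kappa and
#'   ARI against that rater.
#' @slot mappings per-rater optimal cluster-to-category assignments.
#' @slot meanKappa,sdKappa summary of post-alignment kappa over raters.
#' @slot ari headline ARI against the reference rater.
#' @slot referenceRater rater used for the headline ARI.
#' @export
setClass("ClusterResult",
  representation(embedding = "matrix", labels = "integer",
                 perRater = "data.frame", mappings = "list",
                 meanKappa = "numeric", sdKappa = "numeric",
                 ari = "numeric", referenceRater = "character"))

#' ClassifierReport: supervised evaluation of one feature set
#'
#' @slot featureSet `"geometry"` or `"full"`.
#' @slot perRater data.frame: rater, mean kappa, accuracy, macro
#'   precision/recall/F1.
#' @slot perRun numeric matrix repeats x raters of per-repeat kappa.
#' @slot meanKappa,sdKappa summary over all per-run values.
#' @slot importances named numeric vector (permutation importance, normalised
#'   to sum 1).
#' @slot columns feature columns the model actually saw (audit trail).
#' @slot seed seed used for fold construction and training.
#' @export
setClass("ClassifierReport",
  representation(featureSet = "character", perRater = "data.frame",
                 perRun = "matrix", meanKappa = "numeric", sdKappa = "numeric",
                 importances = "numeric", columns = "character",
                 seed = "integer"))

#' RunConfig: pipeline configuration
#'
#' @slot dIn,dOut transition-band half-widths (px).
#' @slot K number of contour sample points.
#' @slot k cluster count for the unsupervised experiment.
#' @slot dims embedding dimensionality.
#' @slot reduceMethod `"pca"` or `"laplacian"`.
#' @slot wAbrupt logistic-width threshold separating abrupt from smooth (px).
#' @slot detrendRegion `"band"` or `"full"` plane-fit region.
#' @slot classifier `"xgboost"` or `"ranger"`.
#' @slot folds,repeats cross-validation folds and repeats.
#' @slot seed integer seed recorded in all outputs.
#' @export
setClass("RunConfig",
  representation(dIn = "numeric", dOut = "numeric", K = "numeric",
                 k = "numeric", dims = "numeric", reduceMethod = "character",
                 wAbrupt = "numeric", detrendRegion = "character",
                 classifier = "character", folds = "numeric",
                 repeats = "numeric", seed = "integer"))

setValidity("RunConfig", function(object) {
  if (object@dIn < 1 || object@dOut < 1) return("dIn and dOut must be >= 1")
  if (object@K < 16) return("K must be >= 16")
  if (object@k < 2) return("k must be >= 2")
  if (!object@reduceMethod %in% c("pca", "laplacian"))
    return("reduceMethod must be 'pca' or 'laplacian'")
  if (!object@detrendRegion %in% c("band", "full"))
    return("detrendRegion must be 'band' or 'full'")
  if (!object@classifier %in% c("xgboost", "ranger"))
    return("classifier must be 'xgboost' or 'ranger'")
  TRUE
})

#' Build a RunConfig
#'
#' @param dIn,dOut band half-widths in pixels.
#' @param K contour sample count.
#' @param k cluster count.
#' @param dims embedding dimensionality.
#' @param reduceMethod `"pca"` (default) or `"laplacian"`.
#' @param wAbrupt abrupt/smooth logistic width threshold (px).
#' @param detrendRegion plane-fit region, `"band"` (default) or `"full"`.
#' @param classifier `"xgboost"` (default) or `"ranger"`.
#' @param folds,repeats cross-validation scheme.
#' @param seed integer seed recorded in all outputs.
#' @return A validated [RunConfig-class] object.
#' @examples
#' cfg <- periConfig(dIn = 12, dOut = 12, seed = 7L)
#' @export
periConfig <- function(dIn = 20, dOut = 20, K = 360, k = 5, dims = 5,
                       reduceMethod = "pca", wAbrupt = 3,
                       detrendRegion = "band", classifier = "xgboost",
                       folds = 5, repeats = 10, seed = 1L) {
  new("RunConfig", dIn = dIn, dOut = dOut, K = K, k = k, dims = dims,
      reduceMethod = reduceMethod, wAbrupt = wAbrupt,
      detrendRegion = detrendRegion, classifier = classifier,
      folds = folds, repeats = repeats, seed = as.integer(seed))
}
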