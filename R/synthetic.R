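# Parametric synthetic wound scenes: a radially perturbed contour, an
# archetype-specific depth crater expressed as a function of signed distance
# to the contour, a global planar tilt, distinct bed/peri-wound colours and
# per-archetype texture noise. Ground truth is known, so every downstream
# stage is testable without clinical data.

# Evaluate `expr` under a temporary RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-archetype crater defaults: crater depth D, edge width wE (px), rim /
# plateau height hR (px of relative elevation).
archetypeDefaults <- function(archetype) {
  switch(archetype,
    indistinct      = list(D = 2, wE = 12, hR = 0),
    attached        = list(D = 8, wE = 10, hR = 0),
    not_attached    = list(D = 8, wE = 2,  hR = 0),
    rolled_fibrotic = list(D = 8, wE = 2,  hR = 4),
    hyperkeratotic  = list(D = 8, wE = 3,  hR = 3),
    stop("unknown archetype '", archetype, "'"))
}

#' Archetype crater profile as a function of signed distance
#'
#' Returns the radial depth-generating function `f(s)` of an edge archetype,
#' where `s` is the signed distance to the wound contour (positive outside,
#' negative inside) and the value is relative elevation: 0 on far peri-wound
#' skin, about `-D` on the wound bed. The five archetypes differ in how that
#' descent happens: a shallow wide smooth ramp (indistinct), a linear ramp
#' over the edge width (attached), an abrupt logistic drop (not attached), a
#' raised rim just outside the border before the drop (rolled/fibrotic), and
#' an elevated plateau over a thick outer band before the descent
#' (hyperkeratotic).
#'
#' @param archetype one of [mergedCategories()].
#' @param params list with any of `D`, `wE`, `hR` overriding the archetype
#'   defaults.
#' @return A vectorised function of signed distance `s` (px).
#' @examples
#' f <- craterFunction("not_attached")
#' f(c(10, 0, -10))
#' @export
craterFunction <- function(archetype, params = list()) {
  p <- utils::modifyList(archetypeDefaults(archetype), params)
  D <- p$D; wE <- p$wE; hR <- p$hR
  switch(archetype,
    indistinct = function(s) -D * stats::plogis(-s / (wE / 2)),
    attached = function(s) -D * pmax(pmin(0.5 - s / wE, 1), 0),
    not_attached = function(s) -D * stats::plogis(-s / (wE / 4)),
    rolled_fibrotic = function(s)
      hR * exp(-(s - 4)^2 / (2 * 1.8^2)) - D * stats::plogis(-s / 1),
    hyperkeratotic = function(s)
      hR * (stats::plogis((s - 1) / 0.8) - stats::plogis((s - 9) / 0.8)) -
        D * stats::plogis(-s / 1.5))
}

# Bed / skin / callus colours. Bed tint varies with the colour archetype
# (granulation red, dusky red, fibrin yellow, ...), the peri-wound skin tone
# is shared.
archetypeColours <- function(archetype) {
  bed <- switch(archetype,
    indistinct      = c(0.80, 0.45, 0.42),
    attached        = c(0.65, 0.22, 0.20),
    not_attached    = c(0.45, 0.15, 0.18),
    rolled_fibrotic = c(0.75, 0.62, 0.35),
    hyperkeratotic  = c(0.62, 0.25, 0.22))
  noise <- switch(archetype,
    indistinct = 0.010, attached = 0.020, not_attached = 0.035,
    rolled_fibrotic = 0.030, hyperkeratotic = 0.015)
  list(bed = bed, skin = c(0.87, 0.66, 0.55),
       callus = c(0.93, 0.90, 0.80), noiseSd = noise)
}

# Signed distance to the mask's 0.5 iso-contour, positive outside, via two
# Euclidean distance transforms (half-pixel corrected).
signedDistance <- function(mask) {
  fg <- EBImage::distmap(mask)          # > 0 inside
  bg <- EBImage::distmap(1L - mask)     # > 0 outside
  s <- bg - fg
  s - sign(s) * 0.5
}

#' Generate a synthetic wound scene
#'
#' Builds an RGB image, binary mask and depth raster for one wound whose
#' contour is a radial-Fourier perturbation of a circle,
#' `rho(theta) = r0 (1 + sum_m a_m cos(m theta + phi_m))`, and whose depth is
#' `g_x x + g_y y + crater(s) + noise`, with `crater` the archetype profile
#' of [craterFunction()] evaluated at the signed distance `s` to the
#' contour. Colours separate the reddish wound bed from skin-toned
#' peri-wound tissue, with a whitened callus ring for hyperkeratotic wounds
#' and per-archetype texture noise. Regenerating with the same seed and
#' parameters reproduces the scene exactly.
#'
#' Unspecified parameters are drawn (deterministically from `seed`) from
#' realistic ranges: four radial harmonics with amplitudes up to 0.06, a
#' planar tilt up to 0.02 depth units per pixel, and a +/-10% jitter on the
#' archetype's crater parameters.
#'
#' @param archetype ground-truth archetype from [mergedCategories()].
#' @param params optional overrides: `size`, `r0`, `amplitudes`, `phases`,
#'   `gx`, `gy`, `sigma` (depth noise SD), `D`, `wE`, `hR`,
#'   `colourArchetype` (defaults to `archetype`; lets colour and geometry be
#'   decoupled for controlled experiments), `margin` (frame clearance, px).
#' @param seed integer seed.
#' @return A [SyntheticScene-class].
#' @examples
#' sc <- generateScene("attached", list(size = 128, r0 = 30), seed = 1)
#' @export
generateScene <- function(archetype, params = list(), seed = 1L) {
  archetype <- match.arg(archetype, mergedCategories())
  withSeed(seed, {
    p <- list(size = 512L, r0 = NULL, margin = 24,
              amplitudes = NULL, phases = NULL,
              gx = NULL, gy = NULL, sigma = 0.05,
              colourArchetype = archetype)
    p <- utils::modifyList(p, params)
    # default wound radius scales with the frame (90 px at 512)
    if (is.null(p$r0)) p$r0 <- round(p$size * 90 / 512)
    harmonics <- 2:5
    if (is.null(p$amplitudes)) p$amplitudes <- stats::runif(4L, 0, 0.06)
    if (is.null(p$phases)) p$phases <- stats::runif(4L, 0, 2 * pi)
    if (is.null(p$gx)) p$gx <- stats::runif(1L, -0.02, 0.02)
    if (is.null(p$gy)) p$gy <- stats::runif(1L, -0.02, 0.02)
    cdef <- archetypeDefaults(archetype)
    for (nm in c("D", "wE", "hR"))
      if (is.null(p[[nm]])) p[[nm]] <- cdef[[nm]] * stats::runif(1L, 0.9, 1.1)

    size <- as.integer(p$size)
    rmax <- p$r0 * (1 + sum(p$amplitudes))
    if (rmax + p$margin >= size / 2)
      stop("wound exceeds frame: r0 + perturbation + margin must be < size/2")

    ctr <- (size + 1) / 2
    x <- matrix(seq_len(size), size, size, byrow = TRUE)  # col index
    y <- matrix(seq_len(size), size, size)                # row index
    dx <- x - ctr; dy <- y - ctr
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    rho <- p$r0 * (1 + Reduce(`+`, Map(function(a, m, ph)
      a * cos(m * theta + ph), p$amplitudes, harmonics, p$phases)))
    mask <- matrix(as.integer(r <= rho), size, size)

    s <- signedDistance(mask)
    crater <- craterFunction(archetype,
                             p[c("D", "wE", "hR")])
    depth <- p$gx * x + p$gy * y + crater(s)
    if (p$sigma > 0)
      depth <- depth + matrix(stats::rnorm(size^2, 0, p$sigma), size, size)

    cols <- archetypeColours(p$colourArchetype)
    wIn <- stats::plogis(-s / 1.5)
    img <- array(0, dim = c(size, size, 3L))
    for (ch in 1:3)
      img[, , ch] <- wIn * cols$bed[ch] + (1 - wIn) * cols$skin[ch]
    if (p$colourArchetype == "hyperkeratotic") {
      ring <- stats::plogis((s - 1) / 0.8) * stats::plogis((9 - s) / 0.8)
      for (ch in 1:3)
        img[, , ch] <- (1 - ring) * img[, , ch] + ring * cols$callus[ch]
    }
    img <- img + array(stats::rnorm(3 * size^2, 0, cols$noiseSd),
                       dim = dim(img))
    img <- pmin(pmax(img, 0), 1)

    new("SyntheticScene", image = img, mask = mask, depth = depth,
        truth = archetype, params = p, seed = as.integer(seed))
  })
}

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d x %d, truth '%s', seed %d\n",
              nrow(object@mask), ncol(object@mask), object@truth,
              object@seed))
  cat(sprintf("  wound area %d px, depth range [%.2f, %.2f]\n",
              sum(object@mask), min(object@depth), max(object@depth)))
})

#' Build a simulated rater from an error rate or a confusion matrix
#'
#' With `errorRate = e`, the rater reports the true archetype with
#' probability `1 - e` and otherwise draws uniformly from all five merged
#' categories (so the diagonal is `1 - e + e/5`). A full confusion matrix
#' can be supplied instead.
#'
#' @param raterId rater identifier.
#' @param errorRate uniform-error probability in `[0, 1]`.
#' @param confusion optional explicit 5 x 5 row-stochastic matrix (rows =
#'   true archetype, columns = assigned category, merged vocabulary order).
#' @return An [AnnotatorModel-class].
#' @examples
#' annotatorModel("e1", errorRate = 0.2)
#' @export
annotatorModel <- function(raterId, errorRate = 0, confusion = NULL) {
  k <- length(mergedCategories())
  if (is.null(confusion))
    confusion <- (1 - errorRate) * diag(k) + errorRate / k
  dimnames(confusion) <- list(mergedCategories(), mergedCategories())
  new("AnnotatorModel", raterId = raterId, confusion = confusion)
}

#' Simulate multi-rater annotations from confusion-matrix raters
#'
#' Each rater's label for each image is drawn independently from the rater's
#' confusion row for that image's true archetype.
#'
#' @param truths character vector of true archetypes (merged vocabulary).
#' @param models list of [AnnotatorModel-class] raters.
#' @param seed integer seed.
#' @param imageIds optional image identifiers (default `img0001`, ...).
#' @return A merged-vocabulary [AnnotationTable-class].
#' @export
simulateAnnotations <- function(truths, models, seed = 1L, imageIds = NULL) {
  cats <- mergedCategories()
  stopifnot(all(truths %in% cats), length(models) >= 1L)
  n <- length(truths)
  if (is.null(imageIds)) imageIds <- sprintf("img%04d", seq_len(n))
  withSeed(seed, {
    lab <- matrix(NA_character_, n, length(models),
                  dimnames = list(imageIds,
                                  vapply(models, function(m) m@raterId, "")))
    ti <- match(truths, cats)
    for (j in seq_along(models)) {
      cm <- models[[j]]@confusion
      for (t in unique(ti)) {
        rows <- which(ti == t)
        lab[rows, j] <- sample(cats, length(rows), replace = TRUE,
                               prob = cm[t, ])
      }
    }
    annotationTable(lab, merged = TRUE)
  })
}

#' Exact expected Cohen's kappa between two confusion-matrix raters
#'
#' Computes kappa from the exact joint label distribution implied by two
#' raters observing the same items: observed agreement
#' `p_o = sum_t pi_t sum_c A[t,c] B[t,c]`, chance agreement from the
#' marginal label distributions `pi A` and `pi B`, and
#' `kappa = (p_o - p_e) / (1 - p_e)`. Serves as the closed-form oracle for
#' Monte-Carlo agreement checks.
#'
#' @param modelA,modelB [AnnotatorModel-class] raters.
#' @param truthPrior probability vector over the merged archetypes (sums
#'   to 1).
#' @return Expected kappa (numeric scalar).
#' @examples
#' a <- annotatorModel("a", 0)
#' expectedKappa(a, a, rep(0.2, 5))
#' @export
expectedKappa <- function(modelA, modelB,
                          truthPrior = rep(1 / 5, 5)) {
  stopifnot(abs(sum(truthPrior) - 1) < 1e-9, all(truthPrior >= 0))
  A <- modelA@confusion; B <- modelB@confusion
  po <- sum(truthPrior * rowSums(A * B))
  margA <- drop(truthPrior %*% A)
  margB <- drop(truthPrior %*% B)
  pe <- sum(margA * margB)
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: chance agreement p_e = 1")
  (po - pe) / (1 - pe)
}
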