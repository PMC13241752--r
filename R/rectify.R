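# Depth detrending and normal-wise resampling of the peri-wound band into a
# standardized rectangle (arc length x signed normal offset).

#' Remove a least-squares plane from a depth raster
#'
#' Fits `z = a x + b y + c` over the pixels of `region` only (by default the
#' transition band, so the skin-surface orientation dominates the fit and the
#' crater itself does not bias it) and subtracts the plane from the whole
#' raster. This mitigates artefacts of wound orientation relative to the
#' camera before edge profiles are extracted.
#'
#' @param depth numeric matrix.
#' @param region 0/1 matrix of the same size selecting the fit pixels, or a
#'   [TransitionBand-class].
#' @return list with `residual` (matrix, depth minus plane) and `fit`
#'   (a [PlaneFit-class]).
#' @export
detrendDepth <- function(depth, region) {
  if (is(region, "TransitionBand")) region <- region@band
  stopifnot(identical(dim(depth), dim(region)))
  idx <- which(region > 0)
  if (length(idx) < 3L)
    stop("detrend region must contain at least 3 pixels")
  ai <- arrayInd(idx, dim(depth))
  xs <- ai[, 2L]; ys <- ai[, 1L]
  X <- cbind(1, xs, ys)
  if (qr(X)$rank < 3L)
    stop("degenerate detrend region: pixels are collinear")
  coef <- stats::lm.fit(X, depth[idx])$coefficients
  nr <- nrow(depth); nc <- ncol(depth)
  plane <- coef[1L] + coef[2L] * matrix(seq_len(nc), nr, nc, byrow = TRUE) +
    coef[3L] * matrix(seq_len(nr), nr, nc)
  residual <- depth - plane
  rms <- sqrt(mean(residual[idx]^2))
  list(residual = residual,
       fit = new("PlaneFit", a = unname(coef[2L]), b = unname(coef[3L]),
                 c = unname(coef[1L]), rms = rms,
                 region = sprintf("%d px region", length(idx))))
}

setMethod("show", "PlaneFit", function(object) {
  cat(sprintf("PlaneFit: z = %.4g x + %.4g y + %.4g (RMS %.4g, %s)\n",
              object@a, object@b, object@c, object@rms, object@region))
})

#' Resample a raster along contour normals into the standardized band
#'
#' For every contour point `p_k` with outward normal `n_k`, samples the
#' raster by bilinear interpolation at `p_k + delta n_k` for
#' `delta = dOut, dOut - 1, ..., 0, ..., -dIn`. Row `k` of the result
#' follows contour point `k`; columns run outside -> inside with the wound
#' border at column `dOut + 1` (offset `delta = 0`). Samples falling outside
#' the raster are flagged invalid rather than being fatal.
#'
#' @param raster numeric matrix (depth) or H x W x 3 array (RGB).
#' @param contour a [Contour-class].
#' @param dIn,dOut half-widths in pixels.
#' @return A [RectifiedBand-class] with `K x (dIn + dOut + 1)` values.
#' @export
rectifyBand <- function(raster, contour, dIn = 20, dOut = 20) {
  stopifnot(is(contour, "Contour"))
  pts <- contour@points; nrm <- contour@normals
  K <- nrow(pts)
  delta <- seq(dOut, -dIn)
  W <- length(delta)
  sx <- outer(pts[, 1L], rep(1, W)) + outer(nrm[, 1L], delta)
  sy <- outer(pts[, 2L], rep(1, W)) + outer(nrm[, 2L], delta)
  isRGB <- length(dim(raster)) == 3L
  if (isRGB) {
    vals <- array(NA_real_, dim = c(K, W, 3L))
    for (ch in 1:3)
      vals[, , ch] <- matrix(bilinearSample(raster[, , ch], as.vector(sx),
                                            as.vector(sy)), K, W)
    valid <- !is.na(vals[, , 1L])
  } else {
    vals <- matrix(bilinearSample(raster, as.vector(sx), as.vector(sy)),
                   K, W)
    valid <- !is.na(vals)
    dim(vals) <- c(K, W)
  }
  new("RectifiedBand", values = vals, valid = valid,
      dIn = dIn, dOut = dOut, channel = if (isRGB) "rgb" else "depth")
}

setMethod("show", "RectifiedBand", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "RectifiedBand (%s): %d contour rows x %d offsets (border col %d), %.1f%% valid\n",
    object@channel, d[1L], d[2L], borderColumn(object),
    100 * mean(object@valid)))
})

#' @describeIn rectifyBand column index (1-based) of the wound border
#'   (`delta = 0`).
#' @param band a [RectifiedBand-class].
#' @export
borderColumn <- function(band) as.integer(band@dOut + 1)

#' @describeIn rectifyBand signed normal offsets for each column (px,
#'   positive outside).
#' @export
bandOffsets <- function(band) seq(band@dOut, -band@dIn)

#' @describeIn rectifyBand the values array/matrix.
#' @export
bandValues <- function(band) band@values
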