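# Mask cleanup, morphological transition band and ordered contour
# extraction.

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a small union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nLab <- max(lab)
  if (nLab <= 1L) return(lab)
  parent <- seq_len(nLab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]   # down-right diagonal pairs
  pairs <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
  a <- lab[-nr, -1L]; b <- lab[-1L, -nc]   # down-left diagonal pairs
  pairs <- rbind(pairs,
                 cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]))
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) union(pairs[i, 1L], pairs[i, 2L])
  }
  roots <- vapply(seq_len(nLab), find, 1L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Keep only the largest 8-connected wound component
#'
#' Retains the maximal-area 8-connected foreground component (secondary
#' lesions and segmentation artefacts are discarded) and fills any interior
#' holes. Area ties are broken by the component whose lexicographically
#' smallest (row, col) pixel comes first.
#'
#' @param mask integer/logical matrix, foreground non-zero.
#' @return Integer 0/1 matrix with exactly one connected component.
#' @export
largestComponent <- function(mask) {
  mask <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (sum(mask) == 0L) stop("empty mask: no foreground pixels")
  lab <- label8(mask)
  nLab <- max(lab)
  if (nLab > 1L) {
    areas <- tabulate(lab[lab > 0], nbins = nLab)
    cand <- which(areas == max(areas))
    if (length(cand) > 1L) {
      # lexicographic (row, col) of each candidate's first pixel
      firstIdx <- vapply(cand, function(l) {
        w <- which(lab == l, arr.ind = TRUE)
        w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
        w[1L, 1L] * (ncol(mask) + 1) + w[1L, 2L]
      }, 0)
      cand <- cand[which.min(firstIdx)]
    }
    mask <- matrix(as.integer(lab == cand[1L]), nrow(mask), ncol(mask))
  }
  filled <- EBImage::fillHull(mask)
  if (sum(filled) > sum(mask))
    message("largestComponent: filled ", sum(filled) - sum(mask),
            " interior hole pixel(s)")
  matrix(as.integer(filled > 0), nrow(mask), ncol(mask))
}

diskBrush <- function(r) {
  if (r < 1) return(matrix(1L, 1L, 1L))
  EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
}

#' Build the peri-wound transition band by morphology
#'
#' The band is `dilate(mask, disk(dOut)) & !erode(mask, disk(dIn))`: an
#' annulus straddling the wound border, `dOut` pixels outward and `dIn`
#' pixels inward.
#'
#' @param mask single-component 0/1 matrix (see [largestComponent()]).
#' @param dIn,dOut inner and outer half-widths in pixels (`dIn = 0` gives
#'   the purely external band).
#' @return A [TransitionBand-class].
#' @export
transitionBand <- function(mask, dIn = 20, dOut = 20) {
  mask <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  dil <- if (dOut >= 1) EBImage::dilate(mask, diskBrush(dOut)) else mask
  inner <- if (dIn >= 1) EBImage::erode(mask, diskBrush(dIn)) else mask
  if (dIn >= 1 && sum(inner) == 0L)
    stop("erosion by dIn = ", dIn, " annihilates the mask; ",
         "use a smaller dIn")
  band <- matrix(as.integer(dil > 0 & !(inner > 0)), nrow(mask), ncol(mask))
  new("TransitionBand", band = band, dIn = dIn, dOut = dOut)
}

setMethod("show", "TransitionBand", function(object) {
  cat(sprintf("TransitionBand: %d px, dIn = %g, dOut = %g\n",
              sum(object@band), object@dIn, object@dOut))
})

#' Extract a closed, uniformly sampled subpixel contour with outward normals
#'
#' The wound boundary is traced at the 0.5 iso-level of the lightly
#' Gaussian-smoothed mask (sigma = 1 px; smoothing removes the pixel
#' staircase so the traced polygon length approximates the true boundary
#' length instead of overestimating it), resampled to `K` points
#' equally spaced in arc length and oriented counterclockwise. Normals come
#' from central-difference tangents after a 5-point circular moving-average
#' smoothing, rotated 90 degrees and sign-fixed to point away from the wound
#' (checked against the mask 2 px along the normal).
#'
#' @param mask single-component 0/1 matrix not touching the image border.
#' @param K number of contour samples (>= 16).
#' @return A [Contour-class]; points are (x, y) = (col, row), 1-based pixel
#'   centres.
#' @export
extractContour <- function(mask, K = 360) {
  mask <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (sum(mask) < 16L) stop("mask too small for contour extraction")
  nr <- nrow(mask); nc <- ncol(mask)
  if (any(mask[1L, ] > 0) || any(mask[nr, ] > 0) ||
      any(mask[, 1L] > 0) || any(mask[, nc] > 0))
    stop("component touches the image border; contour undefined")
  smooth <- EBImage::gblur(matrix(as.numeric(mask), nr, nc), sigma = 1)
  cl <- grDevices::contourLines(x = seq_len(nr), y = seq_len(nc),
                                z = smooth, levels = 0.5)
  if (length(cl) == 0L) stop("no 0.5 iso-contour found")
  lens <- vapply(cl, function(c0)
    polygonPerimeter(cbind(c0$y, c0$x), closed = FALSE), 0)
  c0 <- cl[[which.max(lens)]]
  pts <- cbind(x = c0$y, y = c0$x)   # contourLines: x = row, y = col
  if (all(pts[1L, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), ]

  # enforce counterclockwise winding (positive shoelace area in (x, y))
  if (polygonArea(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]

  resampleClosed <- function(p, k) {
    closed <- rbind(p, p[1L, ])
    seg <- sqrt(rowSums(diff(closed)^2))
    cum <- c(0, cumsum(seg))
    target <- seq(0, cum[length(cum)], length.out = k + 1L)[seq_len(k)]
    cbind(x = stats::approx(cum, closed[, 1L], xout = target)$y,
          y = stats::approx(cum, closed[, 2L], xout = target)$y)
  }
  # dense resampling + low-pass position smoothing suppresses residual
  # pixel-lattice jitter; final resampling restores uniform arc-length
  # spacing
  dense <- resampleClosed(pts, 4L * K)
  dense[, 1L] <- circularSmooth(dense[, 1L], 9L)
  dense[, 2L] <- circularSmooth(dense[, 2L], 9L)
  res <- resampleClosed(dense, K)
  total <- polygonPerimeter(res)

  # smoothed central-difference tangents -> outward unit normals
  sx <- circularSmooth(res[, 1L], 5L)
  sy <- circularSmooth(res[, 2L], 5L)
  tx <- (c(sx[-1L], sx[1L]) - c(sx[K], sx[-K])) / 2
  ty <- (c(sy[-1L], sy[1L]) - c(sy[K], sy[-K])) / 2
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl
  nxv <- ty; nyv <- -tx                     # rotate tangent by -90 deg
  probe <- bilinearSample(mask, res[, 1L] + 2 * nxv, res[, 2L] + 2 * nyv)
  inside <- !is.na(probe) & probe >= 0.5
  if (mean(inside) > 0.5) { nxv <- -nxv; nyv <- -nyv; inside <- !inside }
  nxv[inside] <- -nxv[inside]; nyv[inside] <- -nyv[inside]

  new("Contour", points = res, normals = cbind(nxv, nyv),
      spacing = total / K, length = total)
}

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour: %d points, length %.1f px (spacing %.3f px)\n",
              nrow(object@points), object@length, object@spacing))
})

#' @describeIn extractContour contour point matrix (K x 2, columns x, y).
#' @param contour a [Contour-class].
#' @export
contourPoints <- function(contour) contour@points

#' @describeIn extractContour outward unit normal matrix (K x 2).
#' @export
contourNormals <- function(contour) contour@normals
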