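# Internal numeric helpers shared across modules.

# Bilinear sampling of a matrix at subpixel (x, y) = (col, row) positions,
# 1-based pixel centres. Returns NA outside [1, ncol] x [1, nrow].
bilinearSample <- function(raster, x, y) {
  nr <- nrow(raster); nc <- ncol(raster)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  v00 <- raster[cbind(y0, x0)]
  v01 <- raster[cbind(y0, x0 + 1)]
  v10 <- raster[cbind(y0 + 1, x0)]
  v11 <- raster[cbind(y0 + 1, x0 + 1)]
  out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

# Round half away from zero to `digits` decimals (Table-style percentages;
# base round() rounds half to even).
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shoelace signed area of a closed polygon given as an n x 2 matrix (no
# repeated end point). Positive for counterclockwise winding in (x, y).
polygonArea <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygonPerimeter <- function(pts, closed = TRUE) {
  d <- diff(pts)
  len <- sum(sqrt(rowSums(d^2)))
  if (closed) {
    last <- pts[1L, ] - pts[nrow(pts), ]
    len <- len + sqrt(sum(last^2))
  }
  len
}

# Circular (periodic) moving average with an odd window.
circularSmooth <- function(v, window = 5L) {
  n <- length(v)
  if (window <= 1L || n < window) return(v)
  h <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, o) ((i + o - 1L) %% n) + 1L)
  rowMeans(matrix(v[idx], nrow = n))
}

# All permutations of 1..n (n small; used for exact assignment).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[[i]] <- block
  }
  do.call(rbind, out)
}

# k-means++ seeding followed by Lloyd iterations; best of `restarts` by
# total within-cluster sum of squares. Deterministic given the RNG state.
kmeansPlusPlus <- function(X, k, restarts = 10L, iterMax = 100L) {
  n <- nrow(X)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
    if (k > 1L) for (j in 2:k) {
      prob <- d2 / sum(d2)
      if (!all(is.finite(prob)) || sum(d2) <= 0)
        pick <- sample.int(n, 1L)
      else
        pick <- sample.int(n, 1L, prob = prob)
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                         byrow = TRUE))^2))
    }
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = iterMax,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

# Macro-averaged precision/recall/F1 and accuracy for categorical vectors
# over a fixed class universe.
classificationMetrics <- function(pred, truth, classes) {
  pred <- factor(pred, levels = classes)
  truth <- factor(truth, levels = classes)
  tab <- table(truth, pred)
  tp <- diag(tab)
  prec <- ifelse(colSums(tab) > 0, tp / colSums(tab), 0)
  rec <- ifelse(rowSums(tab) > 0, tp / rowSums(tab), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(tab) > 0  # macro-average over classes present in truth
  list(accuracy = sum(tp) / sum(tab),
       precision = mean(prec[present]),
       recall = mean(rec[present]),
       f1 = mean(f1[present]))
}

# Shannon entropy of a histogram of `x` with `bins` equal-width bins.
histogramEntropy <- function(x, bins = 32L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(0)
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  h <- tabulate(pmin(bins, 1L + floor((x - rng[1L]) / diff(rng) * bins)),
                nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}
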