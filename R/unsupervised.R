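# Experiment 1: group wounds by depth-derived edge-profile similarity
# without labels, then compare the groups post hoc with rater annotations.

#' Reduce a profile-feature matrix to a low-dimensional embedding
#'
#' `"pca"` (default) uses centred principal components with a deterministic
#' sign convention. `"laplacian"` is a neighbor-embedding alternative: a
#' Laplacian eigenmap of the symmetrised k-nearest-neighbour graph with
#' Gaussian edge weights (bandwidth = median neighbour distance), using the
#' eigenvectors of the smallest non-trivial eigenvalues of the normalised
#' graph Laplacian. Both are deterministic given the seed.
#'
#' @param X n x p numeric matrix.
#' @param method `"pca"` or `"laplacian"`.
#' @param dims target dimensionality (`n >= dims + 1`).
#' @param seed integer seed (recorded; the methods themselves are
#'   deterministic).
#' @param knn neighbourhood size for the Laplacian eigenmap.
#' @return n x dims embedding matrix.
#' @export
reduceEmbedding <- function(X, method = c("pca", "laplacian"), dims = 5,
                            seed = 1L, knn = 10L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < dims + 1) stop("need n >= dims + 1 rows")
  if (all(apply(X, 2L, stats::sd) < 1e-14))
    stop("degenerate input: all columns are constant")
  dims <- min(dims, ncol(X))
  if (method == "pca") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    rot <- pc$rotation[, seq_len(min(dims, ncol(pc$rotation))),
                       drop = FALSE]
    # fix signs: largest-magnitude loading positive
    for (j in seq_len(ncol(rot))) {
      m <- which.max(abs(rot[, j]))
      if (rot[m, j] < 0) rot[, j] <- -rot[, j]
    }
    emb <- scale(X, center = pc$center, scale = FALSE) %*% rot
  } else {
    withSeed(seed, {
      n <- nrow(X)
      k <- min(knn, n - 1L)
      D <- as.matrix(stats::dist(X))
      W <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(D[i, ])[2:(k + 1L)]
        W[i, nb] <- D[i, nb]
      }
      sigma <- stats::median(W[W > 0])
      A <- matrix(0, n, n)
      nz <- W > 0 | t(W) > 0
      A[nz] <- exp(-pmax(W, t(W))[nz]^2 / (2 * sigma^2))
      deg <- rowSums(A)
      deg[deg == 0] <- 1
      L <- diag(n) - diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
      eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
      idx <- order(eig$values)[2:(dims + 1L)]
      emb <- eig$vectors[, idx, drop = FALSE]
      for (j in seq_len(ncol(emb))) {
        m <- which.max(abs(emb[, j]))
        if (emb[m, j] < 0) emb[, j] <- -emb[, j]
      }
    })
  }
  rownames(emb) <- rownames(X)
  colnames(emb) <- paste0("dim", seq_len(ncol(emb)))
  emb
}

#' Cluster an embedding with k-means++ restarts
#'
#' k-means with k-means++ initialisation, 10 restarts, keeping the solution
#' with the lowest total within-cluster sum of squares. Deterministic given
#' the seed.
#'
#' @param embedding n x d numeric matrix (`n >= k`).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts.
#' @return Integer cluster labels (length n).
#' @export
clusterEmbedding <- function(embedding, k = 5, seed = 1L, restarts = 10L) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < k)
    stop("need at least k = ", k, " rows, got ", nrow(embedding))
  withSeed(seed, {
    km <- kmeansPlusPlus(embedding, k, restarts = restarts)
    as.integer(km$cluster)
  })
}

#' Compare unsupervised groups post hoc with rater annotations
#'
#' For each rater: optimal cluster-to-category matching ([alignLabels()])
#' followed by Cohen's kappa of the relabeled clusters, plus the Adjusted
#' Rand Index of the raw partitions (ARI needs no alignment). The headline
#' single ARI is reported against a configurable reference rater.
#'
#' @param labels integer cluster labels aligned with the table rows.
#' @param table an [AnnotationTable-class] (merged vocabulary).
#' @param embedding optional embedding to carry along in the result.
#' @param referenceRater rater id for the headline ARI (default: first).
#' @return A [ClusterResult-class].
#' @export
evaluateUnsupervised <- function(labels, table, embedding = NULL,
                                 referenceRater = NULL) {
  stopifnot(is(table, "AnnotationTable"))
  lab <- labelMatrix(table)
  if (length(labels) != nrow(lab))
    stop("cluster labels (", length(labels), ") do not match table rows (",
         nrow(lab), ")")
  if (is.null(referenceRater)) referenceRater <- colnames(lab)[1L]
  raters <- colnames(lab)
  kap <- ari <- numeric(length(raters))
  mappings <- vector("list", length(raters))
  names(mappings) <- raters
  for (j in seq_along(raters)) {
    al <- alignLabels(labels, lab[, j])
    kap[j] <- cohenKappa(al$relabeled, lab[, j])
    ari[j] <- adjustedRand(labels, lab[, j])
    mappings[[j]] <- al$mapping
  }
  new("ClusterResult",
      embedding = if (is.null(embedding)) matrix(numeric(0), 0, 0)
                  else as.matrix(embedding),
      labels = as.integer(labels),
      perRater = data.frame(rater = raters, kappa = kap, ari = ari,
                            stringsAsFactors = FALSE),
      mappings = mappings,
      meanKappa = mean(kap),
      sdKappa = if (length(kap) > 1L) stats::sd(kap) else 0,
      ari = ari[match(referenceRater, raters)],
      referenceRater = referenceRater)
}

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: %d items, %d clusters; kappa = %.3f +/- %.3f, ARI(%s) = %.3f\n",
    length(object@labels), length(unique(object@labels)),
    object@meanKappa, object@sdKappa, object@referenceRater, object@ari))
  print(object@perRater, row.names = FALSE)
})

#' Run the full unsupervised experiment
#'
#' Reduce the profile matrix, cluster the embedding, and evaluate against
#' the annotation table.
#'
#' @param profMat profile-feature matrix (see [profileMatrix()]).
#' @param table an [AnnotationTable-class] aligned with the matrix rows.
#' @param config a [RunConfig-class].
#' @return A [ClusterResult-class].
#' @export
runUnsupervised <- function(profMat, table, config = periConfig()) {
  emb <- reduceEmbedding(profMat, config@reduceMethod, config@dims,
                         seed = config@seed)
  labels <- clusterEmbedding(emb, config@k, seed = config@seed)
  evaluateUnsupervised(labels, table, embedding = emb)
}
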