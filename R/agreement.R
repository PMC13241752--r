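# Chance-corrected agreement statistics shared by both experiments:
# Cohen's kappa, pairwise rater agreement, Adjusted Rand Index, exact
# optimal cluster-to-label assignment, and the pooled two-sample t-test.

#' Cohen's kappa between two categorical label vectors
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is the observed agreement
#' fraction and `p_e` the chance agreement from the two raters' marginal
#' label distributions. Unweighted (categories are nominal). Ranges from -1
#' to 1; 0 is chance-level agreement.
#'
#' @param a,b equal-length label vectors (character or factor).
#' @return kappa (numeric scalar).
#' @examples
#' cohenKappa(c("x", "x", "y"), c("x", "y", "y"))
#' @export
cohenKappa <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b))
    stop("label vectors differ in length (", length(a), " vs ",
         length(b), ")")
  if (length(a) < 2L) stop("need at least 2 items")
  lev <- sort(unique(c(a, b)))
  fa <- factor(a, levels = lev); fb <- factor(b, levels = lev)
  po <- mean(a == b)
  pe <- sum(table(fa) / length(a) * table(fb) / length(b))
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: both raters constant and equal (p_e = 1)")
  unname((po - pe) / (1 - pe))
}

#' Pairwise Cohen's kappa over all raters of an annotation table
#'
#' Computes kappa for every rater pair and summarises the off-diagonal upper
#' triangle as mean +/- sample SD (SD over the C(R,2) pairs; 0 by convention
#' when there is a single pair).
#'
#' @param table an [AnnotationTable-class] with >= 2 raters.
#' @return An [AgreementReport-class].
#' @export
pairwiseKappa <- function(table) {
  stopifnot(is(table, "AnnotationTable"))
  lab <- labelMatrix(table)
  R <- ncol(lab)
  if (R < 2L) stop("need at least 2 raters")
  km <- diag(1, R)
  dimnames(km) <- list(colnames(lab), colnames(lab))
  for (i in seq_len(R - 1L)) for (j in (i + 1L):R)
    km[i, j] <- km[j, i] <- cohenKappa(lab[, i], lab[, j])
  up <- km[upper.tri(km)]
  new("AgreementReport", raters = colnames(lab), kappa = km,
      mean = mean(up), sd = if (length(up) > 1L) stats::sd(up) else 0)
}

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport: %d raters, kappa = %.3f +/- %.3f\n",
              length(object@raters), object@mean, object@sd))
  print(round(object@kappa, 3))
})

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected similarity of two partitions of the same items:
#' `ARI = (Index - Expected) / (Max - Expected)` over pair counts of the
#' contingency table. Invariant to any relabeling of either partition.
#'
#' @param a,b equal-length partition label vectors.
#' @return ARI (numeric scalar; 1 for identical partitions, ~0 at chance).
#' @export
adjustedRand <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 items")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  index <- sum(ch2(tab))
  rowPairs <- sum(ch2(rowSums(tab)))
  colPairs <- sum(ch2(colSums(tab)))
  expected <- rowPairs * colPairs / ch2(n)
  maxIndex <- (rowPairs + colPairs) / 2
  if (abs(maxIndex - expected) < 1e-12) return(0)
  (index - expected) / (maxIndex - expected)
}

#' Optimal one-to-one matching of predicted groups to reference categories
#'
#' Solves the assignment problem on the contingency table exactly (by
#' enumeration over injective mappings; group counts here never exceed six),
#' maximizing the total diagonal count, and returns the relabeled
#' predictions. Reference categories that receive no predicted group are
#' simply never predicted.
#'
#' @param pred predicted group labels (any values).
#' @param ref reference category labels; must have at least as many distinct
#'   values as `pred`.
#' @return list with `mapping` (named character vector, predicted group ->
#'   reference category) and `relabeled` (character vector aligned with
#'   `pred`).
#' @export
alignLabels <- function(pred, ref) {
  pred <- as.character(pred); ref <- as.character(ref)
  stopifnot(length(pred) == length(ref))
  gp <- sort(unique(pred)); gr <- sort(unique(ref))
  if (length(gp) > length(gr))
    stop("more predicted groups (", length(gp), ") than reference ",
         "categories (", length(gr), ")")
  tab <- table(factor(pred, levels = gp), factor(ref, levels = gr))
  perms <- allPermutations(length(gr))
  take <- perms[, seq_along(gp), drop = FALSE]   # injective assignments
  take <- unique(take)
  scores <- apply(take, 1L, function(asg)
    sum(tab[cbind(seq_along(gp), asg)]))
  bestAsg <- take[which.max(scores), ]
  mapping <- gr[bestAsg]
  names(mapping) <- gp
  list(mapping = mapping, relabeled = unname(mapping[pred]))
}

#' Pooled-variance two-sample Student's t-test
#'
#' Classical equal-variance two-sided t-test (via [stats::t.test()] with
#' `var.equal = TRUE`).
#'
#' @param x,y numeric samples, each with >= 2 values.
#' @return list with `t`, `p`, `df`, and the two sample means.
#' @export
twoSampleT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(x) + stats::var(y) == 0)
    stop("degenerate t-test: zero variance in both samples")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), meanX = mean(x), meanY = mean(y))
}
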