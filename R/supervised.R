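# Experiment 2: supervised reproduction of each rater's wound-edge labels,
# comparing geometry-only against full-feature descriptor sets across
# repeated stratified cross-validation.

# Stratified fold assignment: within each class, shuffled round-robin.
stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

classWeights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  w[match(y, names(tab))]
}

fitClassifier <- function(X, y, classes, config) {
  w <- classWeights(y)
  if (config@classifier == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(X, label = match(y, classes) - 1L,
                                   weight = w)
    params <- list(objective = "multi:softprob",
                   num_class = length(classes),
                   max_depth = 4, eta = 0.15,
                   subsample = 0.9, colsample_bytree = 0.9,
                   nthread = 1, verbosity = 0)
    model <- xgboost::xgb.train(params, dtrain, nrounds = 120, verbose = 0)
    list(kind = "xgboost", model = model, classes = classes)
  } else {
    df <- as.data.frame(X)
    fit <- ranger::ranger(y = factor(y, levels = classes), x = df,
                          num.trees = 300, case.weights = w,
                          num.threads = 1,
                          seed = sample.int(.Machine$integer.max, 1L))
    list(kind = "ranger", model = fit, classes = classes)
  }
}

predictClassifier <- function(fit, X) {
  if (fit$kind == "xgboost") {
    pr <- predict(fit$model, xgboost::xgb.DMatrix(X))
    if (!is.matrix(pr))
      pr <- matrix(pr, ncol = length(fit$classes), byrow = TRUE)
    fit$classes[max.col(pr, ties.method = "first")]
  } else {
    as.character(predict(fit$model, data = as.data.frame(X),
                         num.threads = 1)$predictions)
  }
}

#' Train and evaluate a supervised wound-edge classifier per rater
#'
#' For every rater, a model (gradient-boosted trees by default, random
#' forest optional) is trained on that rater's merged five-category labels
#' and evaluated by repeated stratified cross-validation: within each
#' repeat, out-of-fold predictions over all folds are pooled and Cohen's
#' kappa against the rater is recorded, giving a repeats x raters matrix of
#' per-run kappa values. Accuracy and macro precision/recall/F1 are averaged
#' over repeats. Geometry-only and full-feature runs with the same seed use
#' identical fold assignments (paired design). Permutation feature
#' importance (accuracy drop on held-out folds of the first repeat,
#' averaged, clipped at zero and normalised to sum 1) is attached.
#'
#' @param features n x p feature matrix (rows = images, named columns).
#' @param groups per-column `"geometry"`/`"visual"` tags
#'   (see [featureGroups()]).
#' @param table a merged-vocabulary [AnnotationTable-class] whose rows align
#'   with `features`.
#' @param featureSet `"geometry"` (geometry-tagged columns only) or
#'   `"full"`.
#' @param config a [RunConfig-class] (folds, repeats, classifier).
#' @param seed fold/training seed; defaults to `config@seed`.
#' @param nPermutations permutations per feature for the importance
#'   analysis (0 disables it).
#' @return A [ClassifierReport-class].
#' @export
trainEval <- function(features, groups, table,
                      featureSet = c("full", "geometry"),
                      config = periConfig(), seed = NULL,
                      nPermutations = 5L) {
  featureSet <- match.arg(featureSet)
  stopifnot(is(table, "AnnotationTable"), isMerged(table))
  lab <- labelMatrix(table)
  if (nrow(features) != nrow(lab))
    stop("feature rows (", nrow(features), ") do not match table rows (",
         nrow(lab), ")")
  if (!is.null(rownames(features)) &&
      !identical(rownames(features), rownames(lab)))
    stop("feature row ids do not match annotation image ids")
  if (is.null(seed)) seed <- config@seed
  cols <- if (featureSet == "geometry") which(groups == "geometry")
          else seq_along(groups)
  X <- as.matrix(features[, cols, drop = FALSE])
  classes <- mergedCategories()
  raters <- colnames(lab)
  nRep <- as.integer(config@repeats); nFold <- as.integer(config@folds)

  perRun <- matrix(NA_real_, nRep, length(raters),
                   dimnames = list(NULL, raters))
  perRater <- data.frame()
  impAcc <- stats::setNames(numeric(ncol(X)), colnames(X))
  impN <- 0L

  for (j in seq_along(raters)) {
    y <- lab[, j]
    if (length(unique(y)) < 2L) {
      warning("rater '", raters[j], "' uses < 2 classes; skipped")
      next
    }
    mets <- vector("list", nRep)
    for (r in seq_len(nRep)) {
      # fold seed depends only on (seed, rater, repeat): identical folds
      # for both feature sets
      withSeed(seed + 7919L * r + 104729L * j, {
        folds <- stratifiedFolds(y, nFold)
        pred <- character(length(y))
        for (f in seq_len(nFold)) {
          tr <- folds != f; te <- !tr
          if (!any(te)) next
          fit <- fitClassifier(X[tr, , drop = FALSE], y[tr], classes,
                               config)
          pred[te] <- predictClassifier(fit, X[te, , drop = FALSE])
          if (r == 1L && nPermutations > 0L) {
            baseAcc <- mean(pred[te] == y[te])
            for (v in seq_len(ncol(X))) {
              drop <- 0
              for (q in seq_len(nPermutations)) {
                Xp <- X[te, , drop = FALSE]
                Xp[, v] <- sample(Xp[, v])
                drop <- drop +
                  (baseAcc - mean(predictClassifier(fit, Xp) == y[te]))
              }
              impAcc[v] <- impAcc[v] + drop / nPermutations
            }
            impN <- impN + 1L
          }
        }
        perRun[r, j] <- cohenKappa(pred, y)
        mets[[r]] <- classificationMetrics(pred, y, classes)
      })
    }
    mm <- function(nm) mean(vapply(mets, function(m) m[[nm]], 0))
    perRater <- rbind(perRater, data.frame(
      rater = raters[j], kappa = mean(perRun[, j]),
      accuracy = mm("accuracy"), precision = mm("precision"),
      recall = mm("recall"), f1 = mm("f1"), stringsAsFactors = FALSE))
  }

  keep <- !is.na(perRun[1L, ])
  perRun <- perRun[, keep, drop = FALSE]
  imp <- pmax(impAcc, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp)
         else stats::setNames(rep(1 / length(imp), length(imp)),
                              names(imp))
  allRuns <- as.vector(perRun)
  new("ClassifierReport", featureSet = featureSet, perRater = perRater,
      perRun = perRun, meanKappa = mean(allRuns),
      sdKappa = if (length(allRuns) > 1L) stats::sd(allRuns) else 0,
      importances = imp, columns = colnames(X), seed = as.integer(seed))
}

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf(
    "ClassifierReport (%s, %d features): kappa = %.3f +/- %.3f over %d runs\n",
    object@featureSet, length(object@columns), object@meanKappa,
    object@sdKappa, length(object@perRun)))
  print(object@perRater, row.names = FALSE, digits = 3)
})

#' Compare geometry-only and full-feature classifier reports
#'
#' Two-sample Student's t-test (pooled variance, two-sided) on the per-run
#' kappa values of the two reports. Both reports must come from identical
#' cross-validation splits: same raters, same run counts, same seed.
#'
#' @param reportGeo,reportFull [ClassifierReport-class] objects for the
#'   geometry-only and full feature sets.
#' @return list with `t`, `p`, `df`, `meanGeometry`, `meanFull`,
#'   `sdGeometry`, `sdFull`.
#' @export
compareFeatureSets <- function(reportGeo, reportFull) {
  stopifnot(is(reportGeo, "ClassifierReport"),
            is(reportFull, "ClassifierReport"))
  if (!identical(dim(reportGeo@perRun), dim(reportFull@perRun)) ||
      !identical(colnames(reportGeo@perRun), colnames(reportFull@perRun)))
    stop("reports are not comparable: different raters or run counts")
  if (reportGeo@seed != reportFull@seed)
    stop("reports are not comparable: different seeds (fold assignments)")
  ht <- twoSampleT(as.vector(reportGeo@perRun),
                   as.vector(reportFull@perRun))
  list(t = ht$t, p = ht$p, df = ht$df,
       meanGeometry = reportGeo@meanKappa, meanFull = reportFull@meanKappa,
       sdGeometry = reportGeo@sdKappa, sdFull = reportFull@sdKappa)
}
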