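# Shared fixtures, all built in code.

# Exact radial-distance matrix and digitized disk mask.
radialGrid <- function(n = 128) {
  ctr <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  sqrt((x - ctr)^2 + (y - ctr)^2)
}

diskMask <- function(n = 128, r = 50) {
  matrix(as.integer(radialGrid(n) <= r), n, n)
}

# Desk-scale synthetic scene parameters used throughout the tests (the
# generator defaults are 512 px frames; tests run at 160 px so whole suites
# stay fast).
testSceneParams <- function(...) {
  utils::modifyList(list(size = 160, r0 = 40), list(...))
}

testConfig <- function(...) {
  do.call(periConfig,
          utils::modifyList(list(dIn = 12, dOut = 12, K = 180, seed = 1L),
                            list(...)))
}

# Per-rater marginal counts of the four-expert annotation summary (raw
# six-category vocabulary), used to rebuild a worked-example table: rows are
# raters e1..e4, columns follow rawCategories().
expertMarginals <- function() {
  m <- rbind(
    e1 = c(57, 718, 523, 83, 255, 224),
    e2 = c(115, 612, 788, 207, 72, 66),
    e3 = c(84, 981, 231, 82, 400, 82),
    e4 = c(67, 893, 634, 90, 149, 27))
  storage.mode(m) <- "integer"
  colnames(m) <- rawCategories()
  m
}

# Build an AnnotationTable realising those per-rater marginals (any row
# arrangement realises per-rater counts).
expertTable <- function() {
  m <- expertMarginals()
  lab <- vapply(rownames(m), function(r)
    rep(rawCategories(), times = m[r, ]), character(1860))
  rownames(lab) <- sprintf("img%04d", seq_len(nrow(lab)))
  annotationTable(lab)
}

# A small archetype-balanced scene set with per-scene features; cached per
# test file run.
makeSceneSet <- function(perClass = 4, seedBase = 1000, params = list()) {
  classes <- rep(mergedCategories(), each = perClass)
  scenes <- lapply(seq_along(classes), function(i)
    generateScene(classes[i],
                  utils::modifyList(testSceneParams(), params),
                  seed = seedBase + i))
  names(scenes) <- sprintf("img%04d", seq_along(scenes))
  list(scenes = scenes, classes = classes)
}
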