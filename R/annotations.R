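#' Construct an AnnotationTable from a label matrix or data.frame
#'
#' @param labels character matrix (rows = images, columns = raters) with
#'   rownames/colnames, or a data.frame whose first column is `image_id`.
#' @param merged whether labels use the merged five-category vocabulary.
#' @return An [AnnotationTable-class] object.
#' @examples
#' lab <- matrix(c("attached", "fibrotic", "indistinct", "attached"),
#'               2, 2, dimnames = list(c("img1", "img2"), c("e1", "e2")))
#' annotationTable(lab)
#' @export
annotationTable <- function(labels, merged = FALSE) {
  if (is.data.frame(labels)) {
    ids <- as.character(labels[[1L]])
    m <- as.matrix(labels[, -1L, drop = FALSE])
    storage.mode(m) <- "character"
    rownames(m) <- ids
    labels <- m
  }
  new("AnnotationTable", labels = labels, merged = merged)
}

#' @describeIn annotationTable image identifiers (row order preserved).
#' @param object,x an `AnnotationTable`.
#' @export
imageIds <- function(object) rownames(object@labels)

#' @describeIn annotationTable rater identifiers.
#' @export
raterIds <- function(object) colnames(object@labels)

#' @describeIn annotationTable the underlying character label matrix.
#' @export
labelMatrix <- function(object) object@labels

#' @describeIn annotationTable whether the table is in the merged state.
#' @export
isMerged <- function(object) object@merged

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d images x %d raters (%s vocabulary)\n",
              nrow(object@labels), ncol(object@labels),
              if (object@merged) "merged 5-category" else "raw 6-category"))
  cat("raters:", paste(colnames(object@labels), collapse = ", "), "\n")
})

setMethod("dim", "AnnotationTable", function(x) dim(x@labels))

#' Read a multi-rater wound-edge annotation table from CSV
#'
#' Expects a header `image_id,<rater1>,<rater2>,...` and lower-snake-case
#' category strings from the raw six-category vocabulary (or the merged one
#' with `merged = TRUE`). Every cell must be filled; unknown categories,
#' duplicated image ids and missing cells are errors that cite the offending
#' row.
#'
#' @param path CSV file path.
#' @param merged whether the file uses the merged vocabulary.
#' @return An [AnnotationTable-class].
#' @seealso [writeAnnotations()], [mergeCategories()]
#' @export
readAnnotations <- function(path, merged = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = character(0))
  if (ncol(df) < 2L || names(df)[1L] != "image_id")
    stop("annotation CSV must have header 'image_id,<rater>,...'")
  ids <- df[["image_id"]]
  if (anyDuplicated(ids))
    stop("duplicate image_id '", ids[duplicated(ids)][1L],
         "' at row ", which(duplicated(ids))[1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "character"
  rownames(m) <- ids
  blank <- which(is.na(m) | m == "", arr.ind = TRUE)
  if (nrow(blank) > 0L)
    stop(sprintf("missing label for image '%s', rater '%s' (row %d)",
                 ids[blank[1L, 1L]], colnames(m)[blank[1L, 2L]],
                 blank[1L, 1L]))
  vocab <- if (merged) mergedCategories() else rawCategories()
  bad <- which(!(m %in% vocab), arr.ind = FALSE)
  if (length(bad) > 0L) {
    ai <- arrayInd(bad[1L], dim(m))
    stop(sprintf("unknown category '%s' at row %d (image '%s', rater '%s')",
                 m[bad[1L]], ai[1L], ids[ai[1L]], colnames(m)[ai[2L]]))
  }
  annotationTable(m, merged = merged)
}

#' Write an AnnotationTable to CSV
#'
#' Inverse of [readAnnotations()]: round-trips every cell byte-for-byte.
#'
#' @param table an [AnnotationTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(table, path) {
  stopifnot(is(table, "AnnotationTable"))
  df <- data.frame(image_id = rownames(table@labels),
                   table@labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge the rolled-under and fibrotic categories
#'
#' Collapses `rolled_under` and `fibrotic` into the single `rolled_fibrotic`
#' category, reflecting their substantial visual overlap on two-dimensional
#' photographs; all other labels are unchanged. The resulting table is in the
#' merged five-category state.
#'
#' @param table a raw-vocabulary [AnnotationTable-class].
#' @return The merged [AnnotationTable-class].
#' @export
mergeCategories <- function(table) {
  stopifnot(is(table, "AnnotationTable"))
  if (isMerged(table))
    stop("table is already in the merged five-category state")
  m <- table@labels
  m[m %in% c("rolled_under", "fibrotic")] <- "rolled_fibrotic"
  annotationTable(m, merged = TRUE)
}

#' Per-category counts and dataset percentages for one rater
#'
#' Percentages are relative to the total number of images and rounded half
#' away from zero to one decimal, the convention used in per-rater annotation
#' summaries.
#'
#' @param table an [AnnotationTable-class].
#' @param raterId rater column to summarise.
#' @return data.frame with columns `category`, `count`, `percent`, one row
#'   per vocabulary category (including zero counts).
#' @examples
#' lab <- matrix("attached", 4, 1, dimnames = list(paste0("i", 1:4), "e1"))
#' categoryCounts(annotationTable(lab), "e1")
#' @export
categoryCounts <- function(table, raterId) {
  stopifnot(is(table, "AnnotationTable"))
  if (!raterId %in% raterIds(table))
    stop("unknown rater '", raterId, "'; raters: ",
         paste(raterIds(table), collapse = ", "))
  vocab <- if (isMerged(table)) mergedCategories() else rawCategories()
  n <- nrow(table@labels)
  cnt <- table(factor(table@labels[, raterId], levels = vocab))
  data.frame(category = vocab,
             count = as.integer(cnt),
             percent = roundHalfUp(100 * as.integer(cnt) / n, 1L),
             stringsAsFactors = FALSE)
}
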