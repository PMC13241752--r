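# Raster I/O: RGB photographs (PNG), binary masks (PNG, foreground > 0) and
# float depth rasters (single-channel float32 TIFF).

#' Read and write wound rasters
#'
#' `readImageRGB` reads an 8-bit PNG (or TIFF) photograph as an H x W x 3
#' array in `[0, 1]`. `readWoundMask` reads a mask PNG, treating any value
#' > 0 as foreground. `readDepthRaster` reads a single-channel float TIFF.
#' The matching writers produce the same containers; depth is written as
#' uncompressed IEEE float32 TIFF so that values are preserved exactly
#' (including negatives).
#'
#' @param path file path.
#' @return `readImageRGB`: numeric array H x W x 3; `readWoundMask`: integer
#'   0/1 matrix; `readDepthRaster`: numeric matrix.
#' @name rasterIO
NULL

#' @rdname rasterIO
#' @export
readImageRGB <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname rasterIO
#' @export
readWoundMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m > 0), nrow(m), ncol(m))
}

#' @rdname rasterIO
#' @export
readDepthRaster <- function(path) {
  d <- tiff::readTIFF(path)
  if (length(dim(d)) == 3L) d <- d[, , 1L]
  d
}

#' @rdname rasterIO
#' @param image H x W x 3 array in `[0, 1]`.
#' @export
writeImageRGB <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname rasterIO
#' @param mask integer/logical matrix, foreground non-zero.
#' @export
writeWoundMask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname rasterIO
#' @param depth numeric matrix.
#' @export
writeDepthRaster <- function(depth, path) {
  writeFloatTiff(depth, path)
  invisible(path)
}

# Minimal single-strip uncompressed float32 grayscale TIFF writer
# (little-endian, SampleFormat = IEEE float). Needed because the installed
# TIFF bindings only write integer sample formats clipped to [0, 1].
writeFloatTiff <- function(depth, path) {
  stopifnot(is.matrix(depth), all(is.finite(depth)))
  h <- nrow(depth); w <- ncol(depth)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  writeBin(charToRaw("II"), con); u16(42L); u32(8L)  # header, IFD at byte 8
  nTags <- 11L
  ifdSize <- 2L + nTags * 12L + 4L
  dataOffset <- 8L + ifdSize
  tag <- function(id, type, count, value) {  # type 3 = SHORT, 4 = LONG
    u16(id); u16(type); u32(count)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }
  u16(nTags)
  tag(256L, 4L, 1L, w)                     # ImageWidth
  tag(257L, 4L, 1L, h)                     # ImageLength
  tag(258L, 3L, 1L, 32L)                   # BitsPerSample
  tag(259L, 3L, 1L, 1L)                    # Compression: none
  tag(262L, 3L, 1L, 1L)                    # Photometric: BlackIsZero
  tag(273L, 4L, 1L, dataOffset)            # StripOffsets
  tag(277L, 3L, 1L, 1L)                    # SamplesPerPixel
  tag(278L, 4L, 1L, h)                     # RowsPerStrip
  tag(279L, 4L, 1L, 4L * w * h)            # StripByteCounts
  tag(284L, 3L, 1L, 1L)                    # PlanarConfiguration
  tag(339L, 3L, 1L, 3L)                    # SampleFormat: IEEE float
  u32(0L)                                  # next IFD: none
  # row-major pixel data
  writeBin(as.numeric(t(depth)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Write and read a synthetic scene as standard raster files
#'
#' Writes `<stem>_image.png`, `<stem>_mask.png` and `<stem>_depth.tiff` into
#' `dir` and returns the three paths. `readSceneFiles` loads such a triplet
#' back into a plain list.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if missing).
#' @param stem file-name stem, default the scene's truth label plus seed.
#' @return Named character vector of paths (image, mask, depth).
#' @export
writeSceneFiles <- function(scene, dir, stem = NULL) {
  stopifnot(is(scene, "SyntheticScene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- sprintf("%s_%d", scene@truth, scene@seed)
  paths <- c(image = file.path(dir, paste0(stem, "_image.png")),
             mask = file.path(dir, paste0(stem, "_mask.png")),
             depth = file.path(dir, paste0(stem, "_depth.tiff")))
  writeImageRGB(scene@image, paths[["image"]])
  writeWoundMask(scene@mask, paths[["mask"]])
  writeDepthRaster(scene@depth, paths[["depth"]])
  paths
}

#' @rdname writeSceneFiles
#' @param paths named character vector as returned by `writeSceneFiles`.
#' @export
readSceneFiles <- function(paths) {
  list(image = readImageRGB(paths[["image"]]),
       mask = readWoundMask(paths[["mask"]]),
       depth = readDepthRaster(paths[["depth"]]))
}
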