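# PNG/TIFF raster I/O.  Everything downstream works on H x W x 3 arrays of
# unit-range doubles; 8- and 16-bit integer files are scaled on read by the
# underlying readers.

#' Read an RGB image from PNG or TIFF
#'
#' Grayscale inputs are promoted to three identical channels with a message;
#' an alpha channel, if present, is dropped with a message.
#'
#' @param path File path; format chosen from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @return An H x W x 3 array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image(): no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("read_image(): unsupported extension '", ext, "' (PNG/TIFF only)"))
  if (is.matrix(x)) {
    message("read_image(): grayscale input promoted to 3 identical channels")
    x <- array(rep(x, 3L), c(dim(x), 3L))
  } else if (length(dim(x)) == 3L && dim(x)[3L] == 2L) {
    message("read_image(): grayscale+alpha input; alpha dropped, channels replicated")
    x <- array(rep(x[, , 1L], 3L), c(dim(x)[1:2], 3L))
  } else if (length(dim(x)) == 3L && dim(x)[3L] == 4L) {
    message("read_image(): alpha channel dropped")
    x <- x[, , 1:3, drop = FALSE]
  }
  if (length(dim(x)) != 3L || dim(x)[3L] != 3L)
    stop("read_image(): unsupported channel layout in ", path)
  pmin(pmax(x, 0), 1)
}

#' Write an RGB array to PNG or TIFF
#'
#' @param img An H x W x 3 array in `[0, 1]` (clipped on write), or an
#'   H x W matrix for grayscale output.
#' @param path Destination; format chosen from the extension.  The file is
#'   written to a temporary sibling and renamed, so a failed write never
#'   leaves a partial output.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", ext))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  switch(ext,
    png = png::writePNG(img, tmp),
    tif = , tiff = tiff::writeTIFF(img, tmp, bits.per.sample = 16L),
    stop("write_image(): unsupported extension '", ext, "'"))
  if (!file.rename(tmp, path)) stop("write_image(): could not move output into place")
  invisible(path)
}
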