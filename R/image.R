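#' Pseudo-color images
#'
#' A pseudo-color image is a plain `H x W x 3` integer array with channel
#' values in 0-255, in R, G, B channel order. Exoscope systems that cannot
#' export raw grayscale NIR frames paint detected fluorescence as blue in an
#' ordinary 24-bit photograph; all measurements in this package operate on
#' that rendering.
#'
#' `as_pseudocolor()` validates (and coerces) an array; `is_pseudocolor()`
#' tests without erroring.
#'
#' @param pixels an `H x W x 3` numeric array with values in 0-255.
#' @return `as_pseudocolor()` returns the validated integer array.
#' @export
as_pseudocolor <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_fq("a pseudo-color image must be an H x W x 3 array")
  if (anyNA(pixels)) stop_fq("image contains missing values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_fq("channel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  pixels
}

#' @rdname as_pseudocolor
#' @export
is_pseudocolor <- function(pixels) {
  is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L &&
    !anyNA(pixels) && min(pixels) >= 0 && max(pixels) <= 255
}

#' Read and write pseudo-color images
#'
#' PNG is read/written through the \pkg{png} package; TIFF through \pkg{tiff}
#' when it is installed. Both formats store channels on `[0, 1]`; values are
#' rescaled to the 0-255 integer convention on read and back on write.
#' Alpha channels, if present, are dropped.
#'
#' @param path file path; format is chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `read_image()` returns an `H x W x 3` integer array;
#'   `write_image()` returns `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_fq("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop_fq("unsupported image format: .", ext)
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  as_pseudocolor(round(raw * 255))
}

#' @rdname read_image
#' @param image an `H x W x 3` pseudo-color image array.
#' @export
write_image <- function(image, path) {
  image <- as_pseudocolor(image)
  ext <- tolower(tools::file_ext(path))
  scaled <- image / 255
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_fq("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(scaled, path)
    },
    stop_fq("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Write a boolean mask as a 0/255 grayscale PNG
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a 0/255 mask PNG back to a logical matrix
#'
#' @param path PNG path.
#' @return logical matrix; pixels with value >= 0.5 are `TRUE`.
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw >= 0.5
}
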