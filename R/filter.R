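#' Median-filter a pseudo-color image
#'
#' Applies an independent median filter to each of the three channels over a
#' square `(2 * radius + 1)^2` neighborhood, the standard denoising step
#' applied to specimen photographs before color thresholding. Image borders
#' use replicate (clamp-to-edge) padding, so every window holds an odd
#' number of samples and the output is always one of the input values of
#' that channel. `radius = 0` returns the image unchanged.
#'
#' @param image an `H x W x 3` pseudo-color image array (0-255).
#' @param radius non-negative integer window radius; the default 1 gives the
#'   common 3x3 kernel.
#' @return a filtered image of the same dimensions.
#' @export
median_filter <- function(image, radius = 1L) {
  image <- as_pseudocolor(image)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 0L) stop_fq("radius must be >= 0")
  if (radius == 0L) return(image)
  .median_filter_cpp(image, radius)
}
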