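#' Convert a pseudo-color image to hue/saturation/intensity planes on 0-255
#'
#' Image-analysis packages used for color thresholding of surgical
#' fluorescence report hue and intensity on a 0-255 scale. This function
#' reproduces that convention: the circular HSV hue angle in `[0, 360)`
#' degrees is rescaled by 255/360 and rounded to the nearest integer, so
#' pure blue (240 degrees) maps to 170 - the centre of the 165-180 band in
#' which blue pseudo-colored fluorescence falls. Intensity is the HSV value
#' channel (the maximum of R, G, B), which for integer input is exact.
#' Saturation is rescaled to 0-255 and never gates any threshold; it is
#' carried only for inspection. Achromatic pixels (saturation 0, e.g. the
#' white background) are assigned hue 0 by convention, which lies outside
#' the blue band, so background can never pass a blue-band threshold.
#'
#' @param image an `H x W x 3` pseudo-color image array (0-255).
#' @return an object of class `hsi_view`: a list of three `H x W` integer
#'   matrices `hue`, `saturation`, `intensity`, all on 0-255.
#' @examples
#' px <- array(0L, c(1, 1, 3)); px[1, 1, 3] <- 255L  # pure blue
#' v <- rgb_to_hsi(px)
#' v$hue[1, 1]        # 170
#' v$intensity[1, 1]  # 255
#' @export
rgb_to_hsi <- function(image) {
  image <- as_pseudocolor(image)
  dm <- dim(image)[1:2]
  r <- as.numeric(image[, , 1])
  g <- as.numeric(image[, , 2])
  b <- as.numeric(image[, , 3])
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  # hue angle in degrees from the standard hexagonal projection; computed
  # on the raw 0-255 channels so integer inputs give exact ratios
  ang <- numeric(length(r))
  chrom <- d > 0
  i_r <- chrom & mx == r
  i_g <- chrom & !i_r & mx == g
  i_b <- chrom & !i_r & !i_g
  ang[i_r] <- 60 * (((g[i_r] - b[i_r]) / d[i_r]) %% 6)
  ang[i_g] <- 60 * ((b[i_g] - r[i_g]) / d[i_g] + 2)
  ang[i_b] <- 60 * ((r[i_b] - g[i_b]) / d[i_b] + 4)
  sat <- ifelse(mx > 0, d / mx, 0)
  out <- list(
    hue = matrix(as.integer(round(ang / 360 * 255)), dm[1], dm[2]),
    saturation = matrix(as.integer(round(sat * 255)), dm[1], dm[2]),
    intensity = matrix(as.integer(mx), dm[1], dm[2])
  )
  class(out) <- "hsi_view"
  out
}

#' @export
print.hsi_view <- function(x, ...) {
  cat("<hsi_view> ", nrow(x$hue), " x ", ncol(x$hue),
      " (hue/saturation/intensity, 0-255)\n", sep = "")
  invisible(x)
}

# Integer RGB triple whose 0-255 hue equals `hue255` and whose intensity
# (max channel) equals `v` exactly. Only defined for the blue sector the
# generator uses (hue255 in [150, 192]); the interpolated channel is nudged
# by +/- a few units to undo integer-rounding drift of the hue.
fluor_rgb <- function(hue255, v, s = 220L) {
  stopifnot(hue255 >= 150, hue255 <= 192, v >= 0, v <= 255)
  v <- as.integer(v)
  if (v == 0L) return(c(0L, 0L, 0L))
  m <- as.integer(round(v * (1 - s / 255)))
  theta <- hue255 * 360 / 255
  interp <- function(t) as.integer(round(m + abs(t - 240) / 60 * (v - m)))
  mid0 <- interp(theta)
  hue_of <- function(r, g, b) {
    px <- array(c(r, g, b), c(1L, 1L, 3L))
    rgb_to_hsi(px)$hue[1L, 1L]
  }
  best <- NULL
  for (off in c(0L, 1L, -1L, 2L, -2L, 3L, -3L)) {
    mid <- min(max(mid0 + off, m), v)
    rgb <- if (theta >= 240) c(mid, m, v) else c(m, mid, v)
    got <- hue_of(rgb[1], rgb[2], rgb[3])
    if (got == hue255) return(rgb)
    if (is.null(best) || abs(got - hue255) < best$err)
      best <- list(rgb = rgb, err = abs(got - hue255))
  }
  best$rgb
}
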