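#' Regions of interest
#'
#' An ROI is a boolean raster over the image together with its pixel area
#' and a label (`"node"` for the specimen outline, `"background"` for the
#' fixed reference circle placed on clean background). Pixel centers are at
#' integer coordinates `(x = column, y = row)`, 1-based.
#'
#' @param mask logical matrix, `TRUE` inside the region.
#' @param label `"node"` or `"background"`.
#' @return a `fluoro_roi` object with fields `mask`, `area_px`, `label`.
#' @export
roi_from_mask <- function(mask, label = "node") {
  stopifnot(is.logical(mask), is.matrix(mask))
  label <- match.arg(label, c("node", "background"))
  structure(list(mask = mask, area_px = sum(mask), label = label),
            class = "fluoro_roi")
}

#' @export
print.fluoro_roi <- function(x, ...) {
  cat(sprintf("<fluoro_roi %s> %d x %d, area %d px\n",
              x$label, nrow(x$mask), ncol(x$mask), x$area_px))
  invisible(x)
}

#' @rdname roi_from_mask
#' @param dims image dimensions `c(height, width)` in pixels.
#' @param x0,y0,x1,y1 inclusive rectangle corners (columns `x`, rows `y`).
#' @export
roi_rectangle <- function(dims, x0 = 1, y0 = 1, x1 = dims[2], y1 = dims[1],
                          label = "node") {
  if (x0 < 1 || y0 < 1 || x1 > dims[2] || y1 > dims[1] || x0 > x1 || y0 > y1)
    stop_fq("rectangle lies outside the image")
  m <- matrix(FALSE, dims[1], dims[2])
  m[y0:y1, x0:x1] <- TRUE
  roi_from_mask(m, label)
}

# Pixel-center ellipse rasterization; rotation in degrees, counterclockwise.
ellipse_mask <- function(dims, center, axes, rotation = 0) {
  th <- rotation * pi / 180
  x <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE) - center[1]
  y <- matrix(seq_len(dims[1]), dims[1], dims[2]) - center[2]
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' @rdname roi_from_mask
#' @param center ellipse/circle center `c(x, y)` in pixel coordinates.
#' @param axes semi-axes `c(semi_major, semi_minor)` in pixels.
#' @param rotation rotation of the major axis, degrees.
#' @export
roi_ellipse <- function(dims, center, axes, rotation = 0, label = "node") {
  ext <- max(axes)
  if (center[1] - ext < 1 || center[1] + ext > dims[2] ||
      center[2] - ext < 1 || center[2] + ext > dims[1])
    stop_fq("ellipse lies outside the image")
  roi_from_mask(ellipse_mask(dims, center, axes, rotation), label)
}

#' @rdname roi_from_mask
#' @param radius circle radius in pixels.
#' @export
roi_circle <- function(dims, center, radius, label = "background") {
  roi_ellipse(dims, center, c(radius, radius), 0, label)
}

#' @rdname roi_from_mask
#' @param vertices two-column matrix of polygon vertices `(x, y)`.
#' @export
roi_polygon <- function(dims, vertices, label = "node") {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L)
  if (min(vertices[, 1]) < 1 || max(vertices[, 1]) > dims[2] ||
      min(vertices[, 2]) < 1 || max(vertices[, 2]) > dims[1])
    stop_fq("polygon lies outside the image")
  xs <- rep(seq_len(dims[2]), each = dims[1])
  ys <- rep(seq_len(dims[1]), dims[2])
  inside <- pracma::inpolygon(xs, ys, vertices[, 1], vertices[, 2],
                              boundary = TRUE)
  roi_from_mask(matrix(inside, dims[1], dims[2]), label)
}

#' Fixed background reference circle
#'
#' Intensity measurement uses a uniform circle on clean background, the same
#' circle for every image, with a conventional area of 5,806 pixels. Because
#' a rasterized circle can only take areas equal to counts of lattice points,
#' the radius is chosen so the rasterized area is as close as possible to
#' `area_px` (for 5,806 the realized area is within a few pixels; radius is
#' about 43).
#'
#' @param dims image dimensions `c(height, width)`.
#' @param center circle center `c(x, y)`; default places the circle in the
#'   top-left corner region.
#' @param area_px target pixel area; default 5806.
#' @return a `fluoro_roi` labelled `"background"`.
#' @export
background_circle <- function(dims, center = NULL, area_px = 5806L) {
  if (is.null(center)) {
    r_est <- sqrt(area_px / pi)
    center <- c(ceiling(r_est) + 2, ceiling(r_est) + 2)
  }
  x <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE) - center[1]
  y <- matrix(seq_len(dims[1]), dims[1], dims[2]) - center[2]
  d2 <- x^2 + y^2
  ds <- sort(as.vector(d2))
  if (length(ds) < area_px)
    stop_fq("image too small for the requested background area")
  # threshold at the squared distance whose cumulative count is closest to
  # the target; ties in d2 are all-in or all-out
  r2 <- ds[area_px]
  n_in <- sum(ds <= r2)
  if (any(ds < r2)) {
    r2_lo <- ds[max(which(ds < r2))]
    if (abs(sum(ds <= r2_lo) - area_px) < abs(n_in - area_px)) r2 <- r2_lo
  }
  roi_from_mask(d2 <= r2, "background")
}

#' Place the background circle clear of the node
#'
#' Scans candidate centers on a coarse grid and returns the first
#' background circle that fits inside the image without touching the node
#' ROI (with a 2 px margin).
#'
#' @param node_roi the node `fluoro_roi`.
#' @param dims image dimensions `c(height, width)`.
#' @param area_px target circle area; default 5806.
#' @return a background `fluoro_roi`, or an error if no placement exists.
#' @export
place_background_circle <- function(node_roi, dims, area_px = 5806L) {
  r <- ceiling(sqrt(area_px / pi)) + 2
  for (cy in seq(r + 1, dims[1] - r, by = 8)) {
    for (cx in seq(r + 1, dims[2] - r, by = 8)) {
      roi <- background_circle(dims, c(cx, cy), area_px)
      if (!any(roi$mask & node_roi$mask)) return(roi)
    }
  }
  stop_fq("no background-circle placement avoids the node ROI")
}
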