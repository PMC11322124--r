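#' Specify a synthetic specimen scene
#'
#' A scene is an elliptical lymph-node region on a clean white background in
#' which a controlled fraction of node pixels carries blue pseudo-colored
#' fluorescence inside the 165-180 hue band at a controlled intensity, and
#' everything else is tissue-colored or background. The defaults emulate the
#' standardized imaging conditions the measurement pipeline assumes: pure
#' white background, a node that fits well inside the frame, fluorescent
#' intensities centred near 52 AU (the scale of median intensities reported
#' for fluorescent nodes), and zero background signal.
#'
#' @param width,height canvas size in pixels (default 512 x 512).
#' @param center node ellipse center `c(x, y)`; default the image center.
#' @param axes node semi-axes `c(semi_major, semi_minor)` in px.
#' @param rotation major-axis rotation, degrees.
#' @param fraction target fluorescent fraction of node pixels, in `[0, 1]`;
#'   0 declares a negative-control scene.
#' @param fluor_hue hue of fluorescent pixels on 0-255; must lie in the blue
#'   band 165-180 for a positive scene. Default 170 (pure blue).
#' @param fluor_intensity_mean,fluor_intensity_spread fluorescent pixel
#'   intensity is drawn uniformly from
#'   `mean - spread .. mean + spread` (integers, clipped to 0-255).
#' @param fluor_saturation saturation of fluorescent pixels (0-255); kept
#'   high by default so hue is well defined. Saturation is never
#'   thresholded.
#' @param nonfluor_node_color RGB triple for non-fluorescent node tissue;
#'   its hue must fall outside 165-180.
#' @param background_color RGB triple for the background; default pure
#'   white.
#' @param region_mode `"subset"` places fluorescent pixels as a random
#'   pixel subset of the node, which makes the realized fraction exact to
#'   within one pixel; `"blob"` grows a contiguous region around a random
#'   seed pixel for visual plausibility at the same pixel-count accuracy.
#' @param seed integer RNG seed; the whole scene is deterministic given the
#'   spec.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(width = 512L, height = 512L,
                       center = c(width / 2, height / 2),
                       axes = c(150, 100), rotation = 0,
                       fraction = 0.5,
                       fluor_hue = 170L,
                       fluor_intensity_mean = 52L,
                       fluor_intensity_spread = 7L,
                       fluor_saturation = 220L,
                       nonfluor_node_color = c(210L, 180L, 170L),
                       background_color = c(255L, 255L, 255L),
                       region_mode = c("subset", "blob"),
                       seed = 1L) {
  region_mode <- match.arg(region_mode)
  spec <- list(
    width = as.integer(width), height = as.integer(height),
    center = as.numeric(center), axes = as.numeric(axes),
    rotation = as.numeric(rotation), fraction = as.numeric(fraction),
    fluor_hue = as.integer(fluor_hue),
    fluor_intensity_mean = as.integer(fluor_intensity_mean),
    fluor_intensity_spread = as.integer(fluor_intensity_spread),
    fluor_saturation = as.integer(fluor_saturation),
    nonfluor_node_color = as.integer(nonfluor_node_color),
    background_color = as.integer(background_color),
    region_mode = region_mode, seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (width < 1 || height < 1) stop_fq("canvas must be at least 1 x 1")
    if (fraction < 0 || fraction > 1) stop_fq("fraction must lie in [0, 1]")
    ext <- max(axes)
    if (center[1] - ext < 1 || center[1] + ext > width ||
        center[2] - ext < 1 || center[2] + ext > height)
      stop_fq("node ellipse must lie fully inside the image")
    if (fraction > 0 && (fluor_hue < 165 || fluor_hue > 180))
      stop_fq("a positive scene requires fluor_hue inside the blue band ",
              "165-180")
    tissue_hue <- rgb_hue255(nonfluor_node_color)
    if (tissue_hue >= 165 && tissue_hue <= 180)
      stop_fq("nonfluor_node_color falls inside the blue hue band 165-180")
    if (any(c(nonfluor_node_color, background_color) < 0) ||
        any(c(nonfluor_node_color, background_color) > 255))
      stop_fq("colors must be 0-255 RGB triples")
  })
  invisible(spec)
}

rgb_hue255 <- function(rgb) {
  h <- grDevices::rgb2hsv(matrix(as.numeric(rgb), 3), maxColorValue = 255)[1, ]
  as.integer(round(h * 255))
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %dx%d, node axes (%g, %g), fraction %.3f, hue %d, seed %d\n",
    x$width, x$height, x$axes[1], x$axes[2], x$fraction, x$fluor_hue, x$seed))
  invisible(x)
}

#' Generate a pseudo-colored node image with exact ground truth
#'
#' Rasterizes the node ellipse, selects `round(fraction * n_node)` node
#' pixels as fluorescent (so the realized fraction matches the request to
#' within one pixel count), paints them with the requested hue at intensity
#' drawn uniformly within `mean +/- spread`, paints the remaining node
#' pixels tissue-colored and every background pixel exactly
#' `background_color`, and returns the image together with the true node
#' and fluorescence masks. Deterministic given the spec (including its
#' seed).
#'
#' @param spec a [scene_spec()].
#' @return a `synthetic_scene` list with elements
#'   \describe{
#'     \item{image}{`H x W x 3` pseudo-color array;}
#'     \item{truth}{list `node_mask`, `fluor_mask`, `realized_fraction`,
#'       `realized_mean_intensity`;}
#'     \item{spec}{the generating spec.}
#'   }
#' @examples
#' syn <- generate_node_image(scene_spec(fraction = 0.5, seed = 7))
#' syn$truth$realized_fraction
#' @export
generate_node_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  h <- spec$height; w <- spec$width
  node <- ellipse_mask(c(h, w), spec$center, spec$axes, spec$rotation)
  n_node <- sum(node)
  if (n_node < 1L) stop_fq("node rasterizes to zero pixels")
  k <- as.integer(round(spec$fraction * n_node))

  img <- array(0L, c(h, w, 3L))
  for (c in 1:3) {
    plane <- matrix(spec$background_color[c], h, w)
    plane[node] <- spec$nonfluor_node_color[c]
    img[, , c] <- plane
  }

  fluor <- matrix(FALSE, h, w)
  mean_v <- 0
  if (k > 0L) {
    node_idx <- which(node)
    sel <- with_seed(spec$seed, {
      idx <- if (spec$region_mode == "subset") {
        sample(node_idx, k)
      } else {
        seed_px <- sample(node_idx, 1L)
        sy <- (seed_px - 1L) %% h + 1L
        sx <- (seed_px - 1L) %/% h + 1L
        py <- (node_idx - 1L) %% h + 1L
        px <- (node_idx - 1L) %/% h + 1L
        d2 <- (px - sx)^2 + (py - sy)^2
        node_idx[order(d2, node_idx)][seq_len(k)]
      }
      v <- spec$fluor_intensity_mean +
        sample.int(2L * spec$fluor_intensity_spread + 1L, k,
                   replace = TRUE) - spec$fluor_intensity_spread - 1L
      list(idx = idx, v = pmax(pmin(v, 255L), 0L))
    })
    fluor[sel$idx] <- TRUE
    mean_v <- mean(sel$v)
    colors <- vapply(sort(unique(sel$v)), fluor_rgb,
                     integer(3), hue255 = spec$fluor_hue,
                     s = spec$fluor_saturation)
    colnames(colors) <- sort(unique(sel$v))
    rgb_px <- colors[, as.character(sel$v), drop = FALSE]
    plane_sz <- h * w
    img[sel$idx] <- rgb_px[1, ]
    img[sel$idx + plane_sz] <- rgb_px[2, ]
    img[sel$idx + 2L * plane_sz] <- rgb_px[3, ]
  }

  structure(list(
    image = as_pseudocolor(img),
    truth = list(
      node_mask = node, fluor_mask = fluor,
      realized_fraction = k / n_node,
      realized_mean_intensity = mean_v
    ),
    spec = spec
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %dx%d, node %d px, fluorescent fraction %.4f\n",
    nrow(x$truth$node_mask), ncol(x$truth$node_mask),
    sum(x$truth$node_mask), x$truth$realized_fraction))
  invisible(x)
}

#' Generate a negative-control scene
#'
#' A negative control is a node never exposed to the fluorophore: the
#' fluorescent fraction is zero and no pixel anywhere in the image has a hue
#' inside the blue band, so every downstream measurement must return 0%
#' surface fluorescence and 0 AU mean intensity.
#'
#' @param size canvas side length in pixels (square canvas).
#' @param seed RNG seed (kept for interface symmetry; a negative control is
#'   fully deterministic).
#' @return a `synthetic_scene`; see [generate_node_image()].
#' @export
generate_negative_control <- function(size = 512L, seed = 1L) {
  generate_node_image(scene_spec(
    width = size, height = size,
    axes = c(size * 0.29, size * 0.2),
    fraction = 0, seed = seed
  ))
}

#' Perturb a synthetic scene
#'
#' Emulates the degradations described for real specimen photographs:
#' \describe{
#'   \item{`dull_fluorescence`}{pulls fluorescent-pixel intensities toward a
#'     dull dark-blue level (`target`, default 32 AU, just above the
#'     lenient 30 AU intensity floor but below the strict 45 AU one);
#'     `magnitude` in `[0, 1]` blends linearly, 1 sets all to `target`.}
#'   \item{`fat_occlusion`}{overwrites a contiguous portion of the
#'     fluorescent region (a fraction `magnitude` of its pixels) with
#'     non-fluorescent tissue color, as fat covering the signal; the ground
#'     truth masks are updated accordingly.}
#'   \item{`ambient_light`}{adds a faint warm tint to the background, whose
#'     hue stays far outside the blue band.}
#' }
#'
#' @param scene a `synthetic_scene` from [generate_node_image()].
#' @param mode one of `"dull_fluorescence"`, `"fat_occlusion"`,
#'   `"ambient_light"`.
#' @param magnitude perturbation strength in `[0, 1]`; 0 returns the scene
#'   unchanged.
#' @param seed RNG seed for the perturbation's own randomness.
#' @param target dull-intensity target in AU (only for
#'   `dull_fluorescence`).
#' @return a modified `synthetic_scene` with consistent ground truth.
#' @export
perturb_scene <- function(scene, mode, magnitude, seed = 1L, target = 32L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  mode <- match.arg(mode,
    c("dull_fluorescence", "fat_occlusion", "ambient_light"))
  if (magnitude < 0 || magnitude > 1) stop_fq("magnitude must lie in [0, 1]")
  if (magnitude == 0) return(scene)
  spec <- scene$spec
  img <- scene$image
  truth <- scene$truth
  plane_sz <- spec$height * spec$width

  if (mode == "dull_fluorescence") {
    idx <- which(truth$fluor_mask)
    if (length(idx)) {
      v_old <- pmax(pmax(img[idx], img[idx + plane_sz]),
                    img[idx + 2L * plane_sz])
      v_new <- as.integer(round(v_old + magnitude * (target - v_old)))
      for (v in unique(v_new)) {
        rgb <- fluor_rgb(spec$fluor_hue, v, spec$fluor_saturation)
        at <- idx[v_new == v]
        img[at] <- rgb[1]; img[at + plane_sz] <- rgb[2]
        img[at + 2L * plane_sz] <- rgb[3]
      }
      truth$realized_mean_intensity <- mean(v_new)
    }
  } else if (mode == "fat_occlusion") {
    idx <- which(truth$fluor_mask)
    n_cover <- as.integer(round(magnitude * length(idx)))
    if (n_cover > 0L) {
      cover <- with_seed(seed, {
        seed_px <- sample(idx, 1L)
        h <- spec$height
        sy <- (seed_px - 1L) %% h + 1L
        sx <- (seed_px - 1L) %/% h + 1L
        py <- (idx - 1L) %% h + 1L
        px <- (idx - 1L) %/% h + 1L
        d2 <- (px - sx)^2 + (py - sy)^2
        idx[order(d2, idx)][seq_len(n_cover)]
      })
      img[cover] <- spec$nonfluor_node_color[1]
      img[cover + plane_sz] <- spec$nonfluor_node_color[2]
      img[cover + 2L * plane_sz] <- spec$nonfluor_node_color[3]
      truth$fluor_mask[cover] <- FALSE
      truth$realized_fraction <- sum(truth$fluor_mask) / sum(truth$node_mask)
      rem <- which(truth$fluor_mask)
      truth$realized_mean_intensity <- if (length(rem)) {
        mean(pmax(pmax(img[rem], img[rem + plane_sz]),
                  img[rem + 2L * plane_sz]))
      } else 0
    }
  } else { # ambient_light
    bg <- which(!truth$node_mask)
    img[bg + plane_sz] <- pmax(img[bg + plane_sz] -
                                 as.integer(round(magnitude * 10)), 0L)
    img[bg + 2L * plane_sz] <- pmax(img[bg + 2L * plane_sz] -
                                      as.integer(round(magnitude * 25)), 0L)
  }

  structure(list(image = as_pseudocolor(img), truth = truth, spec = spec),
            class = "synthetic_scene")
}

#' Write a synthetic scene to disk
#'
#' Writes the image as 24-bit PNG, the node and fluorescence masks as 0/255
#' PNGs, and the ground truth (spec fields plus realized values) as a JSON
#' sidecar.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem, e.g. `"scene_03"`.
#' @return named character vector of the paths written, invisibly.
#' @export
write_scene <- function(scene, dir, stem) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(stem, ".png")),
    node_mask = file.path(dir, paste0(stem, "_node_mask.png")),
    fluor_mask = file.path(dir, paste0(stem, "_fluor_mask.png")),
    truth = file.path(dir, paste0(stem, "_truth.json"))
  )
  write_image(scene$image, paths[["image"]])
  write_mask(scene$truth$node_mask, paths[["node_mask"]])
  write_mask(scene$truth$fluor_mask, paths[["fluor_mask"]])
  sidecar <- c(
    scene$spec[setdiff(names(scene$spec), c("center", "axes"))],
    list(center = scene$spec$center, axes = scene$spec$axes,
         realized_fraction = scene$truth$realized_fraction,
         realized_mean_intensity = scene$truth$realized_mean_intensity,
         node_area_px = sum(scene$truth$node_mask),
         fluor_area_px = sum(scene$truth$fluor_mask))
  )
  jsonlite::write_json(sidecar, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
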