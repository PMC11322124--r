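#' Color thresholds on the 0-255 hue/intensity scales
#'
#' A color threshold is an inclusive hue-band x intensity-band gate: a pixel
#' passes iff `hue_min <= hue <= hue_max` and
#' `intensity_min <= intensity <= intensity_max`. Saturation never gates.
#'
#' Five thresholds are built in, all sharing the blue pseudo-color hue band
#' 165-180 and differing in the intensity floor:
#' \describe{
#'   \item{A}{intensity 30-255, used for surface-fluorescence area.}
#'   \item{B}{intensity 45-255, the stricter area threshold that drops dull
#'     (dark-blue) fluorescence.}
#'   \item{T1}{intensity 30-255, used for intensity measurement.}
#'   \item{T2}{intensity 35-255.}
#'   \item{T3}{intensity 45-255.}
#' }
#'
#' @param name identifier for the threshold.
#' @param hue_min,hue_max inclusive hue bounds, integers in 0-255.
#' @param intensity_min,intensity_max inclusive intensity bounds, 0-255.
#' @return a `color_threshold` object.
#' @examples
#' color_threshold("A", 165, 180, 30, 255)
#' builtin_threshold("T2")
#' @export
color_threshold <- function(name, hue_min, hue_max, intensity_min,
                            intensity_max) {
  vals <- c(hue_min, hue_max, intensity_min, intensity_max)
  if (any(vals < 0 | vals > 255)) stop_fq("threshold bounds must be in [0, 255]")
  if (hue_min > hue_max) stop_fq("hue_min must not exceed hue_max")
  if (intensity_min > intensity_max)
    stop_fq("intensity_min must not exceed intensity_max")
  structure(
    list(name = as.character(name),
         hue_min = as.integer(hue_min), hue_max = as.integer(hue_max),
         intensity_min = as.integer(intensity_min),
         intensity_max = as.integer(intensity_max)),
    class = "color_threshold"
  )
}

#' @rdname color_threshold
#' @export
builtin_thresholds <- function() {
  list(
    A  = color_threshold("A",  165, 180, 30, 255),
    B  = color_threshold("B",  165, 180, 45, 255),
    T1 = color_threshold("T1", 165, 180, 30, 255),
    T2 = color_threshold("T2", 165, 180, 35, 255),
    T3 = color_threshold("T3", 165, 180, 45, 255)
  )
}

#' @rdname color_threshold
#' @export
builtin_threshold <- function(name) {
  tl <- builtin_thresholds()
  if (!name %in% names(tl))
    stop_fq("unknown built-in threshold '", name, "'; available: ",
            paste(names(tl), collapse = ", "))
  tl[[name]]
}

# Accept a color_threshold or the name of a built-in.
resolve_threshold <- function(t) {
  if (inherits(t, "color_threshold")) return(t)
  if (is.character(t) && length(t) == 1L) return(builtin_threshold(t))
  stop_fq("expected a color_threshold or a built-in threshold name")
}

#' @export
print.color_threshold <- function(x, ...) {
  cat(sprintf("<color_threshold %s> hue %d-%d, intensity %d-%d\n",
              x$name, x$hue_min, x$hue_max, x$intensity_min, x$intensity_max))
  invisible(x)
}
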