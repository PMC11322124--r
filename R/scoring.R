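#' Semi-quantitative surface-fluorescence score
#'
#' The ordinal scale used for visual assessment of specimen fluorescence:
#' 0 = no fluorescence, 1+ = 1-25% of the node surface fluorescent,
#' 2+ = 26-50%, 3+ = 51-75%, 4+ = 76-100%. For continuous measured
#' percentages the integer bands are read as half-open intervals with
#' inclusive upper bounds - `(0, 25]`, `(25, 50]`, `(50, 75]`, `(75, 100]` -
#' so e.g. 25.4% scores 2+ and exactly 25% scores 1+. Score 0 requires
#' exactly 0%: any detected signal is at least 1+.
#'
#' @param pct surface-fluorescence percentage(s) in `[0, 100]`.
#' @param boundaries upper band boundaries for scores 1+, 2+, 3+ (the 4+
#'   band always ends at 100); override to change the binning convention.
#' @return integer score(s) in 0-4.
#' @examples
#' assign_score(c(0, 12, 25, 25.4, 50, 76, 100))  # 0 1 1 2 2 4 4
#' @export
assign_score <- function(pct, boundaries = c(25, 50, 75)) {
  if (anyNA(pct) || any(pct < 0 | pct > 100))
    stop_fq("percentages must lie in [0, 100]")
  stopifnot(length(boundaries) == 3L, !is.unsorted(boundaries))
  ifelse(pct == 0, 0L,
         1L + findInterval(pct, boundaries, left.open = TRUE))
}

#' @rdname assign_score
#' @param score integer score(s) in 0-4.
#' @return `score_label()` returns the display form `"0"`, `"1+"`, ...,
#'   `"4+"`.
#' @export
score_label <- function(score) {
  stopifnot(all(score %in% 0:4))
  ifelse(score == 0L, "0", paste0(score, "+"))
}

#' Dichotomous fluorescence status
#'
#' Scores are collapsed to a positive (1) / negative (0) fluorescence
#' status: score 0 is negative, any score 1+ to 4+ is positive.
#'
#' @param score integer score(s) in 0-4.
#' @return integer status, 0 (negative) or 1 (positive).
#' @export
dichotomize <- function(score) {
  stopifnot(all(score %in% 0:4))
  as.integer(score > 0L)
}

#' Score a quantification result
#'
#' Applies [assign_score()] and [dichotomize()] to the surface-fluorescence
#' percentage measured under one threshold (by default Threshold A, the
#' threshold validated for surface-area measurement).
#'
#' @param quant a data frame from [quantify_image()].
#' @param threshold which threshold's row to score; default `"A"`.
#' @return a list with `score`, `label`, `status`, and the `pct` used.
#' @export
score_image <- function(quant, threshold = "A") {
  row <- quant[quant$threshold == threshold, , drop = FALSE]
  if (nrow(row) != 1L)
    stop_fq("quant must contain exactly one row for threshold '",
            threshold, "'")
  s <- assign_score(row$surface_fluorescence_pct)
  list(score = s, label = score_label(s), status = dichotomize(s),
       pct = row$surface_fluorescence_pct)
}
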