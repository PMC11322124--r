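#' Wilcoxon-Mann-Whitney rank-sum comparison
#'
#' Compares two sets of measurements (e.g. surface-fluorescence percentages
#' obtained under two color thresholds) without a normality assumption.
#' Wraps [stats::wilcox.test()]: the reported statistic is the Mann-Whitney
#' U for the first sample, with tie-corrected two-sided p (exact for small
#' tie-free samples, normal approximation otherwise).
#'
#' @param x,y numeric samples; both nonempty.
#' @return list with `statistic` (U), `p_value`, and the underlying
#'   `htest`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop_fq("both samples must be nonempty")
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, htest = ht)
}

#' Friedman test across paired threshold measurements
#'
#' Compares k matched measurement columns (e.g. average intensities of the
#' same specimens under intensity thresholds 1-3) by within-specimen ranks,
#' via [stats::friedman.test()]. Pairwise post-hoc comparisons are Wilcoxon
#' signed-rank tests; for each pair the centered signed-rank statistic
#' `S = V - n'(n'+1)/4` (positive-rank sum minus its null mean, over the
#' `n'` non-tied pairs) and an approximate Z are reported alongside the
#' p-value.
#'
#' @param values a numeric matrix or data frame, one row per specimen and
#'   one column per threshold (at least 2 columns, 2 rows).
#' @return list with `statistic` (Friedman chi-square), `df`, `p_value`,
#'   and a `pairwise` data frame (`pair`, `S`, `Z`, `V`, `p_value`).
#' @export
friedman_fi <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop_fq("need at least 2 specimens and 2 measurement columns")
  ht <- stats::friedman.test(values)
  # every row fully tied (e.g. identical columns): the rank statistic
  # carries no information; report 0 with p = 1 rather than NaN
  if (is.nan(ht$statistic)) {
    ht$statistic[] <- 0
    ht$p.value <- 1
  }
  cols <- colnames(values)
  if (is.null(cols)) cols <- paste0("col", seq_len(ncol(values)))
  pairs <- utils::combn(ncol(values), 2)
  pw <- apply(pairs, 2, function(ij) {
    d <- values[, ij[1]] - values[, ij[2]]
    d <- d[d != 0]
    wt <- suppressWarnings(
      stats::wilcox.test(values[, ij[1]], values[, ij[2]], paired = TRUE))
    v <- unname(wt$statistic)
    n <- length(d)
    s <- v - n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    data.frame(
      pair = paste(cols[ij[1]], "vs", cols[ij[2]]),
      S = s, Z = if (sigma > 0) s / sigma else NA_real_, V = v,
      p_value = wt$p.value, stringsAsFactors = FALSE
    )
  })
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, pairwise = do.call(rbind, pw))
}

#' Logistic regression and empirical ROC for intensity as a predictor of
#' fluorescence status
#'
#' Fits `status ~ fi` by maximum-likelihood logistic regression, reporting
#' the slope with its Wald chi-square and p-value and the odds ratio
#' `exp(slope)` with a Wald 95% CI, then sweeps the empirical ROC: for
#' every cut-point `c` (midpoints between consecutive distinct intensity
#' values, plus sentinels below and above the data) a specimen is predicted
#' positive iff `fi >= c`. AUC is the trapezoidal area under the
#' (1-specificity, sensitivity) curve. The optimal cut-point maximizes
#' Youden's J = sensitivity + specificity - 1; ties are broken toward the
#' higher specificity (larger cut-point), reflecting that a more specific
#' intensity test is the more clinically useful one.
#'
#' Under complete separation the maximum-likelihood slope diverges; the fit
#' is then flagged `converged = FALSE` and its Wald quantities set to `NA`,
#' while the empirical ROC and cut-point are still reported.
#'
#' @param fi average fluorescence intensities (AU).
#' @param status binary fluorescence status (0 negative, 1 positive); both
#'   classes must be present.
#' @return a `roc_result` list: `auc`, `cutpoint_au`, `sensitivity_pct`,
#'   `specificity_pct`, `slope`, `slope_se`, `wald_chi2`, `p_value`,
#'   `odds_ratio`, `or_ci95`, `converged`, and the swept `roc` data frame
#'   (`cutpoint`, `sensitivity`, `specificity`).
#' @export
fi_logistic_roc <- function(fi, status) {
  status <- as.integer(status)
  if (length(fi) != length(status)) stop_fq("fi and status must be paired")
  if (!all(status %in% c(0L, 1L))) stop_fq("status must be binary 0/1")
  if (length(unique(status)) < 2L) stop_fq("both classes must be present")
  if (any(!is.finite(fi))) stop_fq("fi must be finite")

  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(status ~ fi, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  slope <- unname(coef(fit)[2])
  se <- sqrt(diag(stats::vcov(fit)))[2]
  # treat a boundary fit (fitted probabilities pinned at 0/1) as separated
  eps <- 1e-8
  separated <- warned &&
    all(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  converged <- fit$converged && !separated
  if (converged) {
    wald <- (slope / se)^2
    p_value <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
    or <- exp(slope)
    or_ci <- exp(slope + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    wald <- p_value <- or <- NA_real_
    or_ci <- c(NA_real_, NA_real_)
  }

  # empirical ROC sweep: predict positive iff fi >= cutpoint
  u <- sort(unique(fi))
  cuts <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  n_pos <- sum(status == 1L); n_neg <- sum(status == 0L)
  sens <- vapply(cuts, function(ct) sum(fi >= ct & status == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(cuts, function(ct) sum(fi < ct & status == 0L) / n_neg,
                 numeric(1))
  ord <- order(1 - spec, sens)
  fpr <- c(0, (1 - spec)[ord], 1)
  tpr <- c(0, sens[ord], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(cuts[best])]  # ties -> higher specificity

  structure(list(
    auc = auc, cutpoint_au = cuts[best],
    sensitivity_pct = 100 * sens[best], specificity_pct = 100 * spec[best],
    slope = slope, slope_se = unname(se), wald_chi2 = unname(wald),
    p_value = p_value, odds_ratio = or, or_ci95 = or_ci,
    converged = converged,
    roc = data.frame(cutpoint = cuts, sensitivity = sens, specificity = spec)
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.4f, cut-point %.2f AU (sens %.1f%%, spec %.1f%%)\n",
    x$auc, x$cutpoint_au, x$sensitivity_pct, x$specificity_pct))
  if (isTRUE(x$converged)) {
    cat(sprintf(
      "logistic slope %.4f (Wald chi2 %.3f, p = %.3g), OR %.3f (%.3f-%.3f)\n",
      x$slope, x$wald_chi2, x$p_value, x$odds_ratio, x$or_ci95[1],
      x$or_ci95[2]))
  } else {
    cat("logistic fit did not converge (complete separation);",
        "Wald estimates unavailable\n")
  }
  invisible(x)
}

#' Spearman rank association between intensity and surface fluorescence
#'
#' Spearman's rho with tie correction via [stats::cor.test()], plus
#' `rho^2` as a monotone-association strength summary. Constant input makes
#' the rank correlation undefined; `rho` is then `NA` with a warning.
#'
#' @param fi,pct paired measurements; length >= 3.
#' @return list with `rho`, `r_squared`, `p_value`.
#' @export
spearman_assoc <- function(fi, pct) {
  if (length(fi) != length(pct) || length(fi) < 3L)
    stop_fq("need paired samples of length >= 3")
  if (stats::sd(fi) == 0 || stats::sd(pct) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, r_squared = NA_real_, p_value = NA_real_))
  }
  ht <- suppressWarnings(
    stats::cor.test(fi, pct, method = "spearman", exact = FALSE))
  rho <- unname(ht$estimate)
  list(rho = rho, r_squared = rho^2, p_value = ht$p.value)
}

#' Randomized grouping of specimens
#'
#' Deterministically shuffles `n_items` and partitions the shuffled order
#' into consecutive groups of `group_size`; the last group holds the
#' remainder when the total is not a multiple (83 items in groups of 21
#' gives sizes 21, 21, 21, 20).
#'
#' @param n_items number of items.
#' @param group_size target group size.
#' @param seed RNG seed.
#' @return integer vector of length `n_items`: the group index of each
#'   item.
#' @export
randomize_groups <- function(n_items, group_size, seed = 1L) {
  stopifnot(n_items >= 1L, group_size >= 1L)
  perm <- with_seed(seed, sample.int(n_items))
  groups <- integer(n_items)
  groups[perm] <- (seq_len(n_items) - 1L) %/% group_size + 1L
  groups
}
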