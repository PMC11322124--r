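#' Percentage agreement between two raters
#'
#' @param rating_a,rating_b paired ratings of the same specimens (any
#'   comparable type); equal length, no missing values.
#' @return exact-match agreement as a percentage in `[0, 100]`.
#' @export
percent_agreement <- function(rating_a, rating_b) {
  if (length(rating_a) == 0L) stop_fq("empty rating table")
  if (length(rating_a) != length(rating_b))
    stop_fq("ratings must be paired (equal length)")
  if (anyNA(rating_a) || anyNA(rating_b)) stop_fq("missing ratings")
  100 * mean(rating_a == rating_b)
}

#' Qualitative band for a kappa coefficient
#'
#' Conventional interpretation bands: below 0.21 poor/slight, 0.21-0.40
#' fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1 almost perfect.
#'
#' @param kappa kappa value(s) in `[-1, 1]`.
#' @return character band label(s).
#' @export
interpret_kappa <- function(kappa) {
  cut(kappa,
      breaks = c(-1, 0.21, 0.41, 0.61, 0.81, 1),
      labels = c("poor/slight", "fair", "moderate", "substantial",
                 "almost perfect"),
      right = FALSE, include.lowest = TRUE) |> as.character() |>
    (\(x) ifelse(kappa == 1, "almost perfect", x))()
}

# Agreement-weight matrix for k ordered categories. Identity weights give
# simple kappa; linear (Cicchetti-Allison) and quadratic (Fleiss-Cohen)
# weights down-weight near-diagonal disagreement less than distant
# disagreement.
kappa_weights <- function(k, scheme = c("identity", "linear", "quadratic")) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(scheme,
    identity = (d == 0) * 1,
    linear = 1 - d / (k - 1),
    quadratic = 1 - (d / (k - 1))^2
  )
}

#' Cohen's simple and weighted kappa
#'
#' Chance-corrected agreement between two raters of the same specimens on a
#' shared ordinal (or nominal) category set. With observed cell proportions
#' `p[i,j]`, margins `r[i]`, `c[j]` and agreement weights `w[i,j]`,
#' \deqn{p_o = \sum w_{ij} p_{ij}, \quad p_e = \sum w_{ij} r_i c_j, \quad
#'   \kappa = (p_o - p_e) / (1 - p_e).}
#' Simple kappa uses identity weights; weighted kappa defaults to linear
#' (Cicchetti-Allison) weights with quadratic (Fleiss-Cohen) selectable.
#' The 95% confidence interval uses the large-sample
#' (Fleiss-Cohen-Everitt) standard error; the two-sided p-value tests
#' `H0: kappa = 0` with the null-hypothesis standard error.
#'
#' @param rating_a,rating_b paired ratings; factors, integers or characters
#'   on a common category set.
#' @param weighted `FALSE` for simple kappa (default), `TRUE` for weighted.
#' @param scheme weight scheme for weighted kappa: `"linear"` (default) or
#'   `"quadratic"`.
#' @param levels optional explicit category levels (in order); by default
#'   the sorted union of observed categories.
#' @param conf_level confidence level for the interval; default 0.95.
#' @return an `agreement_result` list: `kappa`, `kappa_kind`,
#'   `weight_scheme`, `se`, `ci95`, `z`, `p_value`, `band`,
#'   `percent_agreement`, `n`, `table`.
#' @examples
#' a <- c(0, 1, 2, 3, 4, 4, 2, 1)
#' cohens_kappa(a, a, weighted = TRUE)$kappa  # 1
#' @export
cohens_kappa <- function(rating_a, rating_b, weighted = FALSE,
                         scheme = c("linear", "quadratic"), levels = NULL,
                         conf_level = 0.95) {
  scheme <- match.arg(scheme)
  if (length(rating_a) != length(rating_b) || length(rating_a) == 0L)
    stop_fq("ratings must be paired and nonempty")
  if (anyNA(rating_a) || anyNA(rating_b)) stop_fq("missing ratings")
  lev <- if (is.null(levels)) sort(unique(c(rating_a, rating_b))) else levels
  if (length(lev) < 2L)
    stop_fq("kappa is undefined: both raters use a single category")
  fa <- factor(rating_a, levels = lev)
  fb <- factor(rating_b, levels = lev)
  n <- length(fa)
  tab <- table(fa, fb)
  p <- tab / n
  r <- rowSums(p); cc <- colSums(p)
  k <- length(lev)
  w <- kappa_weights(k, if (weighted) scheme else "identity")

  po <- sum(w * p)
  pe <- sum(w * outer(r, cc))
  if (1 - pe < .Machine$double.eps)
    stop_fq("kappa is undefined: expected agreement is 1 ",
            "(both raters effectively constant)")
  kap <- (po - pe) / (1 - pe)

  # large-sample variance (Fleiss, Cohen & Everitt): w_i. / w_.j are the
  # weighted margin means
  wi <- as.vector(w %*% cc)   # row i: sum_j c_j w_ij
  wj <- as.vector(r %*% w)    # col j: sum_i r_i w_ij
  wsum <- outer(wi, wj, "+")
  var_hat <- (sum(p * (w - wsum * (1 - kap))^2) -
                (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  var_null <- (sum(outer(r, cc) * (w - wsum)^2) - pe^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_hat, 0))
  se0 <- sqrt(max(var_null, 0))
  z <- if (se0 > 0) kap / se0 else NA_real_
  p_value <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  alpha <- 1 - conf_level
  half <- stats::qnorm(1 - alpha / 2) * se
  ci <- c(max(kap - half, -1), min(kap + half, 1))

  structure(list(
    kappa = kap, kappa_kind = if (weighted) "weighted" else "simple",
    weight_scheme = if (weighted) scheme else "identity",
    se = se, ci95 = ci, z = z, p_value = p_value,
    band = interpret_kappa(kap),
    percent_agreement = percent_agreement(rating_a, rating_b),
    n = n, table = tab
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's %s kappa%s: %.4f (95%% CI %.4f-%.4f), p = %.3g [%s]\n",
    x$kappa_kind,
    if (x$kappa_kind == "weighted") paste0(" (", x$weight_scheme, ")") else "",
    x$kappa, x$ci95[1], x$ci95[2], x$p_value, x$band))
  cat(sprintf("percent agreement %.1f%% on n = %d pairs\n",
              x$percent_agreement, x$n))
  invisible(x)
}
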