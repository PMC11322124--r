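# Independent brute-force reference implementations used as oracles.
# These are deliberately written as plain per-pixel / per-cell loops from
# the textbook definitions, sharing no code with the package internals.

oracle_hsi <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  hue <- sat <- int <- matrix(0L, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    r <- image[y, x, 1]; g <- image[y, x, 2]; b <- image[y, x, 3]
    mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
    ang <- if (d == 0) 0 else if (mx == r) 60 * (((g - b) / d) %% 6)
      else if (mx == g) 60 * ((b - r) / d + 2)
      else 60 * ((r - g) / d + 4)
    hue[y, x] <- as.integer(round(ang / 360 * 255))
    sat[y, x] <- if (mx == 0) 0L else as.integer(round((d / mx) * 255))
    int[y, x] <- as.integer(mx)
  }
  list(hue = hue, saturation = sat, intensity = int)
}

oracle_median_filter <- function(image, radius) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- image
  for (c in 1:3) for (y in seq_len(h)) for (x in seq_len(w)) {
    vals <- c()
    for (dy in -radius:radius) for (dx in -radius:radius) {
      yy <- min(max(y + dy, 1), h)
      xx <- min(max(x + dx, 1), w)
      vals <- c(vals, image[yy, xx, c])
    }
    out[y, x, c] <- sort(vals)[(length(vals) + 1) %/% 2]
  }
  out
}

oracle_threshold <- function(hsi, roi_mask, hue_min, hue_max, int_min,
                             int_max) {
  h <- nrow(roi_mask); w <- ncol(roi_mask)
  out <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    out[y, x] <- roi_mask[y, x] &&
      hsi$hue[y, x] >= hue_min && hsi$hue[y, x] <= hue_max &&
      hsi$intensity[y, x] >= int_min && hsi$intensity[y, x] <= int_max
  }
  out
}

oracle_mean_over_mask <- function(plane, mask) {
  total <- 0; n <- 0
  for (i in seq_along(plane)) if (mask[i]) {
    total <- total + plane[i]; n <- n + 1
  }
  if (n == 0) 0 else total / n
}

# Cohen's kappa from the contingency-table definition, explicit loops.
oracle_kappa <- function(a, b, weights) {
  lev <- sort(unique(c(a, b)))
  k <- length(lev)
  tab <- matrix(0, k, k)
  for (i in seq_along(a)) {
    ia <- match(a[i], lev); ib <- match(b[i], lev)
    tab[ia, ib] <- tab[ia, ib] + 1
  }
  p <- tab / length(a)
  po <- 0; pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    po <- po + weights[i, j] * p[i, j]
    pe <- pe + weights[i, j] * sum(p[i, ]) * sum(p[, j])
  }
  (po - pe) / (1 - pe)
}

oracle_linear_weights <- function(k) {
  w <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) w[i, j] <- 1 - abs(i - j) / (k - 1)
  w
}

oracle_quadratic_weights <- function(k) {
  w <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) w[i, j] <- 1 - (abs(i - j) / (k - 1))^2
  w
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    u <- 0
    for (xi in xs) for (yi in ys) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, u_of)
  mu <- n * m / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p = p)
}

# Friedman chi-square from within-row midranks (no tie correction, the
# classical statistic).
oracle_friedman <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  rk <- t(apply(mat, 1, rank))
  colsum <- colSums(rk)
  12 / (n * k * (k + 1)) * sum(colsum^2) - 3 * n * (k + 1)
}

# Empirical ROC by counting TP/FP/TN/FN at each cut (positive iff fi >= c).
oracle_roc_point <- function(fi, status, cut) {
  tp <- sum(fi >= cut & status == 1)
  fn <- sum(fi < cut & status == 1)
  tn <- sum(fi < cut & status == 0)
  fp <- sum(fi >= cut & status == 0)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

# Small synthetic scene used across tests (fast: 128 px canvas).
tiny_scene <- function(fraction, seed = 1L, ...) {
  generate_node_image(scene_spec(
    width = 128L, height = 128L, axes = c(40, 28),
    fraction = fraction, seed = seed, ...
  ))
}
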