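random_image <- function(h, w, seed) {
  set.seed(seed)
  as_pseudocolor(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

test_that("HSI conversion follows the 0-255 hue convention", {
  px <- array(0L, c(1, 1, 3))
  px[1, 1, 3] <- 255L                      # pure blue
  v <- rgb_to_hsi(px)
  expect_identical(v$hue[1, 1], 170L)      # 240 deg * 255/360
  expect_identical(v$saturation[1, 1], 255L)
  expect_identical(v$intensity[1, 1], 255L)

  white <- array(255L, c(1, 1, 3))
  vw <- rgb_to_hsi(white)
  expect_identical(vw$hue[1, 1], 0L)       # achromatic convention
  expect_identical(vw$saturation[1, 1], 0L)
  expect_identical(vw$intensity[1, 1], 255L)
})

test_that("HSI conversion matches a per-pixel formula oracle", {
  for (seed in 1:3) {
    img <- random_image(12, 9, seed)
    got <- rgb_to_hsi(img)
    ref <- oracle_hsi(img)
    expect_identical(got$hue, ref$hue)
    expect_identical(got$intensity, ref$intensity)
    expect_identical(got$saturation, ref$saturation)
  }
})

test_that("HSI conversion agrees with grDevices::rgb2hsv as a reference", {
  img <- random_image(15, 15, 31)
  got <- rgb_to_hsi(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  ref <- grDevices::rgb2hsv(m, maxColorValue = 255)
  # identical up to integer rounding of the 0-255 rescale (ties may round
  # the other way in the reference's pre-scaled arithmetic)
  expect_true(all(abs(got$hue - round(ref[1, ] * 255)) <= 1))
  expect_true(all(abs(got$saturation - round(ref[2, ] * 255)) <= 1))
  expect_identical(as.vector(got$intensity), as.integer(round(ref[3, ] * 255)))
})

test_that("median filter is exact against a brute-force neighborhood oracle", {
  for (seed in 1:3) {
    img <- random_image(10, 10, seed + 20)
    for (r in 1:2) {
      expect_identical(median_filter(img, r), oracle_median_filter(img, r))
    }
  }
})

test_that("median filter leaves constants alone, removes salt noise, and r=0 is identity", {
  const <- as_pseudocolor(array(77L, c(8, 8, 3)))
  expect_identical(median_filter(const, 1), const)

  field <- as_pseudocolor(array(200L, c(9, 9, 3)))
  noisy <- field
  noisy[5, 5, ] <- c(0L, 0L, 0L)
  expect_identical(median_filter(noisy, 1), field)

  img <- random_image(6, 6, 99)
  expect_identical(median_filter(img, 0), img)
  expect_error(median_filter(img, -1), "radius")
})

test_that("ROIs rasterize with the expected areas", {
  full <- roi_rectangle(c(20, 30))
  expect_identical(full$area_px, 600L)

  bg <- background_circle(c(512, 512))
  expect_lte(abs(bg$area_px - 5806) / 5806, 0.01)

  syn <- tiny_scene(0.5)
  node <- roi_from_mask(syn$truth$node_mask)
  expect_identical(node$area_px, sum(syn$truth$node_mask))

  # a polygon traced around the full canvas covers it
  poly <- roi_polygon(c(10, 10), cbind(c(1, 10, 10, 1), c(1, 1, 10, 10)))
  expect_identical(poly$area_px, 100L)

  expect_error(roi_ellipse(c(50, 50), c(25, 25), c(30, 10)), "outside")
  expect_error(roi_rectangle(c(10, 10), x1 = 11), "outside")
})

test_that("background circle placement avoids the node", {
  syn <- generate_node_image(scene_spec(
    width = 300, height = 300, axes = c(80, 60), fraction = 0.5, seed = 1))
  node <- roi_from_mask(syn$truth$node_mask)
  bg <- place_background_circle(node, c(300, 300))
  expect_false(any(bg$mask & node$mask))
  expect_lte(abs(bg$area_px - 5806) / 5806, 0.01)
})

test_that("thresholding matches a per-pixel comparison oracle", {
  for (seed in 4:6) {
    img <- random_image(16, 16, seed)
    hsi <- rgb_to_hsi(img)
    roi <- roi_rectangle(c(16, 16), 3, 2, 14, 15)
    for (tn in c("A", "B", "T2")) {
      t <- builtin_threshold(tn)
      got <- apply_threshold(hsi, roi, t)
      ref <- oracle_threshold(hsi, roi$mask, t$hue_min, t$hue_max,
                              t$intensity_min, t$intensity_max)
      expect_identical(got, ref)
    }
  }
})

test_that("raising the intensity floor never grows the signal mask", {
  syn <- tiny_scene(0.7, seed = 2, fluor_intensity_mean = 40,
                    fluor_intensity_spread = 12)
  hsi <- rgb_to_hsi(syn$image)
  node <- roi_from_mask(syn$truth$node_mask)
  m_a <- apply_threshold(hsi, node, "A")    # floor 30
  m_2 <- apply_threshold(hsi, node, "T2")   # floor 35
  m_3 <- apply_threshold(hsi, node, "T3")   # floor 45
  expect_true(all(m_2 <= m_a))
  expect_true(all(m_3 <= m_2))
  expect_gte(sum(m_a), sum(m_2))
  expect_gte(sum(m_2), sum(m_3))
})

test_that("surface fluorescence is the exact signal share of the node", {
  syn <- tiny_scene(0.5, seed = 7)
  node <- roi_from_mask(syn$truth$node_mask)

  empty <- matrix(FALSE, 128, 128)
  expect_equal(surface_fluorescence(empty, node)$surface_fluorescence_pct, 0)

  full <- surface_fluorescence(node$mask, node)
  expect_equal(full$surface_fluorescence_pct, 100)

  part <- surface_fluorescence(syn$truth$fluor_mask, node)
  expect_equal(part$surface_fluorescence_pct,
               100 * syn$truth$realized_fraction)
  expect_lte(abs(part$surface_fluorescence_pct - 50), 1)

  expect_error(surface_fluorescence(empty, roi_from_mask(empty)),
               "degenerate")
  outside <- matrix(TRUE, 128, 128)
  expect_error(surface_fluorescence(outside, node), "outside")
})

test_that("average intensity is the blue-channel mean over signal pixels", {
  syn <- tiny_scene(0.5, seed = 3, fluor_intensity_spread = 0,
                    fluor_intensity_mean = 200)
  hsi <- rgb_to_hsi(syn$image)
  node <- roi_from_mask(syn$truth$node_mask)
  sig <- apply_threshold(hsi, node, "A")
  bg <- background_circle(c(128, 128), c(20, 20), 900)
  got <- average_intensity(syn$image, hsi, sig, bg, "A", node)
  expect_equal(got$mean_fi_au, 200)
  expect_equal(got$background_fi_au, 0)

  # jittered intensities: matches a brute-force sum/N over the mask
  syn2 <- tiny_scene(0.5, seed = 4, fluor_intensity_mean = 90,
                     fluor_intensity_spread = 15)
  hsi2 <- rgb_to_hsi(syn2$image)
  node2 <- roi_from_mask(syn2$truth$node_mask)
  sig2 <- apply_threshold(hsi2, node2, "A")
  got2 <- average_intensity(syn2$image, hsi2, sig2, NULL, "A")
  expect_equal(got2$mean_fi_au,
               oracle_mean_over_mask(syn2$image[, , 3], sig2))

  # empty signal mask yields the 0 AU convention
  none <- matrix(FALSE, 128, 128)
  expect_equal(average_intensity(syn$image, hsi, none, bg, "A")$mean_fi_au, 0)

  # background ROI overlapping the node is rejected
  expect_error(
    average_intensity(syn$image, hsi, sig, node, "A", node),
    "overlaps")
})

test_that("quantify_image recovers ground truth over a fraction grid", {
  for (seed in 1:3) {
    realized <- measured <- numeric(0)
    for (fr in seq(0, 1, by = 0.1)) {
      syn <- tiny_scene(fr, seed = seed)
      node <- roi_from_mask(syn$truth$node_mask)
      q <- quantify_image(syn$image, node, thresholds = "A",
                          filter_radius = 0)
      measured <- c(measured, q$surface_fluorescence_pct)
      realized <- c(realized, 100 * syn$truth$realized_fraction)
      expect_equal(q$surface_fluorescence_pct,
                   100 * syn$truth$realized_fraction)
    }
    expect_lte(max(abs(measured - seq(0, 100, by = 10))), 1)
    expect_false(is.unsorted(measured))
  }
})

test_that("constant-intensity scenes recover the construction intensity exactly", {
  syn <- tiny_scene(0.6, seed = 5, fluor_intensity_mean = 52,
                    fluor_intensity_spread = 0)
  node <- roi_from_mask(syn$truth$node_mask)
  q <- quantify_image(syn$image, node, thresholds = c("T1", "T2", "T3"),
                      filter_radius = 0)
  expect_true(all(q$mean_fi_au == 52))
  expect_true(all(q$background_fi_au == 0))
})

test_that("dull scenes separate the lenient and strict thresholds", {
  syn <- tiny_scene(0.5, seed = 6, fluor_intensity_mean = 38,
                    fluor_intensity_spread = 4)
  node <- roi_from_mask(syn$truth$node_mask)
  q <- quantify_image(syn$image, node, thresholds = c("A", "B", "T2", "T3"),
                      filter_radius = 0)
  pct <- setNames(q$surface_fluorescence_pct, q$threshold)
  expect_gt(pct[["A"]], pct[["B"]])
  expect_gt(pct[["T2"]], 0)
  expect_equal(pct[["T3"]], 0)
})
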