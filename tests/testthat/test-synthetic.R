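test_that("generated scenes are deterministic and honor the requested fraction", {
  for (fr in c(0.25, 0.5, 0.9)) {
    a <- tiny_scene(fr, seed = 7)
    b <- tiny_scene(fr, seed = 7)
    expect_identical(a$image, b$image)
    expect_identical(a$truth, b$truth)

    n_node <- sum(a$truth$node_mask)
    n_fluor <- sum(a$truth$fluor_mask)
    expect_lte(abs(n_fluor - fr * n_node), 1)
    expect_equal(a$truth$realized_fraction, n_fluor / n_node)
    expect_lte(abs(a$truth$realized_fraction - fr), 0.01)
    # fluorescent pixels are node pixels
    expect_false(any(a$truth$fluor_mask & !a$truth$node_mask))
  }
})

test_that("limits of the fraction range behave as negative/positive controls", {
  neg <- tiny_scene(0)
  expect_false(any(neg$truth$fluor_mask))
  expect_identical(neg$truth$realized_fraction, 0)

  pos <- tiny_scene(1, seed = 2)
  expect_identical(pos$truth$realized_fraction, 1)
  hsi <- rgb_to_hsi(pos$image)
  in_band <- hsi$hue >= 165 & hsi$hue <= 180
  expect_true(all(in_band[pos$truth$node_mask]))
})

test_that("requested-vs-realized pixel count matches a brute-force recount", {
  syn <- generate_node_image(scene_spec(
    width = 160, height = 160, axes = c(60, 40), fraction = 0.5, seed = 7))
  n_node <- sum(syn$truth$node_mask)
  n_fluor <- sum(syn$truth$fluor_mask)
  expect_lte(abs(n_fluor - round(0.5 * n_node)), 1)
  expect_lte(abs(syn$truth$realized_fraction - 0.5), 0.01)
})

test_that("background pixels equal the background color exactly", {
  syn <- tiny_scene(0.6, seed = 11)
  outside <- !syn$truth$node_mask
  for (c in 1:3) {
    plane <- syn$image[, , c]
    expect_true(all(plane[outside] == syn$spec$background_color[c]))
  }
})

test_that("node area is conserved across fractions and realized fraction is monotone", {
  areas <- integer(0); realized <- numeric(0)
  for (fr in seq(0, 1, by = 0.2)) {
    s <- tiny_scene(fr, seed = 5)
    areas <- c(areas, sum(s$truth$node_mask))
    realized <- c(realized, s$truth$realized_fraction)
  }
  expect_length(unique(areas), 1L)
  expect_false(is.unsorted(realized))
})

test_that("fluorescent pixels carry the requested hue and intensity statistics", {
  syn <- tiny_scene(0.5, seed = 3,
                    fluor_intensity_mean = 120, fluor_intensity_spread = 10)
  hsi <- rgb_to_hsi(syn$image)
  fm <- syn$truth$fluor_mask
  expect_true(all(hsi$hue[fm] == syn$spec$fluor_hue))
  expect_true(all(hsi$intensity[fm] >= 110 & hsi$intensity[fm] <= 130))
  expect_equal(mean(hsi$intensity[fm]), syn$truth$realized_mean_intensity)
  # spread 0 gives a constant intensity exactly at the mean
  syn0 <- tiny_scene(0.5, seed = 3, fluor_intensity_spread = 0)
  hsi0 <- rgb_to_hsi(syn0$image)
  expect_true(all(hsi0$intensity[syn0$truth$fluor_mask] ==
                    syn0$spec$fluor_intensity_mean))
})

test_that("off-center hues inside the blue band are reproduced exactly", {
  for (hue in c(165L, 168L, 175L, 180L)) {
    syn <- tiny_scene(0.4, seed = 4, fluor_hue = hue,
                      fluor_intensity_mean = 80, fluor_intensity_spread = 5)
    hsi <- rgb_to_hsi(syn$image)
    expect_true(all(hsi$hue[syn$truth$fluor_mask] == hue),
                label = paste("hue", hue, "reproduced"))
  }
})

test_that("blob mode places a contiguous region with the same count accuracy", {
  syn <- tiny_scene(0.3, seed = 9, region_mode = "blob")
  n_node <- sum(syn$truth$node_mask)
  expect_lte(abs(sum(syn$truth$fluor_mask) - round(0.3 * n_node)), 1)
  # contiguity: every fluor pixel has a fluor 8-neighbor (for > 1 px regions)
  fm <- syn$truth$fluor_mask
  idx <- which(fm, arr.ind = TRUE)
  has_nb <- apply(idx, 1, function(p) {
    nb <- expand.grid(y = p[1] + (-1:1), x = p[2] + (-1:1))
    nb <- nb[!(nb$y == p[1] & nb$x == p[2]), ]
    nb <- nb[nb$y >= 1 & nb$y <= nrow(fm) & nb$x >= 1 & nb$x <= ncol(fm), ]
    any(fm[cbind(nb$y, nb$x)])
  })
  expect_true(all(has_nb))
})

test_that("invalid scene specs are rejected", {
  expect_error(scene_spec(width = 100, height = 100, axes = c(60, 40)),
               "inside the image")
  expect_error(scene_spec(fraction = 1.2), "fraction")
  expect_error(scene_spec(fraction = 0.5, fluor_hue = 120), "blue band")
  expect_error(scene_spec(nonfluor_node_color = c(40, 40, 200)),
               "hue band")
})

test_that("negative controls contain no thresholdable blue anywhere", {
  for (seed in 1:3) {
    neg <- generate_negative_control(128, seed)
    hsi <- rgb_to_hsi(neg$image)
    hot <- hsi$hue >= 165 & hsi$hue <= 180 & hsi$intensity >= 30
    expect_false(any(hot))
    again <- generate_negative_control(128, seed)
    expect_identical(neg$image, again$image)
  }
})

test_that("dull perturbation pushes intensities between the lenient and strict floors", {
  syn <- tiny_scene(0.5, seed = 6)
  dull <- perturb_scene(syn, "dull_fluorescence", magnitude = 1, target = 32)
  hsi <- rgb_to_hsi(dull$image)
  v <- hsi$intensity[dull$truth$fluor_mask]
  expect_true(all(v == 32))
  expect_equal(dull$truth$realized_mean_intensity, 32)
  # passes the 30 AU floor, fails the 45 AU floor
  node <- roi_from_mask(dull$truth$node_mask)
  expect_gt(sum(apply_threshold(hsi, node, "T1")), 0)
  expect_identical(sum(apply_threshold(hsi, node, "T3")), 0L)
})

test_that("fat occlusion removes the stated share of signal and updates truth", {
  syn <- tiny_scene(0.6, seed = 8)
  occ <- perturb_scene(syn, "fat_occlusion", magnitude = 0.5, seed = 2)
  expect_lte(abs(occ$truth$realized_fraction - 0.3), 0.01)
  expect_false(any(occ$truth$fluor_mask & !syn$truth$fluor_mask))
  node <- roi_from_mask(occ$truth$node_mask)
  q <- quantify_image(occ$image, node, thresholds = "A", filter_radius = 0)
  expect_lte(abs(q$surface_fluorescence_pct - 30), 1)

  expect_identical(perturb_scene(syn, "fat_occlusion", 0), syn)
  expect_error(perturb_scene(syn, "smudge", 0.5), "arg")
})

test_that("ambient light tints only the background and stays off-band", {
  syn <- tiny_scene(0.5, seed = 12)
  amb <- perturb_scene(syn, "ambient_light", magnitude = 1)
  expect_identical(amb$image[syn$truth$node_mask],
                   syn$image[syn$truth$node_mask])
  hsi <- rgb_to_hsi(amb$image)
  bg <- !syn$truth$node_mask
  expect_false(any(hsi$hue[bg] >= 165 & hsi$hue[bg] <= 180 &
                     hsi$intensity[bg] >= 30))
})

test_that("scenes round-trip through PNG and JSON sidecars", {
  dir <- withr::local_tempdir()
  syn <- tiny_scene(0.5, seed = 10)
  paths <- write_scene(syn, dir, "s1")
  expect_identical(read_image(paths[["image"]]), syn$image)
  expect_identical(read_mask(paths[["node_mask"]]), syn$truth$node_mask)
  expect_identical(read_mask(paths[["fluor_mask"]]), syn$truth$fluor_mask)
  side <- jsonlite::read_json(paths[["truth"]])
  expect_equal(side$realized_fraction, syn$truth$realized_fraction)
})
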