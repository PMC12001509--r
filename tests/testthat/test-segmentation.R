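test_that("connected-component labeling matches hand-labeled patterns", {
  m <- matrix(FALSE, 5, 6)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE          # diagonal neighbour of (1,1)
  m[4:5, 4:6] <- TRUE      # block
  lm8 <- label_components(m, 8)
  expect_identical(lm8$n_objects, 2L)
  expect_identical(lm8$labels[1, 1], lm8$labels[2, 2])
  lm4 <- label_components(m, 4)
  expect_identical(lm4$n_objects, 3L)
  expect_false(lm4$labels[1, 1] == lm4$labels[2, 2])
  # labels are consecutive 1..n in row-major first-occurrence order
  expect_identical(sort(unique(as.vector(lm8$labels[lm8$labels > 0]))), 1:2)
})

test_that("distance transform equals a brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    mk <- matrix(runif(25 * 35) < 0.04, 25, 35)
    d <- perimembrane:::distance_to_mask_cpp(mk)
    expect_equal(d, brute_edt(mk), tolerance = 1e-12)
  }
})

test_that("nuclei segmentation recovers ground-truth disks exactly", {
  sp <- noise_free_spec(image_height_px = 420, image_width_px = 420,
                        n_cells = 5, cell_radius_px = c(35, 45), seed = 17)
  sc <- generate_scene(sp)
  expect_identical(sc$n_cells_placed, 5L)
  lm <- segment_nuclei(sc$channels$nuclei, 100)
  expect_identical(lm$n_objects, 5L)
  gt <- sc$ground_truth$nucleus_labels$labels
  # each recovered object's pixel set equals its ground-truth disk
  for (l in 1:5) {
    gl <- unique(gt[lm$labels == l])
    expect_length(gl, 1)
    expect_identical(which(lm$labels == l), which(gt == gl))
  }
})

test_that("nuclei segmentation handles degenerate inputs", {
  zero <- image_channel(matrix(0L, 50, 50), "nuclei")
  expect_identical(segment_nuclei(zero, 10)$n_objects, 0L)
  sig <- image_channel(matrix(0L, 5, 5), "signal")
  expect_error(segment_nuclei(sig, 10), "nuclei channel")
})

test_that("a rasterized disk's recovered area is within 5% of the analytic value", {
  img <- matrix(0L, 60, 60)
  img[disk_mask(20, 10)] <- 10000L
  lm <- segment_nuclei(image_channel(img, "nuclei"), 10)
  expect_identical(lm$n_objects, 1L)
  expect_lt(abs(sum(lm$labels == 1) - pi * 400) / (pi * 400), 0.05)
})

test_that("exclusion mask follows Euclidean expansion semantics", {
  m <- matrix(0L, 11, 11)
  m[6, 6] <- 1L
  lm <- perimembrane:::new_label_map(m, 1L)
  # distance 0 is the nucleus itself
  expect_identical(which(build_exclusion_mask(lm, 0)), which(m == 1L))
  # distance 1 around a single pixel is the 5-pixel plus shape
  ex1 <- build_exclusion_mask(lm, 1)
  expect_identical(sum(ex1), 5L)
  expect_true(all(ex1[cbind(c(5, 6, 6, 6, 7), c(6, 5, 6, 7, 6))]))
  # monotone in the distance
  prev <- ex1
  for (d in c(2, 3.5, 7)) {
    cur <- build_exclusion_mask(lm, d)
    expect_true(all(cur[prev]))
    prev <- cur
  }
  # empty labels give an empty mask
  none <- perimembrane:::new_label_map(matrix(0L, 4, 4), 0L)
  expect_false(any(build_exclusion_mask(none, 5)))
})

test_that("fragment detection respects the exclusion mask and ground truth", {
  sp <- small_noise_free_spec(seed = 23)
  sc <- generate_scene(sp)
  cfg <- run_config()
  nl <- segment_nuclei(sc$channels$nuclei, cfg$nuclei_min_area_px)
  excl <- build_exclusion_mask(nl, cfg$expansion_distance_px)
  lm <- detect_membrane_fragments(sc$channels$signal, excl)
  expect_gt(lm$n_objects, 0)
  # no object pixel inside the exclusion mask
  expect_identical(sum(lm$labels > 0 & excl), 0L)
  # every detected pixel lies in the true membrane annulus
  mem <- sc$ground_truth$membrane_labels$labels > 0
  expect_identical(sum(lm$labels > 0 & !mem), 0L)
  # a zero image yields no objects
  zero <- image_channel(matrix(0L, 30, 30), "signal")
  expect_identical(
    detect_membrane_fragments(zero, matrix(FALSE, 30, 30))$n_objects, 0L)
  expect_error(detect_membrane_fragments(sc$channels$signal, excl,
                                         "mystery"), "unknown threshold")
  expect_error(detect_membrane_fragments(sc$channels$signal,
                                         matrix(FALSE, 2, 2)), "shape")
})

test_that("expanding the exclusion removes halo-level intensities from objects", {
  sp <- small_noise_free_spec(seed = 29)
  sc <- generate_scene(sp)
  nl <- segment_nuclei(sc$channels$nuclei, 100)
  sig <- sc$channels$signal
  halo_val <- sp$perinuclear_intensity
  lm0 <- detect_membrane_fragments(sig, build_exclusion_mask(nl, 0))
  lm10 <- detect_membrane_fragments(sig, build_exclusion_mask(nl, 10))
  px0 <- sig$pixels[lm0$labels > 0]
  px10 <- sig$pixels[lm10$labels > 0]
  # with no expansion the detected pool contains halo-level pixels;
  # a 10 px expansion removes them (membrane is brighter than halo here)
  expect_true(any(px0 == halo_val))
  expect_false(any(px10 == halo_val))
})

test_that("shape measures match analytic geometry within documented bounds", {
  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE
  s <- measure_shape(label_components(sq), 1)
  expect_identical(s$area_px, 400L)
  expect_lt(abs(s$circularity - pi / 4) / (pi / 4), 0.15)

  dk <- disk_mask(30)
  d <- measure_shape(label_components(dk), 1)
  expect_gte(d$circularity, 0.85)

  bar <- matrix(FALSE, 10, 110); bar[4:6, 6:105] <- TRUE
  b <- measure_shape(label_components(bar), 1)
  expect_lt(b$circularity, 0.3)
  expect_lt(abs(b$circularity - 0.089) / 0.089, 1)  # within a factor 2

  expect_error(measure_shape(label_components(sq), 7), "not present")
})

test_that("fragment filtering applies both rules, relabels, and is idempotent", {
  img <- matrix(FALSE, 80, 220)
  img[10:49, 10:49] <- TRUE                      # disk-ish block, circ high
  img[65:67, 10:160] <- TRUE                     # thin bar, retained
  img[75:76, 200:204] <- TRUE                    # tiny object, area < 50
  lm <- label_components(img)
  expect_identical(lm$n_objects, 3L)
  st <- measure_shapes(lm)
  res <- filter_fragments(lm, st, c(50, 10000), 0.3)
  expect_identical(res$map$n_objects, 1L)
  expect_identical(res$mapping$old, 2L)
  expect_identical(res$mapping$new, 1L)
  # the retained object is the bar
  expect_true(all(which(res$map$labels == 1) == which(lm$labels == 2)))
  # idempotence
  st2 <- measure_shapes(res$map)
  res2 <- filter_fragments(res$map, st2, c(50, 10000), 0.3)
  expect_identical(res2$map$labels, res$map$labels)
  # empty input passes through
  none <- perimembrane:::new_label_map(matrix(0L, 5, 5), 0L)
  expect_identical(filter_fragments(none, st[0, ], c(50, 100), 0.3)$map$n_objects, 0L)
})

test_that("thresholds separate known mixtures (cross-checked vs skimage)", {
  # expected values frozen from skimage.filters.threshold_otsu /
  # threshold_multiotsu on the same draws: 134.78 and [31.7, 3335.4]
  set.seed(5)
  lo <- rnorm(4000, 100, 10); hi <- rnorm(1000, 1000, 30)
  t2 <- otsu_threshold(c(lo, hi))
  expect_gt(mean(lo < t2), 0.99)   # low mode below the threshold
  expect_gt(mean(hi > t2), 0.999)  # high mode above it
  expect_lt(abs(t2 - 134.78) / 134.78, 0.05)
  # three-class split of background / cytoplasm / membrane keeps only the top
  set.seed(6)
  bg <- rnorm(20000, 10, 5); cyto <- rnorm(5000, 3000, 80)
  mem <- rnorm(1000, 7500, 100)
  t3 <- perimembrane:::otsu3_thresholds(c(bg, cyto, mem))
  expect_gt(mean(cyto < t3[2]), 0.99)
  expect_identical(mean(mem > t3[2]), 1)
  expect_gt(mean(bg < t3[1]), 0.99)
  expect_lt(abs(t3[2] - 3335.4) / 3335.4, 0.05)
})
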