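test_that("empty spec with no noise yields all-zero channels and empty truth", {
  sp <- small_noise_free_spec(n_cells = 0)
  sc <- generate_scene(sp)
  expect_true(all(sc$channels$nuclei$pixels == 0))
  expect_true(all(sc$channels$signal$pixels == 0))
  expect_identical(sc$ground_truth$nucleus_labels$n_objects, 0L)
  expect_identical(nrow(sc$ground_truth$cell_table), 0L)
})

test_that("painted-intensity contract: membrane/cytoplasm ratio is exact per cell", {
  sp <- small_noise_free_spec(membrane_enrichment = 3, seed = 2)
  sc <- generate_scene(sp, enrichment_multiplier = 1)
  gt <- sc$ground_truth
  sig <- sc$channels$signal$pixels
  for (i in seq_len(sc$n_cells_placed)) {
    mm <- mean(sig[gt$membrane_labels$labels == i])
    cm <- mean(sig[gt$cytoplasm_labels$labels == i])
    expect_equal(mm / cm, 3, tolerance = 1e-12)
  }
  # multiplier scales the ratio exactly
  sc2 <- generate_scene(sp, enrichment_multiplier = 1.35)
  gt2 <- sc2$ground_truth
  r2 <- mean(sc2$channels$signal$pixels[gt2$membrane_labels$labels == 1]) /
    mean(sc2$channels$signal$pixels[gt2$cytoplasm_labels$labels == 1])
  expect_equal(r2, 3 * 1.35, tolerance = 1e-12)
})

test_that("identical spec and seed reproduce byte-identical TIFF output", {
  sp <- small_spec(seed = 7, n_cells = 3)
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$channels$signal$pixels, s2$channels$signal$pixels)
  write_tiff(list(s1$channels$nuclei$pixels, s1$channels$signal$pixels), f1)
  write_tiff(list(s2$channels$nuclei$pixels, s2$channels$signal$pixels), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("ground-truth supports are disjoint and match the cell table", {
  sc <- generate_scene(small_spec(seed = 3))
  gt <- sc$ground_truth
  expect_identical(sum(gt$nucleus_labels$labels > 0 &
                         gt$membrane_labels$labels > 0), 0L)
  expect_identical(sum(gt$nucleus_labels$labels > 0 &
                         gt$halo_labels$labels > 0), 0L)
  mem_labels <- sort(unique(gt$membrane_labels$labels[
    gt$membrane_labels$labels > 0]))
  expect_identical(mem_labels, gt$cell_table$cell)
  # in a noise-free scene the nuclei channel carries no membrane paint
  # and the signal channel carries no nucleus paint
  nf <- generate_scene(small_noise_free_spec(seed = 3))
  gtn <- nf$ground_truth
  expect_true(all(nf$channels$nuclei$pixels[gtn$membrane_labels$labels > 0] == 0))
  expect_true(all(nf$channels$signal$pixels[gtn$nucleus_labels$labels > 0] == 0))
})

test_that("Poisson noise on a constant patch has variance close to its mean", {
  # one large cell; the cytoplasm is a constant-intensity region > 1e4 px
  sp <- scene_spec(image_height_px = 220, image_width_px = 220, n_cells = 1,
                   cell_radius_px = c(95, 95), nucleus_radius_fraction = 0.2,
                   gaussian_noise_sd = 0, poisson_noise = TRUE,
                   cell_brightness_cv = 0, seed = 5)
  sc <- generate_scene(sp)
  cyto <- sc$ground_truth$cytoplasm_labels$labels == 1
  expect_gt(sum(cyto), 1e4)
  v <- as.numeric(sc$channels$signal$pixels[cyto])
  expect_lt(abs(var(v) / mean(v) - 1), 0.1)
})

test_that("values are clipped to the configured bit depth", {
  sp <- small_noise_free_spec(cytoplasm_intensity = 40000,
                              membrane_enrichment = 3, seed = 4)
  sc <- generate_scene(sp)
  expect_lte(max(sc$channels$signal$pixels), 2^16 - 1)
  expect_identical(max(sc$channels$signal$pixels), 65535L)
})

test_that("impossible geometry is rejected with a diagnostic", {
  expect_error(scene_spec(nucleus_radius_fraction = 1.2),
               "impossible geometry")
  expect_error(scene_spec(nucleus_radius_fraction = 0.9),
               "impossible geometry")
})

test_that("crowded fields emit fewer cells with a warning and a record", {
  sp <- scene_spec(image_height_px = 200, image_width_px = 200,
                   n_cells = 30, cell_radius_px = c(35, 45), seed = 9)
  expect_warning(sc <- generate_scene(sp), "placed only")
  expect_lt(sc$n_cells_placed, 30)
  expect_identical(sc$n_cells_requested, 30)
  expect_identical(nrow(sc$ground_truth$cell_table), sc$n_cells_placed)
})

test_that("condition sets write one TIFF per image plus a seeded manifest", {
  out <- withr::local_tempdir()
  presets <- list(condition_preset("CTRL", 1), condition_preset("FK", 1.35),
                  condition_preset("TH", 1.2), condition_preset("FK+TH", 1.5))
  sp <- small_noise_free_spec(seed = 21, n_cells = 2)
  man <- generate_condition_set(sp, presets, images_per_condition = 3, out)
  expect_identical(nrow(man), 12L)
  expect_true(all(file.exists(file.path(out, man$file))))
  expect_identical(sort(unique(man$condition)),
                   sort(c("CTRL", "FK", "TH", "FK+TH")))
  # deterministic rerun: identical manifest and identical image bytes
  out2 <- withr::local_tempdir()
  man2 <- generate_condition_set(sp, presets, images_per_condition = 3, out2)
  expect_identical(man, man2)
  for (f in man$file)
    expect_identical(readBin(file.path(out, f), "raw",
                             file.size(file.path(out, f))),
                     readBin(file.path(out2, f), "raw",
                             file.size(file.path(out2, f))))
})

test_that("condition multipliers scale the true enrichment ratio exactly", {
  sp <- small_noise_free_spec(seed = 31, n_cells = 3)
  ctrl <- generate_scene(local({ s <- sp; s$seed <- 101L; s }), 1)
  trt <- generate_scene(local({ s <- sp; s$seed <- 102L; s }), 1.35)
  # per-cell true enrichment is recorded in the ground truth
  r <- mean(trt$ground_truth$cell_table$enrichment) /
    mean(ctrl$ground_truth$cell_table$enrichment)
  expect_equal(r, 1.35, tolerance = 1e-12)
})

test_that("preset validation rejects duplicates and missing control", {
  sp <- small_noise_free_spec(n_cells = 1)
  out <- withr::local_tempdir()
  expect_error(generate_condition_set(
    sp, list(condition_preset("A", 1), condition_preset("A", 2)), 1, out),
    "duplicate")
  expect_error(generate_condition_set(
    sp, list(condition_preset("A", 1.2), condition_preset("B", 2)), 1, out),
    "control")
  expect_error(condition_preset("A", -1), "positive")
})
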