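test_that("a fixed seed reproduces samples and datasets voxel for voxel", {
  sp <- tiny_spec(seed = 7L)
  a <- generate_sample(sp)
  b <- generate_sample(sp)
  expect_identical(a$image$synapse, b$image$synapse)
  expect_identical(a$image$cytoplasmic, b$image$cytoplasmic)
  expect_identical(truth_mask(a), truth_mask(b))
  expect_identical(a$puncta_truth, b$puncta_truth)

  d1 <- generate_dataset(sp, 3L)
  d2 <- generate_dataset(sp, 3L)
  expect_identical(lapply(d1, truth_mask), lapply(d2, truth_mask))
  expect_length(generate_dataset(sp, 1L), 1L)
  expect_error(generate_dataset(sp, 0L), "n_images")
})

test_that("ground-truth component count equals the requested puncta count", {
  for (seed in 1:5) {
    n <- sample(5:12, 1)
    s <- generate_sample(tiny_spec(seed = seed, n_puncta = n))
    comp <- extract_puncta(s$synapse_truth, s$image, connectivity = 26L)
    expect_identical(nrow(comp$df), as.integer(n))
  }
})

test_that("zero puncta give an all-false truth and a neurite-only image", {
  s <- generate_sample(tiny_spec(seed = 3L, n_puncta = 0L, n_clutter = 0L))
  expect_false(any(s$synapse_truth))
  expect_identical(nrow(s$puncta_truth), 0L)
  # synapse channel is pure background + noise: nothing punctate survives
  bg <- s$spec$background_level
  expect_lt(max(s$image$synapse), bg + 6 * s$spec$noise_sd)
})

test_that("measured punctum SNR matches the nominal preset value within 10%", {
  snr <- vapply(1:20, function(seed) {
    s <- generate_sample(synthetic_spec("small_high_snr", seed = seed))
    ctr <- round(as.matrix(s$puncta_truth[, c("center_z", "center_y", "center_x")]))
    idx <- punctaseg:::coords_to_index(ctr, dim(s$image$synapse))
    (mean(s$image$synapse[idx]) - s$spec$background_level) / s$spec$noise_sd
  }, numeric(1))
  nominal <- 200 / 20
  expect_lt(abs(mean(snr) - nominal) / nominal, 0.10)
})

test_that("all truth voxels lie close to the skeleton polyline", {
  for (seed in c(2L, 9L)) {
    s <- generate_sample(synthetic_spec("small_high_snr", seed = seed))
    vox <- which(truth_mask(s))
    co <- punctaseg:::index_to_coords(vox, dim(s$image$synapse))
    nodes <- as.matrix(s$skeleton_truth$nodes[, c("z", "y", "x")])  # spacing 1
    dmin <- punctaseg:::cpp_min_dist_points(co * 1.0, nodes)
    bound <- s$spec$neurite_radius + max(s$spec$puncta_radius_range)
    expect_lte(max(dmin), bound)
  }
})

test_that("impossible placements error with the achieved count", {
  sp <- tiny_spec(seed = 1L)
  sp$n_puncta <- 500L
  expect_error(generate_sample(sp), "non-overlapping puncta")
})

test_that("spec invariants are validated", {
  expect_error(synthetic_spec(n_puncta = -1), "n_puncta")
  expect_error(synthetic_spec(puncta_radius_range = c(3, 1)), "radius_range")
  expect_error(synthetic_spec(shape = c(8, 32, 32),
                              neurite_paths = cbind(4, 16, c(1, 40))),
               "inside the volume")
})

test_that("a JSON config file fully determines a dataset", {
  sp <- tiny_spec(seed = 9L)
  sp$neurite_paths <- list(cbind(z = c(4, 4), y = c(10, 38), x = c(6, 42)))
  f <- withr::local_tempfile(fileext = ".json")
  write_spec_json(sp, f)
  sp2 <- read_spec_json(f)
  expect_identical(generate_sample(sp2)$image$synapse,
                   generate_sample(sp)$image$synapse)
})

test_that("written samples round-trip through the on-disk formats", {
  s <- generate_sample(tiny_spec(seed = 5L))
  dir <- withr::local_tempdir()
  paths <- write_sample(s, dir, "t")
  expect_true(all(file.exists(paths)))

  img <- suppressWarnings(read_stack(c(synapse = unname(paths["synapse"]),
                                       cytoplasmic = unname(paths["cytoplasmic"]))))
  # 16-bit quantization: intensities agree to the nearest integer
  expect_lt(max(abs(img$synapse - s$image$synapse)), 1)
  expect_identical(punctaseg:::as_mask(read_label(paths["synapse_truth"])),
                   truth_mask(s))
  sk <- load_skeleton(paths["skeleton"])
  expect_equal(sk$total_length, s$skeleton_truth$total_length, tolerance = 1e-6)
  expect_equal(nrow(sk$nodes), nrow(s$skeleton_truth$nodes))
})
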