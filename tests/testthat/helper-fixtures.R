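# Shared fixtures. Heavy artifacts (trained models, multi-seed benchmark
# runs) are computed once per session and cached here so several test
# files can assert on the same run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# strip the synapse image down to a single channel (no cytoplasmic
# giveaway), the single-channel-reporter scenario where masking matters
syn_only <- function(sample) {
  vol_image(sample$image$synapse, spacing = sample$image$spacing)
}

truth_mask <- function(sample) punctaseg:::as_mask(sample$synapse_truth)

# region of interest used for masked prediction: dilated true neurite
roi_mask <- function(sample, r = 2L) {
  punctaseg:::cpp_dilate_binary(punctaseg:::as_mask(sample$neurite_truth), r, FALSE)
}

# small, quick spec for unit tests that only need a labeled image
tiny_spec <- function(seed = 1L, n_puncta = 6L, n_clutter = 2L) {
  synthetic_spec("small_high_snr", shape = c(8L, 48L, 48L),
                 n_puncta = n_puncta, n_clutter = n_clutter, seed = seed)
}

# pure-R recursive flood fill: the independent component-labelling oracle
flood_fill_oracle <- function(vol, connectivity) {
  d <- dim(vol)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[s > 0 & s <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  fill <- function(z, y, x) {
    lab[z, y, x] <<- cur
    for (k in seq_len(nrow(offs))) {
      z2 <- z + offs[k, 1]; y2 <- y + offs[k, 2]; x2 <- x + offs[k, 3]
      if (z2 >= 1 && z2 <= d[1] && y2 >= 1 && y2 <= d[2] &&
          x2 >= 1 && x2 <= d[3] && vol[z2, y2, x2] && lab[z2, y2, x2] == 0L)
        fill(z2, y2, x2)
    }
  }
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1]))
    if (vol[z, y, x] && lab[z, y, x] == 0L) { cur <- cur + 1L; fill(z, y, x) }
  lab
}

# canonical form of a labelling: component id of each positive voxel,
# components renumbered by their first voxel in array order
canonical_partition <- function(lab) {
  ids <- lab[lab > 0]
  match(ids, unique(ids))
}

# straight skeleton along x: n nodes spaced `step` um apart
straight_skeleton <- function(n = 11L, step = 1, z = 2, y = 2) {
  skeleton_from_nodes(cbind(rep(z, n), rep(y, n), seq(0, by = step, length.out = n) + 1),
                      parent = c(-1L, seq_len(n - 1L)))
}

# ---- cached heavy runs used by the acceptance suite ----

# two-layer model trained on one synapse-only image, plus ten held-out
# seeds scored masked: component counts and per-layer F1
recovery_runs <- function() cached("recovery_runs", {
  spec <- synthetic_spec("small_high_snr", seed = 101L)
  train <- generate_sample(spec)
  model <- train_synapse_model(syn_only(train), train$synapse_truth, seed = 0L)
  res <- lapply(1:10, function(i) {
    sp <- spec; sp$seed <- 200L + i
    s <- generate_sample(sp)
    mask <- roi_mask(s)
    p2 <- segment_synapses(model, syn_only(s), mask = mask)
    p1 <- segment_synapses(model, syn_only(s), mask = mask, layers = 1)
    list(truth_n = nrow(s$puncta_truth),
         pred_n = nrow(extract_puncta(p2, s$image)$df),
         f1_l1 = segmentation_score(p1, truth_mask(s))$f1,
         f1_l2 = segmentation_score(p2, truth_mask(s))$f1)
  })
  list(model = model,
       truth_n = vapply(res, `[[`, numeric(1), "truth_n"),
       pred_n = vapply(res, `[[`, numeric(1), "pred_n"),
       f1_l1 = vapply(res, `[[`, numeric(1), "f1_l1"),
       f1_l2 = vapply(res, `[[`, numeric(1), "f1_l2"))
})

# six-image dataset benchmark at training sizes 1 and 5 (all combinations)
benchmark_1v5 <- function() cached("benchmark_1v5", {
  ds <- generate_dataset(synthetic_spec("small_high_snr", seed = 301L), 6L)
  benchmark_training_size(ds, sizes = c(1L, 5L), cap = 6L, seed = 0L)
})

# reduced-scale neurite U-Net: 10 training tubes, 64x64 tiles
# reduced-scale neurite U-Net: 10:2:4 train/validation/test split of 16
# synthetic tube stacks, 64x64 tiles
unet_run <- function() cached("unet_run", {
  ds <- generate_dataset(synthetic_spec("small_high_snr", seed = 401L), 16L)
  cfg <- unet_config(levels = 2L, base = 8L, tile = c(64L, 64L),
                     epochs = 25L, patience = 10L, batch_size = 8L,
                     patches_per_image = 8L, seed = 0L)
  model <- train_neurite_model(ds[1:10], val = ds[11:12], config = cfg)
  ious <- vapply(ds[13:16], function(s)
    compute_iou(segment_neurites(model, s$image), s$neurite_truth), numeric(1))
  list(model = model, ious = ious)
})
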