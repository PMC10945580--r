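test_that("component extraction matches the recursive flood-fill oracle", {
  set.seed(10)
  zero_img <- function(d) vol_image(array(0, d))
  for (i in 1:12) {
    d <- c(sample(2:8, 1), sample(2:8, 1), sample(2:8, 1))
    vol <- array(runif(prod(d)) < 0.35, d)
    for (conn in c(6L, 18L, 26L)) {
      oracle <- flood_fill_oracle(vol, conn)
      got <- punctaseg:::cpp_label_components(vol, conn)
      expect_identical(canonical_partition(got), canonical_partition(oracle))
      ps <- extract_puncta(vol, zero_img(d), connectivity = conn)
      expect_identical(nrow(ps$df), max(oracle))
    }
  }
})

test_that("corner-sharing voxels split by connectivity", {
  vol <- array(FALSE, c(3, 3, 3))
  vol[1, 1, 1] <- TRUE
  vol[2, 2, 2] <- TRUE
  img <- vol_image(array(0, c(3, 3, 3)))
  expect_identical(nrow(extract_puncta(vol, img, 26L)$df), 1L)
  expect_identical(nrow(extract_puncta(vol, img, 18L)$df), 2L)
  expect_identical(nrow(extract_puncta(vol, img, 6L)$df), 2L)
})

test_that("puncta partition the positive voxels and conserve volume", {
  s <- generate_sample(tiny_spec(seed = 31L))
  ps <- extract_puncta(s$synapse_truth, s$image)
  expect_identical(sum(ps$df$voxel_count), sum(s$synapse_truth))
  allvox <- do.call(rbind, ps$voxels)
  expect_identical(nrow(allvox), nrow(unique(allvox)))  # pairwise disjoint
  expect_equal(sum(ps$df$volume_um3),
               sum(s$synapse_truth) * prod(s$image$spacing))
})

test_that("summary arithmetic: components of 3 and 5 voxels", {
  vol <- array(FALSE, c(3, 10, 10))
  vol[2, 2, 2:4] <- TRUE   # 3 voxels
  vol[2, 7, 3:7] <- TRUE   # 5 voxels
  ps <- extract_puncta(vol, vol_image(array(1, c(3, 10, 10))))
  s <- summarize_image(ps)
  expect_equal(s$puncta_count, 2)
  expect_equal(s$total_volume, 8)
  expect_equal(s$mean_volume, 4)
})

test_that("SWC arc lengths, degenerate trees, and malformed files", {
  sk <- straight_skeleton(11L)  # 11 collinear nodes 1 um apart
  expect_equal(sk$total_length, 10)
  expect_equal(sk$arc_length, 0:10)

  single <- skeleton_from_nodes(cbind(1, 1, 1), -1L)
  expect_equal(single$total_length, 0)

  expect_error(skeleton_from_nodes(cbind(c(1, 1), c(1, 2), c(1, 2)),
                                   c(-1L, -1L)), "roots")
  expect_error(skeleton_from_nodes(cbind(c(1, 1, 1), c(1, 2, 3), c(1, 2, 3)),
                                   c(-1L, 3L, 2L)), "disconnected or cyclic")

  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(sk, f)
  back <- load_skeleton(f)
  expect_equal(back$arc_length, sk$arc_length, tolerance = 1e-9)
  expect_identical(back$soma_id, 1L)
})

test_that("centroids map to the nearest node with soma-ward ties", {
  sk <- straight_skeleton(11L)  # nodes at x = 1..11 um, arc 0..10
  img <- vol_image(array(1, c(3, 5, 12)))
  # single voxel 1 um lateral of the node with arc length 3 (x = 4)
  pred <- array(FALSE, c(3, 5, 12)); pred[2, 3, 4] <- TRUE
  mp <- map_puncta_to_skeleton(extract_puncta(pred, img), sk)
  expect_equal(mp$df$position_norm, 0.3)

  # soma and furthest-terminal endpoints hit exactly 0 and 1
  ends <- array(FALSE, c(3, 5, 12)); ends[2, 2, 1] <- TRUE; ends[2, 2, 11] <- TRUE
  me <- map_puncta_to_skeleton(extract_puncta(ends, img), sk)
  expect_equal(sort(me$df$position_norm), c(0, 1))

  # centroid equidistant between arcs 4 and 5 resolves toward the soma
  tie <- array(FALSE, c(3, 5, 12)); tie[2, 2, 5:6] <- TRUE  # centroid x = 5.5
  mt <- map_puncta_to_skeleton(extract_puncta(tie, img), sk)
  expect_identical(mt$df$skeleton_node_id, 5L)
})

test_that("per-voxel mode spreads a straddling punctum over both nodes", {
  sk <- straight_skeleton(11L)
  img <- vol_image(array(1, c(3, 5, 12)))
  pred <- array(FALSE, c(3, 5, 12)); pred[2, 2, 5:6] <- TRUE
  mv <- map_puncta_to_skeleton(extract_puncta(pred, img), sk, mode = "per_voxel")
  s <- attr(mv, "position_samples")
  expect_identical(nrow(s), 2L)
  expect_identical(sort(s$node_id), c(5L, 6L))
  expect_equal(s$weight, c(1, 1))
})

test_that("density normalization and scale invariance", {
  sk <- straight_skeleton(11L)
  img <- vol_image(array(1, c(3, 5, 12)))
  mid <- array(FALSE, c(3, 5, 12)); mid[2, 2, 6] <- TRUE  # arc 5 -> position 0.5
  prof <- puncta_positions(map_puncta_to_skeleton(extract_puncta(mid, img), sk))
  d1 <- population_density(list(prof), n_bins = 10L)
  expect_equal(max(d1$density), 10)
  expect_equal(sum(d1$density > 0), 1L)
  d2 <- population_density(list(prof, prof), n_bins = 10L)
  expect_equal(d2$density, d1$density)  # identical worms change nothing

  set.seed(11)
  rnd <- structure(list(position = runif(40), weight = sample(1:5, 40, TRUE),
                        mode = "entire_neurite"), class = "distribution_profile")
  dd <- population_density(list(rnd), n_bins = 13L)
  expect_lt(abs(sum(dd$density) * (1 / 13) - 1), 1e-9)
})

test_that("synapse-domain rescaling pins the occupied extremes to 0 and 1", {
  sk <- straight_skeleton(11L)
  img <- vol_image(array(1, c(3, 5, 12)))
  pred <- array(FALSE, c(3, 5, 12)); pred[2, 2, c(3, 6, 9)] <- TRUE
  mp <- map_puncta_to_skeleton(extract_puncta(pred, img), sk)
  prof <- puncta_positions(mp, mode = "synapse_domain")
  expect_equal(min(prof$position), 0)
  expect_equal(max(prof$position), 1)
})

test_that("domain summaries: span, densities, and degenerate cases", {
  sk <- straight_skeleton(11L)
  img <- vol_image(array(1, c(3, 5, 12)))
  # 5 separate puncta spanning arcs 2..7 um -> domain 5 um, density 1 per um
  pred <- array(FALSE, c(3, 5, 12))
  pred[cbind(2, c(2, 4, 2, 4, 2), c(3, 4, 5, 6, 8))] <- TRUE
  mp <- map_puncta_to_skeleton(extract_puncta(pred, img), sk)
  s <- summarize_image(mp)
  expect_equal(s$domain_length, 5)
  expect_equal(s$count_density, 1)

  one <- array(FALSE, c(3, 5, 12)); one[2, 2, 6] <- TRUE
  s1 <- summarize_image(map_puncta_to_skeleton(extract_puncta(one, img), sk))
  expect_equal(s1$domain_length, 0)
  expect_true(is.na(s1$count_density))
  expect_true(is.na(s1$volume_density))

  s0 <- summarize_image(extract_puncta(array(FALSE, c(3, 5, 12)), img))
  expect_equal(s0$puncta_count, 0)
  expect_equal(s0$total_volume, 0)
})

test_that("the tube skeletonizer recovers arc length of a synthetic tube", {
  s <- generate_sample(tiny_spec(seed = 33L))
  sk <- skeletonize_tube(s$neurite_truth, s$image$spacing)
  expect_gt(sk$total_length, 0.8 * s$skeleton_truth$total_length)
  expect_lt(sk$total_length, 1.2 * s$skeleton_truth$total_length)
})
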