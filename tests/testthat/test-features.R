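test_that("a constant image has exactly zero derivative features", {
  img <- vol_image(array(5, c(6, 12, 12)))
  X <- compute_features(img)
  expect_identical(unname(colnames(X)),
                   paste0("syn_", feature_bank()$feature_names))
  expect_true(all(X[, "syn_raw"] == 5))
  for (f in c("syn_sobel", "syn_dog_1_2", "syn_dog_2_4", "syn_log_1",
              "syn_log_2", "syn_sd3"))
    expect_true(all(abs(X[, f]) < 1e-10), info = f)
  expect_true(all(X[, "syn_mean3"] == 5))
  expect_true(all(X[, "syn_erosion"] == 5))
})

test_that("LoG response at a single bright voxel is negative and extremal", {
  vol <- array(0, c(9, 15, 15))
  vol[5, 8, 8] <- 100
  X <- compute_features(vol_image(vol))
  log1 <- array(X[, "syn_log_1"], c(9, 15, 15))
  nb <- log1[5, 6:10, 6:10]  # 5x5 in-plane neighborhood
  expect_lt(log1[5, 8, 8], 0)
  expect_identical(which.min(nb), 13L)  # the center is the minimum
})

test_that("feature vector length is 9 per channel", {
  one <- vol_image(array(runif(4 * 8 * 8), c(4, 8, 8)))
  two <- vol_image(one$synapse, one$synapse * 2)
  px <- cbind(z = c(1, 3), y = c(2, 5), x = c(2, 7))
  expect_identical(ncol(compute_features(one, px)), 9L)
  expect_identical(ncol(compute_features(two, px)), 18L)
  expect_error(compute_features(one, cbind(5, 1, 1)), "out of bounds")
})

test_that("the standard scaler centers and scales the training pixels", {
  set.seed(3)
  X <- cbind(rnorm(500, 10, 4), runif(500), rep(2, 500))  # one constant column
  sc <- fit_scaler(X)
  Z <- apply_scaler(sc, X)
  expect_true(all(abs(colMeans(Z)) < 1e-8))
  pop_sd <- apply(Z[, 1:2], 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_true(all(abs(pop_sd - 1) < 1e-8))
  expect_true(all(Z[, 3] == 0))  # constant feature centered, not scaled
})
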