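test_that("patch side is twice the root mean connected-label area", {
  lab <- array(FALSE, c(4, 40, 40))
  lab[1, 5:7, 5:7] <- TRUE      # area 9
  lab[3, 20:23, 20:23] <- TRUE  # area 16
  expect_identical(compute_patch_side(lab), 7L)  # 2 * sqrt(12.5) -> 7

  lab2 <- array(FALSE, c(2, 40, 40))
  lab2[1, 10:14, 10:14] <- TRUE  # area 25
  expect_identical(compute_patch_side(lab2), 10L)

  expect_error(compute_patch_side(array(FALSE, c(2, 8, 8))), "no positive")
})

test_that("every positive pixel lies in some kept patch", {
  set.seed(4)
  for (i in 1:5) {
    lab <- array(runif(3 * 30 * 30) < 0.05, c(3, 30, 30))
    if (!any(lab)) next
    plan <- patch_plan(lab, sample(3:9, 1))
    covered <- array(FALSE, dim(lab))
    covered[punctaseg:::plan_pixel_indices(plan)] <- TRUE
    expect_true(all(covered[lab]))
  }
})

test_that("hard-negative mining only grows the training set", {
  s <- generate_sample(tiny_spec(seed = 11L))
  l1 <- train_layer1(syn_only(s), s$synapse_truth, seed = 1L, tune = FALSE)
  expect_gte(l1$n_step2, l1$n_step1)
  # literal false-negative harvesting also never shrinks it
  l1b <- train_layer1(syn_only(s), s$synapse_truth, seed = 1L, tune = FALSE,
                      harvest = "false_negative")
  expect_gte(l1b$n_step2, l1b$n_step1)
})

test_that("layer 2 consumes layer-1 dimension plus six neighbor probabilities", {
  s <- generate_sample(tiny_spec(seed = 12L))
  m <- cached("tiny_model_12", train_synapse_model(
    syn_only(s), s$synapse_truth, seed = 1L, tune = FALSE))
  expect_identical(m$layer2$classifier$n_features,
                   m$layer1$classifier$n_features + 6L)
})

test_that("border pixels inherit the center probability for missing neighbors", {
  d <- c(4L, 6L, 6L)
  idx <- punctaseg:::coords_to_index(cbind(1, 1, 1), d)
  nb <- punctaseg:::neighbor_indices(idx, d)
  # z-1, y-1, x-1 fall outside and collapse onto the center pixel
  expect_identical(nb[1, c(1, 3, 5)], rep(idx, 3))
  expect_false(any(nb[1, c(2, 4, 6)] == idx))
})

test_that("a supplied mask strictly bounds the prediction", {
  s <- generate_sample(tiny_spec(seed = 12L))
  m <- cached("tiny_model_12", train_synapse_model(
    syn_only(s), s$synapse_truth, seed = 1L, tune = FALSE))
  sp2 <- tiny_spec(seed = 13L)
  s2 <- generate_sample(sp2)
  mask <- roi_mask(s2)
  pred <- segment_synapses(m, syn_only(s2), mask = mask)
  expect_false(any(punctaseg:::as_mask(pred) & !mask))
  # an empty mask yields an empty prediction
  empty <- segment_synapses(m, syn_only(s2), mask = array(FALSE, dim(mask)))
  expect_false(any(empty))
  # mismatched shapes are rejected
  expect_error(segment_synapses(m, syn_only(s2), mask = array(TRUE, c(2, 2, 2))),
               "shapes")
})

test_that("segmentation is deterministic under a fixed seed", {
  s <- generate_sample(tiny_spec(seed = 14L))
  s2 <- generate_sample(tiny_spec(seed = 15L))
  ma <- train_synapse_model(syn_only(s), s$synapse_truth, seed = 5L, tune = FALSE)
  mb <- train_synapse_model(syn_only(s), s$synapse_truth, seed = 5L, tune = FALSE)
  pa <- segment_synapses(ma, syn_only(s2), mask = roi_mask(s2))
  pb <- segment_synapses(mb, syn_only(s2), mask = roi_mask(s2))
  expect_identical(punctaseg:::as_mask(pa), punctaseg:::as_mask(pb))
})

test_that("label edits apply, invert, and feed back into training", {
  s <- generate_sample(tiny_spec(seed = 16L))
  pred <- s$synapse_truth
  vx <- cbind(z = c(1, 2), y = c(1, 1), x = c(1, 2))  # empty corner voxels
  expect_false(any(pred[vx]))
  edited <- edit_labels(pred, add = vx)
  expect_identical(sum(edited), sum(pred) + 2L)
  restored <- edit_labels(edited, remove = vx)
  expect_identical(punctaseg:::as_mask(restored), punctaseg:::as_mask(pred))
  expect_identical(punctaseg:::as_mask(edit_labels(pred)),
                   punctaseg:::as_mask(pred))
  expect_error(edit_labels(pred, add = cbind(99, 1, 1)), "out of bounds")
  # corrected labels are valid training input
  expect_s3_class(train_layer1(syn_only(s), edited, seed = 1L, tune = FALSE),
                  "synapse_layer1")
})

test_that("SVM and MLP families fit and predict through the same surface", {
  set.seed(6)
  X <- rbind(matrix(rnorm(200, 0), 100), matrix(rnorm(200, 3), 100))
  y <- rep(c(FALSE, TRUE), each = 100)
  for (fam in c("svm", "mlp")) {
    clf <- punctaseg:::fit_pixel_classifier(X, y, fam,
                                            punctaseg:::default_params(fam), 1L)
    pr <- punctaseg:::predict_pixel_prob(clf, X)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_gt(punctaseg:::f1_score(pr >= 0.5, y), 0.9)
  }
})

test_that("grid search returns a row of the grid with CV scores", {
  set.seed(7)
  X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 2.5), 50))
  y <- rep(c(FALSE, TRUE), each = 50)
  tuned <- punctaseg:::tune_pixel_classifier(X, y, "random_forest", seed = 1L)
  expect_true(tuned$params$num.trees %in% c(100L, 300L))
  expect_true(tuned$params$max.depth %in% c(0L, 16L))
  expect_identical(nrow(tuned$cv), 4L)
  expect_true(all(tuned$cv$f1 >= 0 & tuned$cv$f1 <= 1))
})
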