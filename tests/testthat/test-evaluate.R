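test_that("IoU on the enumerated toy cases", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE       # 8 voxels
  expect_equal(compute_iou(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[3:4, 3:4, 3:4] <- TRUE
  expect_equal(compute_iou(a, b), 0)
  # two 8-voxel cubes sharing a 4-voxel face column
  c2 <- array(FALSE, c(4, 4, 4)); c2[1:2, 1:2, 2:3] <- TRUE
  expect_equal(compute_iou(a, c2), 4 / 12)
  expect_equal(compute_iou(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
  expect_error(compute_iou(a, array(FALSE, c(2, 2, 2))), "shapes")
})

test_that("IoU is symmetric and bounded by precision and recall", {
  set.seed(20)
  for (i in 1:10) {
    p <- array(runif(4 * 6 * 6) < 0.4, c(4, 6, 6))
    t <- array(runif(4 * 6 * 6) < 0.4, c(4, 6, 6))
    expect_equal(compute_iou(p, t), compute_iou(t, p))
    s <- segmentation_score(p, t)
    expect_equal(s$iou, compute_iou(p, t))
    expect_lte(s$iou, min(s$precision, s$recall) + 1e-12)
    if (s$precision + s$recall > 0)
      expect_equal(s$f1, 2 * s$precision * s$recall / (s$precision + s$recall))
  }
})

test_that("inter-annotator agreement matrix and benchmark", {
  s <- generate_sample(tiny_spec(seed = 41L))
  truth <- truth_mask(s)
  same <- compare_annotators(list(truth, truth, truth))
  expect_true(all(same$iou_matrix == 1))
  expect_equal(same$benchmark, 1)

  ann <- list(a = truth,
              b = punctaseg:::cpp_dilate_binary(truth, 1L, FALSE),
              c = punctaseg:::cpp_dilate_binary(truth, 2L, FALSE))
  res <- compare_annotators(ann)
  expect_equal(diag(res$iou_matrix), c(a = 1, b = 1, c = 1))
  expect_equal(res$iou_matrix, t(res$iou_matrix))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(res$iou_matrix[i, j], compute_iou(ann[[i]], ann[[j]]))
  expect_equal(res$benchmark, mean(res$iou_matrix[upper.tri(res$iou_matrix)]))

  two <- compare_annotators(ann[1:2])
  expect_equal(two$benchmark, compute_iou(ann$a, ann$b))
  expect_error(compare_annotators(ann[1]), "two annotators")
})

test_that("training-size benchmark validates sizes and reports all combinations", {
  ds <- lapply(51:53, function(sd) generate_sample(tiny_spec(seed = sd)))
  expect_error(benchmark_training_size(ds, sizes = 3L), "size")
  tab <- benchmark_training_size(ds, sizes = c(1L, 2L), seed = 1L)
  expect_identical(tab$size, c(1L, 2L))
  expect_identical(tab$n_combos, c(3L, 3L))
  expect_true(all(tab$iou_mean >= 0 & tab$iou_mean <= 1))
  # size = dataset - 1 leaves exactly one hold-out per combination
  expect_false(anyNA(tab$iou_mean))
})
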