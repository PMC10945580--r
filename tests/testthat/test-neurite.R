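test_that("chunk extraction enumerates slice x tile positions with reflect padding", {
  vol <- array(runif(10 * 64 * 64), c(10, 64, 64))
  ch <- extract_chunks(vol, tile = c(64L, 64L))
  expect_length(ch, 10L)
  expect_identical(dim(ch[[1]]$data), c(7L, 64L, 64L))
  # z = 1 chunk reflects slices (3, 2, 1) above itself: depth order 4,3,2,1,2,3,4
  expect_identical(ch[[1]]$data[1, , ], vol[4, , ])
  expect_identical(ch[[1]]$data[4, , ], vol[1, , ])
  expect_identical(ch[[1]]$data[7, , ], vol[4, , ])
})

test_that("a single-slice stack reflects into a uniform 7-slice chunk", {
  vol <- array(runif(1 * 32 * 32), c(1, 32, 32))
  ch <- extract_chunks(vol, tile = c(32L, 32L))
  expect_length(ch, 1L)
  for (k in 1:7) expect_identical(ch[[1]]$data[k, , ], vol[1, , ])
})

test_that("a 300x300 frame tiles into 4 overlapping tiles at stride 200", {
  vol <- array(0, c(2, 300, 300))
  ch <- extract_chunks(vol, tile = c(256L, 256L), stride = 200L)
  expect_length(ch, 2L * 4L)
  pos <- unique(t(sapply(ch, function(c) c(c$y0, c$x0))))
  expect_identical(sort(unique(pos[, 1])), c(1L, 45L))
  # ownership ranges partition every axis position exactly once
  own <- punctaseg:::own_ranges(c(1L, 45L), 256L, 300L)
  covered <- unlist(apply(own, 1, function(r) r[1]:r[2]))
  expect_identical(sort(covered), 1:300)
})

test_that("patch sampling filters blanks and errors on all-blank stacks", {
  vol <- array(10, c(6, 48, 48))
  lab <- array(FALSE, c(6, 48, 48)); lab[3, 10, 10] <- TRUE
  set.seed(1)
  p <- sample_training_patches(vol, lab, n = 20L, blank_threshold = 0,
                               tile = c(32L, 32L))
  expect_length(p, 20L)
  expect_identical(dim(p[[1]]$chunk), c(7L, 32L, 32L))
  expect_identical(dim(p[[1]]$label), c(32L, 32L))
  expect_error(sample_training_patches(array(0, c(4, 32, 32)),
                                       array(FALSE, c(4, 32, 32)),
                                       n = 5L, blank_threshold = 1,
                                       tile = c(16L, 16L)),
               "blank_threshold")
  expect_error(sample_training_patches(vol, array(FALSE, c(6, 48, 40)), n = 2L),
               "shapes")
})

test_that("soft IoU loss is bounded and vanishes at a perfect prediction", {
  set.seed(2)
  for (i in 1:10) {
    p <- runif(50)
    t <- rbinom(50, 1, 0.4)
    l <- soft_iou_loss(p, t)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  t <- rbinom(100, 1, 0.3)
  expect_equal(soft_iou_loss(t, t), 0)
  expect_equal(soft_iou_loss(rep(0, 10), rep(0, 10)), 0)  # perfect absence
})

test_that("analytic U-Net gradients match finite differences", {
  cfg <- unet_config(levels = 2L, base = 4L, tile = c(8L, 8L), seed = 0L)
  set.seed(5)
  w <- punctaseg:::unet_init_weights(cfg)
  x <- array(rnorm(7 * 8 * 8), c(7, 8, 8))
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  g <- punctaseg:::cpp_unet_grad_batch(w, cfg, list(x), list(y))
  lossfun <- function(wm) punctaseg:::cpp_unet_grad_batch(wm, cfg, list(x), list(y))$loss
  for (nm in c("enc0_c1_W", "bot_c2_W", "dec0_c2_W", "out_W", "out_b")) {
    j <- sample(length(w[[nm]]), 1)
    h <- 1e-6
    wp <- w; wp[[nm]][j] <- wp[[nm]][j] + h
    wm <- w; wm[[nm]][j] <- wm[[nm]][j] - h
    num <- (lossfun(wp) - lossfun(wm)) / (2 * h)
    ana <- g$grads[[nm]][j]
    expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
  }
})

test_that("training is deterministic and stitching covers the whole volume", {
  ds <- lapply(21:22, function(sd) generate_sample(tiny_spec(seed = sd)))
  cfg <- unet_config(levels = 2L, base = 4L, tile = c(32L, 32L), epochs = 3L,
                     patience = 3L, batch_size = 4L, patches_per_image = 4L,
                     seed = 9L)
  m1 <- train_neurite_model(ds, config = cfg)
  m2 <- train_neurite_model(ds, config = cfg)
  expect_identical(m1$weights, m2$weights)
  expect_true(all(is.finite(m1$history$train_loss)))
  prob <- predict_neurite_prob(m1, ds[[1]]$image)
  expect_identical(dim(prob), dim(ds[[1]]$image$synapse))
  expect_false(anyNA(prob))            # every voxel predicted exactly once
  expect_true(all(prob >= 0 & prob <= 1))
  # an impossible threshold empties the mask
  expect_false(any(segment_neurites(m1, ds[[1]]$image, threshold = 1 + 1e-9)))
})

test_that("soma removal excises the thick sphere and keeps the thin tube", {
  d <- c(13L, 40L, 80L)
  tube <- punctaseg:::cpp_stamp_balls(d, cbind(6, 19, 0:79), 2)
  sphere <- punctaseg:::cpp_stamp_balls(d, cbind(6, 19, 60), 6)
  phantom <- tube | sphere
  out <- punctaseg:::remove_soma_regions(phantom, soma_diameter = 8)
  # the sphere interior is gone, most of the tube survives
  expect_lt(sum(out & sphere & !tube), 0.1 * sum(sphere & !tube))
  tube_far <- tube; tube_far[, , 45:80] <- FALSE  # away from the sphere
  expect_gt(sum(out & tube_far) / sum(tube_far), 0.9)
})
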