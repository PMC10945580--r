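# Neurite masking with a 2.5D U-Net: a 7-slice chunk of the cytoplasmic
# channel enters as input channels of a 2D encoder-decoder and the center
# slice is predicted. Training minimizes L = L_IoU + L_CE with Adam;
# inference tiles the frame laterally and stitches so that every pixel is
# predicted exactly once.

#' U-Net training and architecture configuration
#'
#' @param levels Resolution levels of the encoder-decoder (4 by default,
#'   giving feature widths `base * 2^(0..levels-1)`).
#' @param base Feature maps at the top level (default 16, so 16 to 128).
#' @param tile Lateral tile `(H, W)`; each dimension must be divisible by
#'   `2^(levels-1)`.
#' @param depth Chunk depth in slices (the center slice is predicted).
#' @param lr Adam learning rate.
#' @param epochs Maximum epochs; training usually converges well before.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param batch_size Chunks per gradient step.
#' @param augment Random flip / 90-degree-rotation augmentation per epoch?
#' @param patches_per_image Random 3D patches drawn per training stack.
#' @param blank_threshold Mean-intensity threshold below which a sampled
#'   patch is discarded as blank background.
#' @param seed Seed fixing initialization, sampling and augmentation.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(levels = 4L, base = 16L, tile = c(256L, 256L),
                        depth = 7L, lr = 0.001, epochs = 200L, patience = 20L,
                        batch_size = 8L, augment = TRUE,
                        patches_per_image = 200L, blank_threshold = 0,
                        seed = 0L) {
  if (levels < 2L) stop("'levels' must be >= 2")
  div <- 2L^(levels - 1L)
  if (any(tile %% div != 0L))
    stop("tile dimensions must be divisible by 2^(levels-1) = ", div)
  if (depth %% 2L != 1L) stop("'depth' must be odd (a center slice is predicted)")
  structure(list(levels = as.integer(levels), base = as.integer(base),
                 in_ch = as.integer(depth), tile = as.integer(tile),
                 depth = as.integer(depth), lr = lr,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 batch_size = as.integer(batch_size), augment = augment,
                 patches_per_image = as.integer(patches_per_image),
                 blank_threshold = blank_threshold, seed = as.integer(seed),
                 iou_eps = 1e-6),
            class = "unet_config")
}

unet_conv_specs <- function(config) {
  L <- config$levels; base <- config$base; in_ch <- config$in_ch
  sp <- list()
  add <- function(n, cin, cout, k) sp[[length(sp) + 1L]] <<-
    list(name = n, cin = cin, cout = cout, k = k)
  for (i in 0:(L - 2)) {
    ci <- bitwShiftL(base, i)
    add(sprintf("enc%d_c1", i), if (i == 0) in_ch else bitwShiftL(base, i - 1), ci, 3L)
    add(sprintf("enc%d_c2", i), ci, ci, 3L)
  }
  cb <- bitwShiftL(base, L - 1)
  add("bot_c1", bitwShiftL(base, L - 2), cb, 3L)
  add("bot_c2", cb, cb, 3L)
  for (i in (L - 2):0) {
    ci <- bitwShiftL(base, i)
    add(sprintf("up%d", i), ci * 2L, ci, 3L)
    add(sprintf("dec%d_c1", i), ci * 2L, ci, 3L)
    add(sprintf("dec%d_c2", i), ci, ci, 3L)
  }
  add("out", base, 1L, 1L)
  sp
}

# He-normal initialization, drawn from the R RNG for reproducibility
unet_init_weights <- function(config) {
  w <- list()
  for (s in unet_conv_specs(config)) {
    fan <- s$cin * s$k^2
    w[[paste0(s$name, "_W")]] <- matrix(rnorm(s$cout * fan, sd = sqrt(2 / fan)),
                                        s$cout, fan)
    w[[paste0(s$name, "_b")]] <- rep(0, s$cout)
  }
  w
}

standardize_chunk <- function(x) {
  s <- sd(x)
  (x - mean(x)) / max(s, 1e-6)
}

# lateral tile origins so the union of tiles covers 1..n
tile_positions <- function(n, tile, stride = tile) {
  if (n <= tile) return(1L)
  p <- seq(1L, n - tile + 1L, by = stride)
  if (p[length(p)] != n - tile + 1L) p <- c(p, n - tile + 1L)
  as.integer(p)
}

# ownership cut points: pixel ranges each tile stitches into the output,
# chosen at overlap midpoints so every pixel is written exactly once
own_ranges <- function(pos, tile, n) {
  k <- length(pos)
  starts <- integer(k); ends <- integer(k)
  for (i in seq_len(k)) {
    starts[i] <- if (i == 1L) 1L else (pos[i] + pos[i - 1L] + tile) %/% 2L
    ends[i] <- if (i == k) n else (pos[i + 1L] + pos[i] + tile) %/% 2L - 1L
  }
  cbind(start = starts, end = ends)
}

reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

#' Extract 7-slice chunks for prediction
#'
#' One chunk per (slice, lateral tile) position: the chunk depth is padded
#' by reflection at the z-boundaries, and frames smaller than the tile are
#' reflect-padded laterally. Tiles overlap when the frame is not a tile
#' multiple; the recorded ownership ranges make the later stitch cover
#' every pixel exactly once.
#'
#' @param image [vol_image] with a cytoplasmic channel, or a 3D array.
#' @param tile Lateral `(H, W)` chunk size.
#' @param stride Lateral stride between tiles (default: the tile, i.e.
#'   non-overlapping except for the final fitted tile).
#' @param depth Chunk depth (odd).
#' @return List of chunks (`data` 3D array `depth x H x W`, `z`, `y0`,
#'   `x0`, ownership ranges), with the tiling recorded as attributes.
#' @export
extract_chunks <- function(image, tile = c(256L, 256L), stride = NULL,
                           depth = 7L) {
  vol <- as_channel(image, "cytoplasmic")
  d <- dim(vol)
  stride <- stride %||% tile
  if (length(stride) == 1L) stride <- rep(stride, 2L)
  half <- (depth - 1L) %/% 2L
  py <- tile_positions(d[2], tile[1], stride[1])
  px <- tile_positions(d[3], tile[2], stride[2])
  oy <- own_ranges(py, tile[1], d[2])
  ox <- own_ranges(px, tile[2], d[3])
  yi_all <- reflect_idx(seq_len(max(tile[1], d[2])), d[2])
  xi_all <- reflect_idx(seq_len(max(tile[2], d[3])), d[3])
  chunks <- list()
  for (z in seq_len(d[1])) {
    zi <- reflect_idx((z - half):(z + half), d[1])
    sub <- vol[zi, , , drop = FALSE]
    for (a in seq_along(py)) for (b in seq_along(px)) {
      yi <- yi_all[py[a] + seq_len(tile[1]) - 1L]
      xi <- xi_all[px[b] + seq_len(tile[2]) - 1L]
      chunks[[length(chunks) + 1L]] <- list(
        data = sub[, yi, xi, drop = FALSE], z = z, y0 = py[a], x0 = px[b],
        own_y = oy[a, ], own_x = ox[b, ])
    }
  }
  attr(chunks, "shape") <- d
  attr(chunks, "tile") <- tile
  chunks
}

#' Sample random training patches from a labeled stack
#'
#' Draws `n` random chunk positions, pairs each chunk with its center-slice
#' truth, and then discards patches whose mean intensity falls below
#' `blank_threshold` (blank background). Errors if nothing survives.
#'
#' @param image [vol_image] (cytoplasmic channel used) or 3D array.
#' @param label Logical neurite truth of matching shape.
#' @param n Patches drawn before filtering.
#' @param blank_threshold Mean-intensity cutoff.
#' @param tile Lateral patch size `(H, W)`.
#' @param depth Chunk depth.
#' @return List of `list(chunk, label)` pairs (label is the center slice).
#' @export
sample_training_patches <- function(image, label, n = 200L,
                                    blank_threshold = 0, tile = c(64L, 64L),
                                    depth = 7L) {
  vol <- as_channel(image, "cytoplasmic")
  m <- as_mask(label)
  check_same_shape(vol, m, "image and label")
  d <- dim(vol)
  half <- (depth - 1L) %/% 2L
  out <- list()
  for (i in seq_len(n)) {
    z <- sample.int(d[1], 1L)
    y0 <- if (d[2] > tile[1]) sample.int(d[2] - tile[1] + 1L, 1L) else 1L
    x0 <- if (d[3] > tile[2]) sample.int(d[3] - tile[2] + 1L, 1L) else 1L
    zi <- reflect_idx((z - half):(z + half), d[1])
    yi <- reflect_idx(y0 + seq_len(tile[1]) - 1L, d[2])
    xi <- reflect_idx(x0 + seq_len(tile[2]) - 1L, d[3])
    chunk <- vol[zi, yi, xi, drop = FALSE]
    if (mean(chunk) < blank_threshold) next
    out[[length(out) + 1L]] <- list(chunk = chunk, label = m[z, yi, xi] * 1.0)
  }
  if (length(out) == 0L)
    stop("all ", n, " sampled patches fell below blank_threshold = ",
         blank_threshold, "; lower the threshold")
  out
}

#' Soft IoU loss between a probability map and a binary target
#'
#' `1 - (sum(p*t) + eps) / (sum(p) + sum(t) - sum(p*t) + eps)`; lies in
#' `[0, 1]` and equals 0 exactly when the prediction equals the label.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param t Binary targets.
#' @param eps Stabilizer.
#' @return Scalar loss.
#' @export
soft_iou_loss <- function(p, t, eps = 1e-6) {
  i <- sum(p * t)
  u <- sum(p) + sum(t) - i
  1 - (i + eps) / (u + eps)
}

augment_patch <- function(chunk, lab) {
  if (runif(1) < 0.5) { chunk <- chunk[, dim(chunk)[2]:1, , drop = FALSE]; lab <- lab[nrow(lab):1, ] }
  if (runif(1) < 0.5) { chunk <- chunk[, , dim(chunk)[3]:1, drop = FALSE]; lab <- lab[, ncol(lab):1] }
  if (dim(chunk)[2] == dim(chunk)[3]) {
    k <- sample(0:3, 1L)
    if (k > 0) for (r in seq_len(k)) {
      chunk <- aperm(chunk, c(1, 3, 2))[, dim(chunk)[3]:1, , drop = FALSE]
      lab <- t(lab)[ncol(lab):1, , drop = FALSE]
    }
  }
  list(chunk = chunk, label = lab)
}

adam_step <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(w)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(w = w, state = state)
}

batch_loss <- function(weights, config, patches) {
  xs <- lapply(patches, function(p) standardize_chunk(p$chunk))
  ys <- lapply(patches, `[[`, "label")
  cpp_unet_grad_batch(weights, config, xs, ys)
}

# forward-only evaluation loss (no gradients), used for validation
forward_loss <- function(weights, config, patches) {
  tot <- 0
  for (p in patches) {
    pr <- cpp_unet_forward(weights, config, standardize_chunk(p$chunk))
    t <- p$label
    pc <- pmin(pmax(pr, 1e-7), 1 - 1e-7)
    ce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
    tot <- tot + ce + soft_iou_loss(pr, t, config$iou_eps)
  }
  tot / length(patches)
}

#' Train the neurite segmentation U-Net
#'
#' Samples random patches from the training stacks (blank patches
#' filtered on mean intensity), optimizes the combined IoU +
#' cross-entropy loss with Adam, applies flip/rotation augmentation each
#' epoch, and early-stops on validation loss, restoring the best
#' weights. Fully deterministic under `config$seed`.
#'
#' @param train List of samples, each `list(image, label)` (a
#'   [synthetic_sample] works directly: its cytoplasmic channel and
#'   `neurite_truth` are used).
#' @param val Optional validation samples in the same form; defaults to
#'   reusing the training patches (history then reports training loss).
#' @param config A [unet_config()].
#' @return Object of class `neurite_model`: weights, config, per-epoch
#'   loss history, best epoch, and validation metrics (accuracy overall;
#'   precision/recall/F1/IoU for the neurite class).
#' @export
train_neurite_model <- function(train, val = NULL, config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  as_pair <- function(s) {
    if (inherits(s, "synthetic_sample"))
      list(image = s$image, label = s$neurite_truth)
    else s
  }
  train <- lapply(train, as_pair)
  if (length(train) == 0L) stop("empty training set")
  val <- if (!is.null(val)) lapply(val, as_pair) else NULL
  set.seed(config$seed)
  weights <- unet_init_weights(config)
  tr_patches <- unlist(lapply(train, function(s)
    sample_training_patches(s$image, s$label, n = config$patches_per_image,
                            blank_threshold = config$blank_threshold,
                            tile = config$tile, depth = config$depth)),
    recursive = FALSE)
  va_patches <- if (!is.null(val)) unlist(lapply(val, function(s)
    sample_training_patches(s$image, s$label, n = config$patches_per_image,
                            blank_threshold = config$blank_threshold,
                            tile = config$tile, depth = config$depth)),
    recursive = FALSE) else tr_patches

  state <- list(t = 0L, m = lapply(weights, function(w) w * 0),
                v = lapply(weights, function(w) w * 0))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_loss <- Inf; best_w <- weights; best_epoch <- 0L; stall <- 0L
  nb <- max(1L, ceiling(length(tr_patches) / config$batch_size))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(tr_patches))
    ep_loss <- 0
    for (b in seq_len(nb)) {
      sel <- ord[seq((b - 1L) * config$batch_size + 1L,
                     min(b * config$batch_size, length(tr_patches)))]
      batch <- lapply(tr_patches[sel], function(p)
        if (config$augment) augment_patch(p$chunk, p$label) else p)
      res <- batch_loss(weights, config, batch)
      st <- adam_step(weights, res$grads, state, config$lr)
      weights <- st$w; state <- st$state
      ep_loss <- ep_loss + res$loss * length(sel)
    }
    ep_loss <- ep_loss / length(tr_patches)
    v_loss <- forward_loss(weights, config, va_patches)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = v_loss))
    if (v_loss < best_loss - 1e-9) {
      best_loss <- v_loss; best_w <- weights; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  metrics <- {
    pr <- unlist(lapply(va_patches, function(p)
      cpp_unet_forward(best_w, config, standardize_chunk(p$chunk))))
    tr <- unlist(lapply(va_patches, `[[`, "label")) > 0.5
    pb <- pr >= 0.5
    tp <- sum(pb & tr); fp <- sum(pb & !tr); fn <- sum(!pb & tr)
    data.frame(accuracy = mean(pb == tr),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA,
               f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA,
               iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA)
  }
  structure(list(weights = best_w, config = config, history = history,
                 best_epoch = best_epoch, val_metrics = metrics),
            class = "neurite_model")
}

#' @export
print.neurite_model <- function(x, ...) {
  cat(sprintf("<neurite_model> %d levels x %d base, tile %s, best epoch %d (val loss %.4f)\n",
              x$config$levels, x$config$base,
              paste(x$config$tile, collapse = "x"), x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' Predict a neurite probability volume
#'
#' Runs the model over all chunks and stitches tiles by their ownership
#' ranges, so the output has the input's shape and each voxel is
#' predicted exactly once.
#'
#' @param model A [train_neurite_model()] result.
#' @param image [vol_image] with a cytoplasmic channel, or 3D array.
#' @return Numeric probability volume in `[0, 1]`.
#' @export
predict_neurite_prob <- function(model, image) {
  stopifnot(inherits(model, "neurite_model"))
  cfg <- model$config
  chunks <- extract_chunks(image, tile = cfg$tile, depth = cfg$depth)
  d <- attr(chunks, "shape")
  prob <- array(NA_real_, d)
  for (ch in chunks) {
    p <- cpp_unet_forward(model$weights, cfg, standardize_chunk(ch$data))
    ys <- ch$own_y[1]:ch$own_y[2]
    xs <- ch$own_x[1]:ch$own_x[2]
    prob[ch$z, ys, xs] <- p[ys - ch$y0 + 1L, xs - ch$x0 + 1L]
  }
  prob
}

#' Segment neurites with a trained model
#'
#' Thresholds the stitched probability map; optionally removes somata by
#' excising mask regions whose in-plane thickness exceeds
#' `soma_diameter` (found by iterated in-plane erosion and re-dilation),
#' so that soma-localized puncta are excluded downstream.
#'
#' @param model A [train_neurite_model()] result.
#' @param image [vol_image] or 3D cytoplasmic array.
#' @param threshold Probability cutoff (default 0.5).
#' @param remove_somata Excise thick cell-body regions?
#' @param soma_diameter In-plane diameter (pixels) above which a region
#'   counts as a soma.
#' @return Logical [label_volume] of kind `neurite_mask`.
#' @export
segment_neurites <- function(model, image, threshold = 0.5,
                             remove_somata = FALSE, soma_diameter = 9) {
  prob <- predict_neurite_prob(model, image)
  mask <- prob >= threshold
  if (remove_somata) mask <- remove_soma_regions(mask, soma_diameter)
  label_volume(mask, "neurite_mask")
}

# Excise regions whose in-plane thickness exceeds soma_diameter: iterated
# in-plane erosion leaves only soma cores, which are re-dilated within the
# mask and removed. Thin tubes vanish under the erosion and survive.
remove_soma_regions <- function(mask, soma_diameter) {
  m <- as_mask(mask)
  if (!any(m)) return(m)
  e <- max(1L, floor(soma_diameter / 2))
  core <- cpp_erode_binary(m, e, TRUE)
  if (any(core)) {
    soma <- cpp_dilate_binary(core, e + 1L, FALSE) & m
    m <- m & !soma
  }
  m
}
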