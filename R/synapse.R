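# Two-layer pixel classification of synaptic puncta. Layer 1 is trained on
# all positive pixels plus negatives sampled near them, then retrained after
# harvesting hard negatives from larger patches; layer 2 extends the feature
# vector with the layer-1 probabilities of the six face neighbors.

# feature volumes computed once per image and indexed repeatedly
feature_volumes <- function(image, bank = feature_bank()) {
  syn <- as_channel(image, "synapse")
  chans <- list(syn = syn)
  if (inherits(image, "vol_image") && !is.null(image$cytoplasmic))
    chans$cyto <- image$cytoplasmic
  out <- list()
  for (cn in names(chans)) {
    fv <- channel_features(chans[[cn]], bank)
    for (fn in names(fv)) out[[paste(cn, fn, sep = "_")]] <- fv[[fn]]
  }
  attr(out, "dim3") <- dim(syn)
  out
}

features_at <- function(fvols, idx) {
  X <- vapply(fvols, function(v) v[idx], numeric(length(idx)))
  if (length(idx) == 1L) X <- matrix(X, 1L, dimnames = list(NULL, names(fvols)))
  X
}

#' Patch side from the labeled puncta
#'
#' The training patch side is twice the square root of the mean area of
#' the 2D connected label components (per slice), with a floor of 3.
#'
#' @param label Logical 3D array of positive pixels.
#' @return Integer patch side in pixels.
#' @export
compute_patch_side <- function(label) {
  m <- as_mask(label)
  areas <- slice_component_areas(m)
  if (length(areas) == 0L) stop("label volume has no positive pixels")
  max(3L, as.integer(round(2 * sqrt(mean(areas)))))
}

slice_component_areas <- function(m) {
  d <- dim(m)
  areas <- integer(0)
  for (z in seq_len(d[1])) {
    sl <- array(m[z, , ], c(1L, d[2], d[3]))
    if (!any(sl)) next
    lab <- cpp_label_components(sl, 26L)  # 8-connectivity in-plane
    areas <- c(areas, tabulate(lab[lab > 0]))
  }
  areas
}

#' Plan of label-bearing patches
#'
#' Divides every slice into non-overlapping `side x side` tiles and keeps
#' those containing positive pixels, so that every positive pixel lies in
#' some kept patch.
#'
#' @param label Logical 3D array.
#' @param side Patch side in pixels (e.g. from [compute_patch_side()]).
#' @return Object of class `patch_plan`: the side and a data frame of kept
#'   tile bounds (`z, y0, x0, y1, x1`, inclusive).
#' @export
patch_plan <- function(label, side) {
  m <- as_mask(label)
  d <- dim(m)
  side <- as.integer(side)
  ys <- seq(1L, d[2], by = side)
  xs <- seq(1L, d[3], by = side)
  rows <- list()
  for (z in seq_len(d[1])) {
    if (!any(m[z, , ])) next
    for (y0 in ys) for (x0 in xs) {
      y1 <- min(y0 + side - 1L, d[2]); x1 <- min(x0 + side - 1L, d[3])
      if (any(m[z, y0:y1, x0:x1]))
        rows[[length(rows) + 1L]] <- c(z, y0, x0, y1, x1)
    }
  }
  tiles <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    as.data.frame(matrix(integer(0), 0, 5))
  names(tiles) <- c("z", "y0", "x0", "y1", "x1")
  structure(list(side = side, tiles = tiles, shape = d), class = "patch_plan")
}

plan_pixel_indices <- function(plan) {
  d <- plan$shape
  t <- plan$tiles
  if (nrow(t) == 0L) return(integer(0))
  idx <- lapply(seq_len(nrow(t)), function(i) {
    g <- expand.grid(y = t$y0[i]:t$y1[i], x = t$x0[i]:t$x1[i])
    t$z[i] + d[1] * (g$y - 1L) + d[1] * d[2] * (g$x - 1L)
  })
  as.integer(unlist(idx))
}

#' Train the first classification layer
#'
#' Step 1 trains on all positive pixels plus negatives sampled inside a
#' dilation band around them (default within 2 voxels, 3 negatives per
#' positive). Step 2 predicts over patches ten times the training patch
#' side, harvests the negatives the classifier marks positive (hard
#' negatives; set `harvest = "false_negative"` for the literal alternative),
#' and refits on the expanded set. Hyperparameters come from a grid search
#' with stratified 5-fold cross-validation unless `tune = FALSE`. The
#' standard scaler is fit on the training pixels only.
#'
#' @param images A [vol_image] or list of them.
#' @param labels Matching logical truth volume(s).
#' @param family `"random_forest"` (default), `"svm"`, or `"mlp"`.
#' @param seed Integer seed for all stochastic steps.
#' @param neg_band Dilation radius (voxels) of the near-positive band.
#' @param neg_ratio Negatives sampled per positive in step 1.
#' @param tune Grid-search hyperparameters with 5-fold CV?
#' @param grid Optional data frame overriding the default grid.
#' @param harvest Which step-2 pixels to add: `"false_positive"`
#'   (negatives predicted positive, the default) or `"false_negative"`.
#' @param bank A [feature_bank()].
#' @return Object of class `synapse_layer1` with the classifier, scaler,
#'   patch plans, and the expanded per-image training pixel sets.
#' @export
train_layer1 <- function(images, labels, family = c("random_forest", "svm", "mlp"),
                         seed = 0L, neg_band = 2L, neg_ratio = 3,
                         tune = TRUE, grid = NULL,
                         harvest = c("false_positive", "false_negative"),
                         bank = feature_bank()) {
  family <- match.arg(family)
  harvest <- match.arg(harvest)
  if (inherits(images, "vol_image") || is.array(images)) images <- list(images)
  if (is.array(labels) || inherits(labels, "label_volume")) labels <- list(labels)
  if (length(images) != length(labels)) stop("need one label per image")
  labels <- lapply(labels, as_mask)
  for (i in seq_along(images))
    check_same_shape(as_channel(images[[i]], "synapse"), labels[[i]],
                     "image and label")
  if (!any(vapply(labels, any, logical(1))))
    stop("no positive pixels in any label; cannot train")

  side <- max(3L, as.integer(round(2 * sqrt(mean(unlist(
    lapply(labels, slice_component_areas)))))))
  set.seed(seed)

  fvols <- lapply(images, feature_volumes, bank = bank)
  train_idx <- vector("list", length(images))  # linear indices per image
  train_y <- vector("list", length(images))
  for (i in seq_along(images)) {
    m <- labels[[i]]
    pos <- which(m)
    band <- which(cpp_dilate_binary(m, as.integer(neg_band), FALSE) & !m)
    n_neg <- min(length(band), ceiling(neg_ratio * length(pos)))
    neg <- if (n_neg > 0) sort(band[sample.int(length(band), n_neg)]) else integer(0)
    train_idx[[i]] <- c(pos, neg)
    train_y[[i]] <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
  }
  X1 <- do.call(rbind, lapply(seq_along(images), function(i)
    features_at(fvols[[i]], train_idx[[i]])))
  y1 <- unlist(train_y)
  n_step1 <- length(y1)

  scaler <- fit_scaler(X1)
  if (tune) {
    tuned <- tune_pixel_classifier(apply_scaler(scaler, X1), y1, family,
                                   grid = grid, seed = seed)
    params <- tuned$params
  } else {
    tuned <- NULL
    params <- default_params(family)
  }
  clf <- fit_pixel_classifier(apply_scaler(scaler, X1), y1, family, params, seed)

  # step 2: hard pixels from patches 10x the training patch side
  for (i in seq_along(images)) {
    plan10 <- patch_plan(labels[[i]], 10L * side)
    cand <- setdiff(plan_pixel_indices(plan10), train_idx[[i]])
    if (length(cand) == 0L) next
    pr <- predict_pixel_prob(clf, apply_scaler(scaler, features_at(fvols[[i]], cand)))
    truth <- labels[[i]][cand]
    keep <- if (harvest == "false_positive") (pr >= 0.5) & !truth
            else (pr < 0.5) & truth
    add <- cand[keep]
    train_idx[[i]] <- c(train_idx[[i]], add)
    train_y[[i]] <- c(train_y[[i]], truth[keep])
  }
  X2 <- do.call(rbind, lapply(seq_along(images), function(i)
    features_at(fvols[[i]], train_idx[[i]])))
  y2 <- unlist(train_y)
  scaler <- fit_scaler(X2)
  clf <- fit_pixel_classifier(apply_scaler(scaler, X2), y2, family, params, seed)

  structure(list(classifier = clf, scaler = scaler, params = params,
                 family = family, side = side, bank = bank, seed = seed,
                 tuning = tuned, harvest = harvest,
                 n_step1 = n_step1, n_step2 = length(y2),
                 train_idx = train_idx, train_y = train_y,
                 plan = patch_plan(labels[[1]], side)),
            class = "synapse_layer1")
}

# layer-1 probabilities at given linear indices of one image
layer1_prob_at <- function(layer1, fvols, idx) {
  if (length(idx) == 0L) return(numeric(0))
  predict_pixel_prob(layer1$classifier,
                     apply_scaler(layer1$scaler, features_at(fvols, idx)))
}

# six face-neighbor linear indices; out-of-volume neighbors fall back to
# the center pixel (they take its probability)
neighbor_indices <- function(idx, d) {
  co <- index_to_coords(idx, d)
  offs <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  out <- matrix(0L, length(idx), 6L)
  for (j in seq_along(offs)) {
    nc <- sweep(co, 2, offs[[j]], `+`)
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] & nc[, 2] >= 1 & nc[, 2] <= d[2] &
          nc[, 3] >= 1 & nc[, 3] <= d[3]
    ni <- idx
    if (any(ok))
      ni[ok] <- as.integer(nc[ok, 1] + d[1] * (nc[ok, 2] - 1L) +
                           d[1] * d[2] * (nc[ok, 3] - 1L))
    out[, j] <- ni
  }
  out
}

# layer-2 design matrix: scaled local features + 6 neighbor probabilities
layer2_features_at <- function(layer1, fvols, idx) {
  d <- attr(fvols, "dim3")
  nb <- neighbor_indices(idx, d)
  uniq <- unique(c(idx, as.vector(nb)))
  pr <- layer1_prob_at(layer1, fvols, uniq)
  Xl <- apply_scaler(layer1$scaler, features_at(fvols, idx))
  P <- matrix(pr[match(as.vector(nb), uniq)], nrow = length(idx))
  colnames(P) <- paste0("nbprob_", c("zm", "zp", "ym", "yp", "xm", "xp"))
  cbind(Xl, P)
}

#' Train the second classification layer
#'
#' Extends each training pixel's scaled feature vector with the layer-1
#' probabilities of its six face neighbors (`-1`/`+1` along z, y, x;
#' volume-border neighbors take the center pixel's probability) and fits a
#' classifier of the same family over the layer-1 training set.
#'
#' @inheritParams train_layer1
#' @param layer1 A fitted [train_layer1()] model.
#' @return Object of class `synapse_layer2`.
#' @export
train_layer2 <- function(images, labels, layer1, tune = TRUE, grid = NULL,
                         seed = layer1$seed) {
  stopifnot(inherits(layer1, "synapse_layer1"))
  if (inherits(images, "vol_image") || is.array(images)) images <- list(images)
  if (is.array(labels) || inherits(labels, "label_volume")) labels <- list(labels)
  fvols <- lapply(images, feature_volumes, bank = layer1$bank)
  X <- do.call(rbind, lapply(seq_along(images), function(i)
    layer2_features_at(layer1, fvols[[i]], layer1$train_idx[[i]])))
  y <- unlist(layer1$train_y)
  if (tune) {
    tuned <- tune_pixel_classifier(X, y, layer1$family, grid = grid, seed = seed)
    params <- tuned$params
  } else {
    tuned <- NULL
    params <- layer1$params
  }
  clf <- fit_pixel_classifier(X, y, layer1$family, params, seed)
  structure(list(classifier = clf, params = params, family = layer1$family,
                 tuning = tuned, seed = seed), class = "synapse_layer2")
}

#' Train the full two-layer synapse segmentation model
#'
#' Convenience wrapper running [train_layer1()] then [train_layer2()].
#'
#' @inheritParams train_layer1
#' @param ... Passed to [train_layer1()].
#' @return Object of class `two_layer_model`.
#' @export
train_synapse_model <- function(images, labels,
                                family = c("random_forest", "svm", "mlp"),
                                seed = 0L, tune = TRUE, grid = NULL, ...) {
  family <- match.arg(family)
  l1 <- train_layer1(images, labels, family = family, seed = seed,
                     tune = tune, grid = grid, ...)
  l2 <- train_layer2(images, labels, l1, tune = tune, grid = grid, seed = seed)
  structure(list(layer1 = l1, layer2 = l2, family = family, seed = seed),
            class = "two_layer_model")
}

#' @export
print.two_layer_model <- function(x, ...) {
  cat(sprintf("<two_layer_model:%s> patch side %d, %d -> %d training pixels, seed %d\n",
              x$family, x$layer1$side, x$layer1$n_step1, x$layer1$n_step2, x$seed))
  invisible(x)
}

#' Segment synaptic puncta with a trained two-layer model
#'
#' With a neurite mask, only masked pixels are predicted and everything
#' outside is background, so the prediction is always a subset of the
#' mask; without one the whole volume is scanned. Optionally attaches an
#' overlay volume (prediction outlines burned into the raw synapse
#' channel) for visual review of problematic regions.
#'
#' @param model A [train_synapse_model()] result (or a `synapse_layer1`
#'   with `layers = 1`).
#' @param image A [vol_image].
#' @param mask Optional logical neurite mask of matching shape.
#' @param threshold Probability threshold for the positive class.
#' @param layers Use the full model (2) or the first layer only (1).
#' @param overlay Attach an `"overlay"` attribute?
#' @return Logical [label_volume] of kind `synapse_prediction`.
#' @export
segment_synapses <- function(model, image, mask = NULL, threshold = 0.5,
                             layers = 2L, overlay = FALSE) {
  l1 <- if (inherits(model, "two_layer_model")) model$layer1 else model
  stopifnot(inherits(l1, "synapse_layer1"))
  syn <- as_channel(image, "synapse")
  d <- dim(syn)
  if (!is.null(mask)) {
    mask <- as_mask(mask)
    check_same_shape(syn, mask, "image and mask")
    idx <- which(mask)
  } else {
    idx <- seq_len(prod(d))
  }
  pred <- array(FALSE, d)
  if (length(idx) > 0L) {
    fvols <- feature_volumes(image, bank = l1$bank)
    if (layers >= 2L) {
      if (!inherits(model, "two_layer_model"))
        stop("a two_layer_model is required for layers = 2")
      p <- predict_pixel_prob(model$layer2$classifier,
                              layer2_features_at(l1, fvols, idx))
    } else {
      p <- layer1_prob_at(l1, fvols, idx)
    }
    pred[idx] <- p >= threshold
  }
  out <- label_volume(pred, "synapse_prediction")
  if (overlay) attr(out, "overlay") <- synapse_overlay(out, image)
  out
}

#' Overlay of prediction outlines on the raw synapse channel
#'
#' Boundary voxels of the predicted puncta are set to the image maximum so
#' problematic regions stand out during review.
#'
#' @param prediction Logical prediction volume.
#' @param image The [vol_image] it came from.
#' @return Numeric volume, raw intensities with burned-in outlines.
#' @export
synapse_overlay <- function(prediction, image) {
  syn <- as_channel(image, "synapse")
  m <- as_mask(prediction)
  check_same_shape(syn, m, "prediction and image")
  edge <- m & !cpp_erode_binary(m, 1L, FALSE)
  out <- syn
  out[edge] <- max(syn)
  out
}

#' Apply manual corrections to a label volume
#'
#' Adds and/or removes voxel sets; corrected volumes can be fed back to
#' [train_layer1()] as new training labels. Out-of-bounds edits error.
#'
#' @param volume Logical label volume.
#' @param add,remove `n x 3` matrices of 1-based `(z, y, x)` coordinates,
#'   or logical arrays of matching shape; `add` is applied first.
#' @return The corrected [label_volume].
#' @export
edit_labels <- function(volume, add = NULL, remove = NULL) {
  kind <- attr(volume, "kind") %||% "synapse_prediction"
  m <- as_mask(volume)
  d <- dim(m)
  as_idx <- function(e) {
    if (is.null(e)) return(integer(0))
    if (is.array(e) && is.logical(e)) { check_same_shape(m, e, "edit and volume"); return(which(e)) }
    coords_to_index(e, d)
  }
  m[as_idx(add)] <- TRUE
  m[as_idx(remove)] <- FALSE
  label_volume(m, kind)
}
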