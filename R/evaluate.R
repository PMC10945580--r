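#' Intersection over union of two binary volumes
#'
#' `|A and B| / |A or B|`; two empty volumes agree perfectly and score 1.
#'
#' @param pred,truth Logical volumes of the same shape.
#' @return IoU in `[0, 1]`.
#' @export
compute_iou <- function(pred, truth) {
  p <- as_mask(pred); t <- as_mask(truth)
  check_same_shape(p, t, "pred and truth")
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}

#' Full segmentation score for one class
#'
#' IoU, precision, recall, F1 and overall pixel accuracy of a binary
#' prediction against truth. Ratios with empty denominators are 0, except
#' that perfect agreement on absence scores 1 throughout.
#'
#' @param pred,truth Logical volumes of the same shape.
#' @return One-row data frame `iou, precision, recall, f1, accuracy`.
#' @export
segmentation_score <- function(pred, truth) {
  p <- as_mask(pred); t <- as_mask(truth)
  check_same_shape(p, t, "pred and truth")
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0)
    return(data.frame(iou = 1, precision = 1, recall = 1, f1 = 1, accuracy = 1))
  data.frame(iou = tp / (tp + fp + fn),
             precision = if (tp + fp > 0) tp / (tp + fp) else 0,
             recall = if (tp + fn > 0) tp / (tp + fn) else 0,
             f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
             accuracy = mean(p == t))
}

#' Inter-annotator agreement matrix
#'
#' Pairwise IoU between the label sets of k annotators of the same
#' images; the mean off-diagonal IoU is the benchmark agreement figure.
#'
#' @param label_sets List (length >= 2) of label volumes, or of lists of
#'   label volumes (one per image; pairwise IoU is then computed on the
#'   pooled voxels of each annotator pair).
#' @return List with the symmetric `iou_matrix` (diagonal 1) and the
#'   scalar `benchmark` (mean off-diagonal IoU).
#' @export
compare_annotators <- function(label_sets) {
  k <- length(label_sets)
  if (k < 2L) stop("need labels from at least two annotators")
  as_list <- function(a) if (is.list(a) && !is.array(a)) a else list(a)
  sets <- lapply(label_sets, function(a) lapply(as_list(a), as_mask))
  n_img <- unique(vapply(sets, length, integer(1)))
  if (length(n_img) > 1L) stop("annotators labeled different numbers of images")
  M <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    inter <- 0; uni <- 0
    for (m in seq_len(n_img)) {
      check_same_shape(sets[[i]][[m]], sets[[j]][[m]], "annotator labels")
      inter <- inter + sum(sets[[i]][[m]] & sets[[j]][[m]])
      uni <- uni + sum(sets[[i]][[m]] | sets[[j]][[m]])
    }
    M[i, j] <- M[j, i] <- if (uni == 0) 1 else inter / uni
  }
  nm <- names(label_sets) %||% paste0("annotator", seq_len(k))
  dimnames(M) <- list(nm, nm)
  list(iou_matrix = M, benchmark = mean(M[upper.tri(M)]))
}

#' IoU as a function of training-set size
#'
#' For each requested size, trains a two-layer synapse model on every
#' combination of that many dataset images (or a seeded subsample when
#' combinations exceed `cap`), scores the held-out images, and
#' aggregates. IoU is computed per held-out image then averaged (the
#' pooled-voxel variant is reported alongside). Predictions are
#' restricted to the dilated true neurite mask, mirroring the masked
#' pipeline.
#'
#' @param dataset List of [synthetic_sample]s (or `list(image, label,
#'   mask)` triples).
#' @param sizes Training-set sizes, all `< length(dataset)`.
#' @param cap Maximum combinations evaluated per size.
#' @param seed Seed for combination subsampling and training.
#' @param tune Grid-search hyperparameters per training run? Defaults to
#'   `FALSE` so that hyperparameters stay constant across sizes.
#' @param ... Passed to [train_synapse_model()].
#' @return Data frame: `size, n_combos, iou_mean, iou_sd, iou_pooled_mean`.
#' @export
benchmark_training_size <- function(dataset, sizes, cap = 50L, seed = 0L,
                                    tune = FALSE, ...) {
  n <- length(dataset)
  if (any(sizes >= n)) stop("every size must be < dataset size ", n)
  as_triple <- function(s) {
    if (inherits(s, "synthetic_sample"))
      list(image = s$image, label = as_mask(s$synapse_truth),
           mask = cpp_dilate_binary(as_mask(s$neurite_truth), 2L, FALSE))
    else s
  }
  ds <- lapply(dataset, as_triple)
  out <- list()
  for (s in sizes) {
    combos <- combn(n, s)
    if (ncol(combos) > cap) {
      set.seed(seed)
      combos <- combos[, sample.int(ncol(combos), cap), drop = FALSE]
    }
    per_combo <- numeric(ncol(combos))
    pooled <- numeric(ncol(combos))
    for (ci in seq_len(ncol(combos))) {
      tr <- combos[, ci]
      model <- train_synapse_model(lapply(ds[tr], `[[`, "image"),
                                   lapply(ds[tr], `[[`, "label"),
                                   seed = seed, tune = tune, ...)
      ho <- setdiff(seq_len(n), tr)
      ious <- numeric(length(ho)); inter <- 0; uni <- 0
      for (h in seq_along(ho)) {
        d0 <- ds[[ho[h]]]
        pred <- segment_synapses(model, d0$image, mask = d0$mask)
        ious[h] <- compute_iou(pred, d0$label)
        inter <- inter + sum(as_mask(pred) & d0$label)
        uni <- uni + sum(as_mask(pred) | d0$label)
      }
      per_combo[ci] <- mean(ious)
      pooled[ci] <- if (uni == 0) 1 else inter / uni
    }
    out[[length(out) + 1L]] <- data.frame(
      size = s, n_combos = ncol(combos), iou_mean = mean(per_combo),
      iou_sd = if (length(per_combo) > 1) sd(per_combo) else NA_real_,
      iou_pooled_mean = mean(pooled))
  }
  do.call(rbind, out)
}
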