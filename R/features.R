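#' Local feature bank for pixel classification
#'
#' The nine per-channel local filters feeding the pixel classifier: raw
#' value, in-plane Sobel gradient magnitude, two difference-of-Gaussians
#' band-passes, two Laplacian-of-Gaussian blob detectors, local mean and
#' standard deviation in a 3x3x3 window, and a 3x3x3 grayscale erosion.
#' Sobel/DoG/LoG are computed in 2D per slice; mean, sd and erosion in 3D.
#' Scales default to {1, 2, 4} voxels, bracketing the 1-3 voxel
#' small-punctum regime, and are configurable per preset.
#'
#' @param dog_scales List of `(sigma1, sigma2)` pairs for DoG.
#' @param log_scales Sigmas for LoG.
#' @return An object of class `feature_bank`.
#' @export
feature_bank <- function(dog_scales = list(c(1, 2), c(2, 4)),
                         log_scales = c(1, 2)) {
  nm <- c("raw", "sobel",
          vapply(dog_scales, function(s) sprintf("dog_%g_%g", s[1], s[2]), ""),
          sprintf("log_%g", log_scales), "mean3", "sd3", "erosion")
  structure(list(dog_scales = dog_scales, log_scales = log_scales,
                 feature_names = nm), class = "feature_bank")
}

channel_features <- function(vol, bank) {
  ms <- cpp_box_mean_sd(vol)
  feats <- c(list(raw = vol, sobel = cpp_sobel_mag(vol)),
             lapply(bank$dog_scales, function(s)
               cpp_gauss2d(vol, s[1]) - cpp_gauss2d(vol, s[2])),
             lapply(bank$log_scales, function(s)
               cpp_laplace2d(cpp_gauss2d(vol, s))),
             list(mean3 = ms$mean, sd3 = ms$sd, erosion = cpp_erode_gray(vol)))
  names(feats) <- bank$feature_names
  feats
}

#' Compute per-pixel local features
#'
#' One row per pixel, `9 * n_channels` columns in the fixed bank order
#' (synapse channel first, cytoplasmic appended when present). Boundary
#' handling is by reflection, so a constant image yields exactly zero
#' derivative features everywhere.
#'
#' @param image A [vol_image] (or bare 3D array treated as the synapse
#'   channel).
#' @param pixels Integer matrix of 1-based `(z, y, x)` coordinates, or
#'   `NULL` for all voxels (rows in array order).
#' @param bank A [feature_bank()].
#' @return Numeric matrix with named columns; the coordinates used are
#'   attached as attribute `"coords"`.
#' @export
compute_features <- function(image, pixels = NULL, bank = feature_bank()) {
  syn <- as_channel(image, "synapse")
  d <- dim(syn)
  chans <- list(syn = syn)
  if (inherits(image, "vol_image") && !is.null(image$cytoplasmic))
    chans$cyto <- image$cytoplasmic
  idx <- if (is.null(pixels)) seq_len(prod(d)) else coords_to_index(pixels, d)
  cols <- list()
  for (cn in names(chans)) {
    fv <- channel_features(chans[[cn]], bank)
    for (fn in names(fv)) cols[[paste(cn, fn, sep = "_")]] <- fv[[fn]][idx]
  }
  X <- do.call(cbind, cols)
  attr(X, "coords") <- if (is.null(pixels)) index_to_coords(idx, d) else as.matrix(pixels)
  X
}

#' Standard scaler over training pixels
#'
#' Per-feature mean and standard deviation estimated on the training set;
#' transformed training features have mean 0 and unit variance. Constant
#' features are passed through centered but unscaled.
#'
#' @param X Feature matrix (rows = pixels).
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s <- s * sqrt((nrow(X) - 1) / nrow(X))  # population sd
  s[!is.finite(s) | s == 0] <- 1
  structure(list(mean = mu, sd = s), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  sweep(sweep(X, 2, scaler$mean, `-`), 2, scaler$sd, `/`)
}
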