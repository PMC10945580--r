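#' Specification of a synthetic reporter stack
#'
#' Defines the study conditions for one synthetic 3D stack: a tubular
#' neurite of known geometry, Gaussian puncta placed on it, off-neurite
#' clutter blobs mimicking tissue autofluorescence, and additive Gaussian
#' noise. Presets mirror the four punctate-signal regimes commonly met in
#' synaptic reporters: small puncta (1-3 voxel radius) at low or high SNR,
#' medium puncta (3-10 voxels), and diffuse signal (>10 voxels).
#'
#' The blob model is an isotropic Gaussian with `sigma = radius/2`; ground
#' truth is the noiseless blob support above half its peak, which gives an
#' apparent radius of about `0.59 * radius` and keeps the regimes
#' controllable. Clutter blobs share the puncta intensity distribution but
#' are kept at least `2 * neurite_radius` clear of the neurite so that
#' mask-based false-positive rejection is exercised.
#'
#' @param preset One of `"small_high_snr"`, `"small_low_snr"`, `"medium"`,
#'   `"diffuse"`; fills radius and intensity defaults (overridable).
#' @param shape Integer length-3 `(z, y, x)` voxel dimensions.
#' @param neurite_paths List of polyline control-point matrices (columns
#'   `z, y, x`, 1-based voxel coordinates), or `NULL` to draw a smooth
#'   seeded path spanning the volume.
#' @param neurite_radius Tube radius in voxels.
#' @param n_puncta Number of puncta placed on the neurite (non-overlapping).
#' @param puncta_radius_range Length-2, min and max punctum radius (voxels).
#' @param puncta_peak_intensity Peak intensity of a punctum above background.
#' @param background_level Constant background intensity.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param n_clutter Number of off-neurite autofluorescence blobs.
#' @param spacing Physical voxel size, um per axis `(z, y, x)`.
#' @param seed Integer seed; fixes the sample voxel-for-voxel.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(preset = c("small_high_snr", "small_low_snr",
                                      "medium", "diffuse"),
                           shape = NULL, neurite_paths = NULL,
                           neurite_radius = 3, n_puncta = NULL,
                           puncta_radius_range = NULL,
                           puncta_peak_intensity = NULL,
                           background_level = 100, noise_sd = 20,
                           n_clutter = NULL, spacing = c(1, 1, 1),
                           seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    small_high_snr = list(shape = c(16L, 128L, 128L), radius = c(1, 3),
                          peak = 200, n = 20L, clutter = 10L),
    small_low_snr  = list(shape = c(16L, 128L, 128L), radius = c(1, 3),
                          peak = 60, n = 20L, clutter = 10L),
    medium         = list(shape = c(24L, 128L, 128L), radius = c(3, 10),
                          peak = 150, n = 8L, clutter = 6L),
    diffuse        = list(shape = c(24L, 160L, 160L), radius = c(10, 14),
                          peak = 80, n = 3L, clutter = 3L))
  shape <- as.integer(shape %||% def$shape)
  puncta_radius_range <- puncta_radius_range %||% def$radius
  puncta_peak_intensity <- puncta_peak_intensity %||% def$peak
  n_puncta <- as.integer(n_puncta %||% def$n)
  n_clutter <- as.integer(n_clutter %||% def$clutter)

  if (length(shape) != 3L || any(shape < 1L)) stop("'shape' must be 3 positive integers")
  if (n_puncta < 0L) stop("'n_puncta' must be >= 0")
  if (n_clutter < 0L) stop("'n_clutter' must be >= 0")
  if (length(puncta_radius_range) != 2L ||
      puncta_radius_range[1] > puncta_radius_range[2] ||
      puncta_radius_range[1] <= 0)
    stop("'puncta_radius_range' must be positive (min, max) with min <= max")
  if (!is.null(neurite_paths)) {
    if (!is.list(neurite_paths)) neurite_paths <- list(neurite_paths)
    for (p in neurite_paths) {
      p <- as.matrix(p)
      if (ncol(p) != 3L) stop("each neurite path needs columns (z, y, x)")
      if (any(p < 1) || any(p[, 1] > shape[1]) || any(p[, 2] > shape[2]) ||
          any(p[, 3] > shape[3]))
        stop("neurite path control points must lie inside the volume")
    }
  }
  structure(list(shape = shape, neurite_paths = neurite_paths,
                 neurite_radius = neurite_radius, n_puncta = n_puncta,
                 puncta_radius_range = as.numeric(puncta_radius_range),
                 puncta_peak_intensity = puncta_peak_intensity,
                 background_level = background_level, noise_sd = noise_sd,
                 n_clutter = n_clutter, snr_preset = preset,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec:%s> shape %s, %d puncta r[%g,%g], peak %g over bg %g, noise %g, %d clutter, seed %d\n",
              x$snr_preset, paste(x$shape, collapse = "x"), x$n_puncta,
              x$puncta_radius_range[1], x$puncta_radius_range[2],
              x$puncta_peak_intensity, x$background_level, x$noise_sd,
              x$n_clutter, x$seed))
  invisible(x)
}

# Smooth default path spanning the long (x) axis, drawn from the current RNG.
default_path <- function(shape) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  margin <- max(4, ceiling(nx / 16))
  xs <- seq(margin, nx - margin, length.out = 8)
  amp <- ny / 5
  phase <- runif(1, 0, 2 * pi)
  freq <- runif(1, 0.8, 1.6)
  ys <- ny / 2 + amp * sin(phase + freq * seq(0, pi, length.out = 8))
  zwig <- max(1, nz / 8)
  zs <- nz / 2 + cumsum(rnorm(8, 0, zwig / 4))
  zs <- pmin(pmax(zs, 1 + 2), nz - 2)
  ys <- pmin(pmax(ys, 3), ny - 2)
  cbind(z = zs, y = ys, x = xs)
}

# Piecewise-linear resampling of a polyline at (approximately) a fixed step.
densify_path <- function(path, step = 0.5) {
  path <- as.matrix(path)
  if (nrow(path) == 1L) return(path)
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  tt <- seq(0, total, by = step)
  if (tt[length(tt)] < total) tt <- c(tt, total)
  out <- sapply(1:3, function(j) approx(s, path[, j], xout = tt)$y)
  colnames(out) <- c("z", "y", "x")
  out
}

add_blob <- function(arr, center, sigma, peak) {
  d <- dim(arr)
  h <- ceiling(3 * sigma)
  zr <- max(1, floor(center[1] - h)):min(d[1], ceiling(center[1] + h))
  yr <- max(1, floor(center[2] - h)):min(d[2], ceiling(center[2] + h))
  xr <- max(1, floor(center[3] - h)):min(d[3], ceiling(center[3] + h))
  g1 <- function(v, c0) exp(-0.5 * (v - c0)^2 / sigma^2)
  blob <- outer(outer(g1(zr, center[1]), g1(yr, center[2])), g1(xr, center[3]))
  arr[zr, yr, xr] <- arr[zr, yr, xr] + peak * array(blob, c(length(zr), length(yr), length(xr)))
  arr
}

#' Generate one synthetic stack with ground truth
#'
#' Renders the neurite tube (cytoplasmic channel), the puncta and clutter
#' blobs (synapse channel), additive noise, and the matching ground-truth
#' volumes: the noiseless blob supports thresholded at half peak, the tube
#' mask, the skeleton, and the puncta table. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_sample`: list with `image`
#'   ([vol_image] with both channels), `neurite_truth` and `synapse_truth`
#'   (logical arrays), `skeleton_truth` (a [skeleton]), and `puncta_truth`
#'   (data frame of centers, 1-based voxel coordinates, and radii).
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  paths <- spec$neurite_paths %||% list(default_path(d))
  dense <- do.call(rbind, lapply(paths, densify_path, step = 0.5))

  neurite_truth <- cpp_stamp_balls(d, dense - 1, spec$neurite_radius)

  # skeleton nodes at ~1-voxel arc spacing along the first path
  skel_pts <- densify_path(paths[[1]], step = 1.0)
  skeleton_truth <- skeleton_from_nodes(
    sweep(skel_pts, 2, spec$spacing, `*`),
    parent = c(-1L, seq_len(nrow(skel_pts) - 1L)))

  # puncta placement: centers on the neurite, pairwise non-overlapping
  rr <- spec$puncta_radius_range
  centers <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)
  if (spec$n_puncta > 0) {
    max_tries <- 200L * spec$n_puncta
    tries <- 0L
    while (nrow(centers) < spec$n_puncta && tries < max_tries) {
      tries <- tries + 1L
      r <- runif(1, rr[1], rr[2])
      base_pt <- dense[sample.int(nrow(dense), 1L), ]
      jit <- rnorm(3)
      jit <- jit / sqrt(sum(jit^2)) * runif(1, 0, 0.8 * spec$neurite_radius)
      ctr <- round(base_pt + jit)  # puncta are centered on neurite voxels
      supp <- 0.5887 * r
      if (any(ctr < 1 + supp) || any(ctr > d - supp + 1)) next
      if (ctr[1] < 1 || ctr[1] > d[1] || ctr[2] < 1 || ctr[2] > d[2] ||
          ctr[3] < 1 || ctr[3] > d[3]) next
      if (nrow(centers) > 0) {
        # half-peak supports have radius ~0.59 r; a center gap of
        # r_i + r_j + 1 keeps the truth components 26-disconnected
        dd <- sqrt(colSums((t(centers) - ctr)^2))
        if (any(dd < radii + r + 1)) next
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
    }
    if (nrow(centers) < spec$n_puncta)
      stop(sprintf("could only place %d of %d non-overlapping puncta; reduce n_puncta or enlarge the volume",
                   nrow(centers), spec$n_puncta))
  }

  # clutter blobs: same intensity model, >= 2 * neurite_radius off the tube
  clutter_centers <- matrix(numeric(0), 0, 3)
  clutter_radii <- numeric(0)
  if (spec$n_clutter > 0) {
    tries <- 0L
    while (nrow(clutter_centers) < spec$n_clutter && tries < 200L * spec$n_clutter) {
      tries <- tries + 1L
      r <- runif(1, rr[1], rr[2])
      m <- pmin(0.5887 * r, (d - 1) / 2)  # keep the half-peak support inside
      ctr <- c(runif(1, 1 + m[1], d[1] - m[1]), runif(1, 1 + m[2], d[2] - m[2]),
               runif(1, 1 + m[3], d[3] - m[3]))
      if (cpp_min_dist_points(rbind(ctr), dense) <
          spec$neurite_radius + 2 * spec$neurite_radius + r) next
      if (nrow(clutter_centers) > 0) {
        dd <- sqrt(colSums((t(clutter_centers) - ctr)^2))
        if (any(dd < clutter_radii + r + 2)) next
      }
      clutter_centers <- rbind(clutter_centers, ctr)
      clutter_radii <- c(clutter_radii, r)
    }
  }

  # synapse channel: blobs + clutter over background, then noise
  syn <- array(0, d)
  if (nrow(centers) > 0)
    for (i in seq_len(nrow(centers)))
      syn <- add_blob(syn, centers[i, ], radii[i] / 2, spec$puncta_peak_intensity)
  if (nrow(clutter_centers) > 0)
    for (i in seq_len(nrow(clutter_centers)))
      syn <- add_blob(syn, clutter_centers[i, ], clutter_radii[i] / 2,
                      spec$puncta_peak_intensity)
  synapse_truth <- if (nrow(centers) > 0) {
    st <- cpp_stamp_balls(d, centers - 1, 0.5887 * radii)
    # the half-peak ball of a radius-1 punctum can miss every voxel
    # center; the nearest voxel always belongs to the support
    st[coords_to_index(pmin(pmax(round(centers), 1),
                            matrix(d, nrow(centers), 3, byrow = TRUE)),
                       d)] <- TRUE
    st
  } else array(FALSE, d)

  syn <- syn + spec$background_level + array(rnorm(prod(d), 0, spec$noise_sd), d)
  cyto <- spec$background_level + 150 * as.numeric(neurite_truth) +
    array(rnorm(prod(d), 0, spec$noise_sd), d)
  syn[syn < 0] <- 0
  cyto[cyto < 0] <- 0
  dim(cyto) <- d

  puncta_truth <- data.frame(center_z = centers[, 1], center_y = centers[, 2],
                             center_x = centers[, 3], radius = radii,
                             row.names = NULL)
  structure(list(
    image = vol_image(syn, cyto, spacing = spec$spacing,
                      provenance = sprintf("synthetic:%s:seed%d", spec$snr_preset, spec$seed)),
    neurite_truth = label_volume(neurite_truth, "neurite_mask"),
    synapse_truth = label_volume(synapse_truth, "synapse_truth"),
    skeleton_truth = skeleton_truth,
    puncta_truth = puncta_truth,
    spec = spec), class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %s, %d puncta, %d truth voxels\n",
              paste(x$spec$shape, collapse = "x"), nrow(x$puncta_truth),
              sum(x$synapse_truth)))
  invisible(x)
}

#' Generate a reproducible synthetic dataset
#'
#' Derives one seed per image deterministically from `spec$seed`, so the
#' whole dataset is fixed by the spec; individual samples are independent
#' draws of paths, puncta and noise.
#'
#' @param spec A [synthetic_spec()].
#' @param n_images Number of samples (>= 1).
#' @return List of `synthetic_sample` objects.
#' @export
generate_dataset <- function(spec, n_images) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_images <- as.integer(n_images)
  if (is.na(n_images) || n_images < 1L) stop("'n_images' must be >= 1")
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- s
    generate_sample(sp)
  })
}

#' Save / load a synthetic spec as a JSON config file
#'
#' The config fully determines a dataset: [generate_dataset()] on the
#' re-read spec reproduces the same samples voxel for voxel.
#'
#' @param spec A [synthetic_spec()].
#' @param path JSON file path.
#' @return `write_spec_json`: invisibly the path; `read_spec_json`: the
#'   [synthetic_spec()].
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("spec config files require the jsonlite package")
  out <- unclass(spec)
  if (!is.null(out$neurite_paths))
    out$neurite_paths <- lapply(out$neurite_paths, function(p)
      as.data.frame(as.matrix(p)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("spec config files require the jsonlite package")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  paths <- if (!is.null(x$neurite_paths) && length(x$neurite_paths))
    lapply(x$neurite_paths, as.matrix) else NULL
  synthetic_spec(preset = x$snr_preset, shape = x$shape,
                 neurite_paths = paths, neurite_radius = x$neurite_radius,
                 n_puncta = x$n_puncta,
                 puncta_radius_range = x$puncta_radius_range,
                 puncta_peak_intensity = x$puncta_peak_intensity,
                 background_level = x$background_level, noise_sd = x$noise_sd,
                 n_clutter = x$n_clutter, spacing = x$spacing, seed = x$seed)
}

#' Write a synthetic sample to disk
#'
#' Writes the two channels as multi-page TIFF, both truth volumes as uint8
#' 0/255 TIFF, the skeleton as SWC, and the puncta table as CSV.
#'
#' @param sample A `synthetic_sample`.
#' @param dir Output directory (created if missing).
#' @param id File-name stem.
#' @return Invisibly, the named vector of paths written.
#' @export
write_sample <- function(sample, dir, id = "sample") {
  stopifnot(inherits(sample, "synthetic_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(synapse = file.path(dir, paste0(id, "_synapse.tif")),
         cytoplasmic = file.path(dir, paste0(id, "_cytoplasmic.tif")),
         neurite_truth = file.path(dir, paste0(id, "_neurite_truth.tif")),
         synapse_truth = file.path(dir, paste0(id, "_synapse_truth.tif")),
         skeleton = file.path(dir, paste0(id, "_skeleton.swc")),
         puncta = file.path(dir, paste0(id, "_puncta_truth.csv")))
  write_stack(sample$image, synapse = p["synapse"], cytoplasmic = p["cytoplasmic"])
  write_label(sample$neurite_truth, p["neurite_truth"])
  write_label(sample$synapse_truth, p["synapse_truth"])
  write_swc(sample$skeleton_truth, p["skeleton"])
  write.csv(sample$puncta_truth, p["puncta"], row.names = FALSE)
  invisible(p)
}
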