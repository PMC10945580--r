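#' Extract puncta from a binary segmentation
#'
#' Connected components of the prediction under 6-, 18- or 26-connectivity
#' (default 26) become puncta, with centroid, voxel count, physical volume
#' (`voxel_count * prod(spacing)`), and intensity statistics taken from
#' the synapse channel. The voxel lists of the puncta partition the
#' positive voxels: they are pairwise disjoint and their counts sum to the
#' number of true voxels.
#'
#' @param prediction Logical volume (prediction or truth).
#' @param image The matching [vol_image] (or synapse-channel array).
#' @param connectivity 6, 18 or 26.
#' @param min_size Minimum voxel count to keep a punctum (default 1 = off).
#' @param image_id Identifier recorded in tables and CSV output.
#' @return An object of class `puncta_set`: data frame `df` (one row per
#'   punctum), list `voxels` of coordinate matrices, spacing and metadata.
#' @export
extract_puncta <- function(prediction, image, connectivity = 26L,
                           min_size = 1L, image_id = "image") {
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  m <- as_mask(prediction)
  syn <- as_channel(image, "synapse")
  check_same_shape(m, syn, "prediction and image")
  spacing <- image_spacing(image)
  vox_vol <- prod(spacing)
  lab <- cpp_label_components(m, as.integer(connectivity))
  n <- max(lab)
  rows <- list()
  voxels <- list()
  kept <- 0L
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    if (length(idx) < min_size) next
    kept <- kept + 1L
    co <- index_to_coords(idx, dim(m))
    vals <- syn[idx]
    rows[[kept]] <- data.frame(
      id = kept, voxel_count = length(idx),
      centroid_z = mean(co[, 1]), centroid_y = mean(co[, 2]),
      centroid_x = mean(co[, 3]),
      volume_um3 = length(idx) * vox_vol,
      mean_intensity = mean(vals), max_intensity = max(vals),
      total_intensity = sum(vals))
    voxels[[kept]] <- co
  }
  df <- if (kept) do.call(rbind, rows) else
    data.frame(id = integer(0), voxel_count = integer(0),
               centroid_z = numeric(0), centroid_y = numeric(0),
               centroid_x = numeric(0), volume_um3 = numeric(0),
               mean_intensity = numeric(0), max_intensity = numeric(0),
               total_intensity = numeric(0))
  structure(list(df = df, voxels = voxels, image_id = image_id,
                 connectivity = as.integer(connectivity), spacing = spacing),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set:%s> %d puncta (%d voxels), %d-connectivity\n",
              x$image_id, nrow(x$df), sum(x$df$voxel_count), x$connectivity))
  invisible(x)
}

# nearest skeleton node for physical points; ties go to the node nearer
# the soma (smaller arc length) for determinism
nearest_node <- function(points_um, skeleton) {
  nd <- as.matrix(skeleton$nodes[, c("z", "y", "x")])
  arc <- skeleton$arc_length
  vapply(seq_len(nrow(points_um)), function(i) {
    d2 <- colSums((t(nd) - points_um[i, ])^2)
    cand <- which(d2 <= min(d2) + 1e-12)
    cand[which.min(arc[cand])]
  }, integer(1))
}

#' Map puncta onto a skeleton
#'
#' Each punctum is assigned the skeleton node nearest (Euclidean, in um)
#' to its centroid; puncta at least `size_threshold` voxels large are
#' instead spread voxel-by-voxel over their nearest nodes, which smooths
#' the distribution of large, unresolved signals. Positions are
#' normalized to `[0, 1]` by total neurite length (soma = 0, furthest
#' terminal = 1).
#'
#' @param puncta A [extract_puncta()] result.
#' @param skeleton A [skeleton] in the same physical frame.
#' @param mode `"centroid"` or `"per_voxel"` for all puncta; the default
#'   `"auto"` switches to per-voxel above `size_threshold`.
#' @param size_threshold Voxel count above which puncta are spread
#'   per-voxel; defaults to the voxel count of a radius-10 sphere
#'   (the boundary of the diffuse-signal regime).
#' @return The `puncta_set` with `skeleton_node_id` and `position_norm`
#'   columns added, per-position weights in attribute
#'   `"position_samples"`, and the skeleton in attribute `"skeleton"`.
#' @export
map_puncta_to_skeleton <- function(puncta, skeleton,
                                   mode = c("auto", "centroid", "per_voxel"),
                                   size_threshold = NULL) {
  stopifnot(inherits(puncta, "puncta_set"), inherits(skeleton, "skeleton"))
  mode <- match.arg(mode)
  if (nrow(skeleton$nodes) == 0L) stop("empty skeleton")
  size_threshold <- size_threshold %||% ceiling(4 / 3 * pi * 10^3)
  spacing <- puncta$spacing
  df <- puncta$df
  total <- skeleton$total_length
  arc <- skeleton$arc_length
  norm_of <- function(a) if (total > 0) a / total else rep(0, length(a))

  samples <- list()
  node_id <- integer(nrow(df))
  pos <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    per_voxel <- (mode == "per_voxel") ||
      (mode == "auto" && df$voxel_count[i] >= size_threshold)
    if (per_voxel) {
      pts <- sweep(puncta$voxels[[i]], 2, spacing, `*`)  # voxel positions in um
      nn <- nearest_node(pts, skeleton)
      tab <- table(nn)
      samples[[i]] <- data.frame(punctum_id = df$id[i],
                                 node_id = as.integer(names(tab)),
                                 arc_um = arc[as.integer(names(tab))],
                                 weight = as.numeric(tab))
      # representative node for the table: weighted majority
      node_id[i] <- as.integer(names(tab))[which.max(tab)]
    } else {
      ctr <- matrix(c(df$centroid_z[i], df$centroid_y[i], df$centroid_x[i]) *
                    spacing, 1, 3)
      nn <- nearest_node(ctr, skeleton)
      samples[[i]] <- data.frame(punctum_id = df$id[i], node_id = nn,
                                 arc_um = arc[nn],
                                 weight = df$voxel_count[i])
      node_id[i] <- nn
    }
    pos[i] <- norm_of(arc[node_id[i]])
  }
  df$skeleton_node_id <- node_id
  df$position_norm <- pos
  out <- puncta
  out$df <- df
  attr(out, "position_samples") <- if (length(samples))
    do.call(rbind, samples) else
    data.frame(punctum_id = integer(0), node_id = integer(0),
               arc_um = numeric(0), weight = numeric(0))
  attr(out, "skeleton") <- skeleton
  out
}

#' Normalized position profile of one worm
#'
#' Converts mapped puncta into voxel-weighted positions on `[0, 1]`,
#' normalized either by the entire neurite length (soma = 0, furthest
#' terminal = 1) or by the synapse domain (the occupied arc-length span,
#' whose extreme occupied nodes map to exactly 0 and 1).
#'
#' @param mapped A [map_puncta_to_skeleton()] result.
#' @param mode `"entire_neurite"` or `"synapse_domain"`.
#' @return Object of class `distribution_profile`: positions, weights
#'   (voxel counts), and the normalization mode.
#' @export
puncta_positions <- function(mapped, mode = c("entire_neurite", "synapse_domain")) {
  mode <- match.arg(mode)
  s <- attr(mapped, "position_samples")
  if (is.null(s)) stop("puncta have not been mapped to a skeleton")
  skel <- attr(mapped, "skeleton")
  if (nrow(s) == 0L) {
    return(structure(list(position = numeric(0), weight = numeric(0),
                          mode = mode), class = "distribution_profile"))
  }
  if (mode == "entire_neurite") {
    p <- if (skel$total_length > 0) s$arc_um / skel$total_length else rep(0, nrow(s))
  } else {
    span <- range(s$arc_um)
    p <- if (diff(span) > 0) (s$arc_um - span[1]) / diff(span) else rep(0, nrow(s))
  }
  structure(list(position = p, weight = s$weight, mode = mode),
            class = "distribution_profile")
}

#' Population probability density of puncta positions
#'
#' Pools the normalized positions of all worms, weighting by voxel counts,
#' and divides by total pooled synaptic volume times bin width so the
#' histogram integrates to exactly 1.
#'
#' @param profiles List of [puncta_positions()] profiles (>= 1 worm),
#'   all with the same normalization mode.
#' @param n_bins Number of equal bins on `[0, 1]`.
#' @return Object of class `population_density`: bin edges, density
#'   values, and the population size.
#' @export
population_density <- function(profiles, n_bins = 20L) {
  if (inherits(profiles, "distribution_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("empty profile pool")
  modes <- unique(vapply(profiles, function(p) p$mode, ""))
  if (length(modes) > 1L) stop("profiles mix normalization modes: ",
                               paste(modes, collapse = ", "))
  pos <- unlist(lapply(profiles, `[[`, "position"))
  w <- unlist(lapply(profiles, `[[`, "weight"))
  if (length(pos) == 0L) stop("no puncta in the pooled profiles")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(pos, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
  bw <- 1 / n_bins
  structure(list(breaks = breaks, density = counts / (sum(w) * bw),
                 counts = counts, n_worms = length(profiles), mode = modes),
            class = "population_density")
}

#' @export
print.population_density <- function(x, ...) {
  cat(sprintf("<population_density:%s> %d bins over %d worm(s); integral %.6f\n",
              x$mode, length(x$density), x$n_worms,
              sum(x$density) * diff(x$breaks[1:2])))
  invisible(x)
}

#' Per-image summary of puncta features
#'
#' Counts, volumes and mean intensity; when a skeleton is available, also
#' the synapse-domain length (arc span between the first and last occupied
#' node) and the count and volume densities over it. A single punctum has
#' domain length 0 and its densities are reported as `NA` rather than
#' infinity.
#'
#' @param puncta A [extract_puncta()] (optionally mapped) result.
#' @param skeleton Optional [skeleton]; required for densities. If the
#'   puncta are not yet mapped they are mapped with defaults.
#' @return One-row data frame: `image_id, puncta_count, total_volume,
#'   mean_volume, mean_intensity, domain_length, count_density,
#'   volume_density`.
#' @export
summarize_image <- function(puncta, skeleton = NULL) {
  stopifnot(inherits(puncta, "puncta_set"))
  df <- puncta$df
  n <- nrow(df)
  base <- data.frame(image_id = puncta$image_id %||% "image",
                     puncta_count = n,
                     total_volume = if (n) sum(df$volume_um3) else 0,
                     mean_volume = if (n) mean(df$volume_um3) else 0,
                     mean_intensity = if (n) mean(df$mean_intensity) else 0)
  if (is.null(skeleton) && is.null(attr(puncta, "skeleton"))) {
    base$domain_length <- NA_real_
    base$count_density <- NA_real_
    base$volume_density <- NA_real_
    return(base)
  }
  if (is.null(attr(puncta, "position_samples"))) {
    if (is.null(skeleton)) stop("densities requested without a skeleton")
    puncta <- map_puncta_to_skeleton(puncta, skeleton)
  }
  s <- attr(puncta, "position_samples")
  if (nrow(s) == 0L) {
    base$domain_length <- 0
    base$count_density <- NA_real_
    base$volume_density <- NA_real_
    return(base)
  }
  domain <- diff(range(s$arc_um))
  base$domain_length <- domain
  base$count_density <- if (domain > 0) n / domain else NA_real_
  base$volume_density <- if (domain > 0) base$total_volume / domain else NA_real_
  base
}
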