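# TIFF conventions: images are written as 16-bit grayscale multi-page
# stacks (one page per z-slice), labels as 8-bit 0/255. Any nonzero voxel
# of a label file reads back as TRUE, so masks drawn with external tools
# (e.g. the Fiji pencil tool) are accepted as-is.

read_pages <- function(path) {
  pg <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pg)) pg <- list(pg)
  pg
}

pages_to_volume <- function(pages) {
  d2 <- dim(pages[[1]])
  for (p in pages)
    if (!identical(dim(p), d2)) stop("TIFF pages have inconsistent dimensions")
  out <- array(0, c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  out
}

#' Read a multi-page TIFF stack as a volumetric image
#'
#' Channels may live in separate files (named vector of paths) or be
#' interleaved as pages of one file (single path plus a named
#' `channel_map` giving the page offset of each channel, e.g.
#' `c(synapse = 1, cytoplasmic = 2)` for strictly alternating pages).
#'
#' @param path Character: one file, or a named vector of per-channel files
#'   (names among `synapse`, `cytoplasmic`).
#' @param channel_map Named integer vector of page offsets for the
#'   interleaved layout; ignored when `path` is named. Default: single
#'   synapse channel.
#' @param spacing Voxel size in um `(z, y, x)`; when `NULL` a 1 um
#'   isotropic grid is assumed with a warning.
#' @return A [vol_image].
#' @export
read_stack <- function(path, channel_map = c(synapse = 1), spacing = NULL) {
  if (is.null(spacing)) {
    warning("no voxel spacing supplied; assuming isotropic 1 um (densities will be per voxel-unit)")
    spacing <- c(1, 1, 1)
  }
  if (!is.null(names(path)) && length(path) >= 1 && all(nzchar(names(path)))) {
    if (!"synapse" %in% names(path)) stop("a 'synapse' channel is required")
    vols <- lapply(path, function(p) pages_to_volume(read_pages(p)))
    shapes <- lapply(vols, dim)
    for (s in shapes)
      if (!identical(s, shapes[[1]]))
        stop("channel files have different shapes: ",
             paste(sapply(shapes, paste, collapse = "x"), collapse = " vs "))
    return(vol_image(vols[["synapse"]], vols[["cytoplasmic"]],
                     spacing = spacing, provenance = unname(path[1])))
  }
  pages <- read_pages(path)
  nch <- length(channel_map)
  if (length(pages) %% nch != 0)
    stop("page count ", length(pages), " is not a multiple of the ",
         nch, "-channel interleave")
  vols <- lapply(channel_map, function(off)
    pages_to_volume(pages[seq(off, length(pages), by = nch)]))
  vol_image(vols[["synapse"]], vols[["cytoplasmic"]],
            spacing = spacing, provenance = path)
}

#' Write a volumetric image as multi-page TIFF (one file per channel)
#'
#' Intensities are stored as 16-bit grayscale; integer values in
#' `[0, 65535]` round-trip exactly through [read_stack()].
#'
#' @param image A [vol_image] or 3D array.
#' @param synapse,cytoplasmic Output paths; `cytoplasmic` may be `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_stack <- function(image, synapse, cytoplasmic = NULL) {
  write_one <- function(vol, path) {
    if (max(vol) > 65535) stop("intensities exceed 16-bit range")
    pages <- lapply(seq_len(dim(vol)[1]), function(z) vol[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  write_one(as_channel(image, "synapse"), synapse)
  out <- c(synapse = synapse)
  if (!is.null(cytoplasmic)) {
    cy <- if (inherits(image, "vol_image")) image$cytoplasmic else NULL
    if (is.null(cy)) stop("image has no cytoplasmic channel to write")
    write_one(cy, cytoplasmic)
    out <- c(out, cytoplasmic = cytoplasmic)
  }
  invisible(out)
}

#' Write / read a binary label volume as uint8 0/255 TIFF
#'
#' @param label Logical 3D array (or [label_volume]).
#' @param path File path.
#' @return `write_label`: invisibly the path; `read_label`: a logical array
#'   (any nonzero voxel is `TRUE`).
#' @export
write_label <- function(label, path) {
  m <- as_mask(label)
  pages <- lapply(seq_len(dim(m)[1]), function(z) m[z, , ] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_label
#' @param kind Label kind recorded on the result.
#' @export
read_label <- function(path, kind = "synapse_prediction") {
  vol <- pages_to_volume(read_pages(path))
  label_volume(vol != 0, kind)
}

#' Write puncta features to CSV
#'
#' One row per punctum with centroid, voxel count, physical volume,
#' intensity statistics, and (when mapped) the normalized skeleton
#' position; plus an optional per-image summary CSV with counts, volumes
#' and synapse-domain densities. An empty set yields a header-only puncta
#' file and a zero-count summary row.
#'
#' @param puncta A [puncta_set][extract_puncta].
#' @param path Per-punctum CSV path.
#' @param summary_path Optional summary CSV path.
#' @param skeleton Optional [skeleton] used for the summary densities.
#' @return Invisibly, the path(s) written.
#' @export
write_puncta_csv <- function(puncta, path, summary_path = NULL, skeleton = NULL) {
  stopifnot(inherits(puncta, "puncta_set"))
  df <- puncta$df
  cols <- c("image_id", "punctum_id", "centroid_z", "centroid_y", "centroid_x",
            "voxel_count", "volume_um3", "mean_intensity", "max_intensity",
            "total_intensity", "skeleton_position_norm")
  out <- data.frame(image_id = rep(puncta$image_id %||% "image", nrow(df)),
                    punctum_id = df$id, centroid_z = df$centroid_z,
                    centroid_y = df$centroid_y, centroid_x = df$centroid_x,
                    voxel_count = df$voxel_count, volume_um3 = df$volume_um3,
                    mean_intensity = df$mean_intensity,
                    max_intensity = df$max_intensity,
                    total_intensity = df$total_intensity,
                    skeleton_position_norm =
                      if ("position_norm" %in% names(df)) df$position_norm
                      else rep(NA_real_, nrow(df)))
  if (nrow(df) == 0L) out <- out[0, cols, drop = FALSE]
  write.csv(out, path, row.names = FALSE)
  paths <- path
  if (!is.null(summary_path)) {
    s <- summarize_image(puncta, skeleton)
    write.csv(s, summary_path, row.names = FALSE)
    paths <- c(paths, summary_path)
  }
  invisible(paths)
}
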