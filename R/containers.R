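#' Volumetric image container
#'
#' A 3D intensity stack in `(z, y, x)` axis order with a required synapse
#' channel and an optional cytoplasmic channel, plus the physical voxel
#' spacing in micrometers. All channels must share shape; intensities must
#' be finite and nonnegative.
#'
#' @param synapse 3D numeric array `(z, y, x)`, the punctate-signal channel.
#' @param cytoplasmic Optional 3D numeric array of the same shape, the
#'   cytoplasmic (neurite) channel used for masking.
#' @param spacing Numeric length-3, physical voxel size in um per axis
#'   `(z, y, x)`.
#' @param provenance Optional free-form origin tag (path, seed, ...).
#' @return An object of class `vol_image`.
#' @export
vol_image <- function(synapse, cytoplasmic = NULL, spacing = c(1, 1, 1),
                      provenance = NULL) {
  if (length(dim(synapse)) != 3L)
    stop("'synapse' must be a 3D array (z, y, x)")
  if (!all(is.finite(synapse)) || any(synapse < 0))
    stop("synapse channel intensities must be finite and nonnegative")
  if (!is.null(cytoplasmic)) {
    if (!identical(dim(cytoplasmic), dim(synapse)))
      stop("channel shapes differ: synapse ", paste(dim(synapse), collapse = "x"),
           " vs cytoplasmic ", paste(dim(cytoplasmic), collapse = "x"))
    if (!all(is.finite(cytoplasmic)) || any(cytoplasmic < 0))
      stop("cytoplasmic channel intensities must be finite and nonnegative")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (z, y, x) in um")
  structure(list(synapse = synapse, cytoplasmic = cytoplasmic,
                 spacing = as.numeric(spacing), provenance = provenance),
            class = "vol_image")
}

#' @export
print.vol_image <- function(x, ...) {
  d <- dim(x$synapse)
  cat(sprintf("<vol_image> %d x %d x %d (z,y,x), channels: synapse%s, spacing %s um\n",
              d[1], d[2], d[3],
              if (is.null(x$cytoplasmic)) "" else " + cytoplasmic",
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
dim.vol_image <- function(x) dim(x$synapse)

# Accept either a vol_image or a bare array where only one channel matters.
as_channel <- function(image, channel = c("synapse", "cytoplasmic")) {
  channel <- match.arg(channel)
  if (inherits(image, "vol_image")) {
    ch <- image[[channel]]
    if (is.null(ch)) stop("image has no ", channel, " channel")
    return(ch)
  }
  if (is.array(image) && length(dim(image)) == 3L) return(image)
  stop("expected a vol_image or a 3D array")
}

image_spacing <- function(image, default = c(1, 1, 1)) {
  if (inherits(image, "vol_image")) image$spacing else default
}

#' Binary label volume
#'
#' A boolean voxel grid aligned to an image, tagging neurite masks, ground
#' truth, or predictions. Stored as a plain logical array with a `kind`
#' attribute; all functions in the package also accept bare logical arrays.
#'
#' @param data 3D logical (or coercible) array `(z, y, x)`.
#' @param kind One of `"neurite_mask"`, `"synapse_truth"`,
#'   `"synapse_prediction"`.
#' @return A logical array of class `label_volume`.
#' @export
label_volume <- function(data, kind = c("synapse_prediction", "synapse_truth",
                                        "neurite_mask")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  out <- array(as.logical(data), dim(data))
  if (anyNA(out)) stop("label volume contains NA")
  structure(out, kind = kind, class = c("label_volume", class(out)))
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_volume:%s> %d x %d x %d, %d positive voxels\n",
              attr(x, "kind") %||% "?", d[1], d[2], d[3], sum(x)))
  invisible(x)
}

as_mask <- function(x) {
  if (length(dim(x)) != 3L) stop("expected a 3D label volume")
  if (is.logical(x)) {
    y <- array(as.vector(x), dim(x))  # strip classes/attrs
  } else {
    y <- array(as.vector(x) != 0, dim(x))
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(what, " have different shapes: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# (z,y,x) 1-based coordinate matrix -> linear indices into an array of dim d
coords_to_index <- function(coords, d) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coordinate matrix must have 3 columns (z, y, x)")
  if (nrow(coords) == 0L) return(integer(0))
  bad <- coords[, 1] < 1 | coords[, 1] > d[1] |
         coords[, 2] < 1 | coords[, 2] > d[2] |
         coords[, 3] < 1 | coords[, 3] > d[3]
  if (any(bad)) stop(sum(bad), " coordinate(s) out of bounds for shape ",
                     paste(d, collapse = "x"))
  as.integer(coords[, 1] + d[1] * (coords[, 2] - 1) +
             d[1] * d[2] * (coords[, 3] - 1))
}

index_to_coords <- function(idx, d) {
  idx0 <- idx - 1L
  z <- idx0 %% d[1]
  rest <- idx0 %/% d[1]
  y <- rest %% d[2]
  x <- rest %/% d[2]
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}
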