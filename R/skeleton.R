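# Neuron skeletons: a rooted tree of 3D nodes in physical (um)
# coordinates, with arc length from the soma along every path. SWC is the
# interchange format (id, type, x, y, z, radius, parent).

#' Build a skeleton from node coordinates and parent links
#'
#' @param nodes `n x 3` matrix of `(z, y, x)` coordinates in um.
#' @param parent Integer vector of parent row indices (`-1` for the root).
#' @param soma_node Optional row index of the soma; defaults to the root.
#' @return An object of class `skeleton`: node table, arc length from the
#'   soma per node (um), total length (max arc length), and terminal set.
#' @export
skeleton_from_nodes <- function(nodes, parent, soma_node = NULL) {
  nodes <- as.matrix(nodes)
  colnames(nodes) <- c("z", "y", "x")
  n <- nrow(nodes)
  parent <- as.integer(parent)
  if (length(parent) != n) stop("'parent' must have one entry per node")
  roots <- which(parent == -1L)
  if (length(roots) == 0L) stop("skeleton has no root node")
  if (length(roots) > 1L) stop("skeleton has ", length(roots), " roots; expected a single tree")
  if (any(parent != -1L & (parent < 1L | parent > n)))
    stop("parent references out of range")
  # BFS from the root: checks connectivity/acyclicity and computes arc length
  children <- split(seq_len(n), factor(parent, levels = seq_len(n)))
  arc <- rep(NA_real_, n)
  arc[roots] <- 0
  queue <- roots
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ch <- children[[as.character(v)]]
    if (!is.null(ch) && length(ch)) {
      seg <- sqrt(rowSums((nodes[ch, , drop = FALSE] -
                           matrix(nodes[v, ], length(ch), 3, byrow = TRUE))^2))
      arc[ch] <- arc[v] + seg
      queue <- c(queue, ch)
    }
  }
  if (anyNA(arc)) stop("skeleton is disconnected or cyclic (",
                       sum(is.na(arc)), " unreachable node(s))")
  has_child <- vapply(as.character(seq_len(n)),
                      function(k) length(children[[k]]) > 0, logical(1))
  structure(list(nodes = data.frame(id = seq_len(n), z = nodes[, 1],
                                    y = nodes[, 2], x = nodes[, 3],
                                    parent = parent),
                 soma_id = soma_node %||% roots,
                 arc_length = arc,
                 total_length = max(arc),
                 terminals = which(!has_child)),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes, total length %.2f um, soma at node %d, %d terminal(s)\n",
              nrow(x$nodes), x$total_length, x$soma_id, length(x$terminals)))
  invisible(x)
}

#' Read a skeleton from an SWC file
#'
#' SWC coordinates are taken as physical (um) and stored in `(z, y, x)`
#' order. The root is treated as the soma unless a node of SWC type 1
#' (soma) exists. Files with multiple roots, cycles, or disconnected
#' nodes are rejected.
#'
#' @param path SWC file path, or a data frame with SWC columns.
#' @return A [skeleton].
#' @export
load_skeleton <- function(path) {
  if (is.data.frame(path)) {
    swc <- path
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty SWC file: ", path)
    swc <- read.table(text = lines,
                      col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  }
  ord <- order(swc$id)
  swc <- swc[ord, ]
  # remap SWC ids to row indices
  id_map <- match(swc$parent, swc$id)
  parent <- ifelse(swc$parent < 0, -1L, id_map)
  if (any(is.na(parent))) stop("SWC parent ids reference missing nodes")
  soma <- which(swc$type == 1L)
  skeleton_from_nodes(cbind(swc$z, swc$y, swc$x), as.integer(parent),
                      soma_node = if (length(soma)) soma[1] else NULL)
}

#' Write a skeleton as SWC
#'
#' @param skeleton A [skeleton].
#' @param path Output path.
#' @param radius Node radius column written to the file.
#' @return Invisibly, the path.
#' @export
write_swc <- function(skeleton, path, radius = 1) {
  stopifnot(inherits(skeleton, "skeleton"))
  nd <- skeleton$nodes
  type <- ifelse(nd$id == skeleton$soma_id, 1L, 3L)
  df <- data.frame(nd$id, type, nd$x, nd$y, nd$z, radius, nd$parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC generated by punctaseg (coordinates in um, x y z)", con)
  write.table(df, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Centerline of a simple tubular mask
#'
#' A minimal skeletonizer for synthetic tube phantoms whose centerline is
#' monotone along x: each x-column's mask centroid becomes a node. Not
#' suitable for branched or looping neurons.
#'
#' @param mask Logical neurite mask.
#' @param spacing Voxel size in um `(z, y, x)`.
#' @return A [skeleton].
#' @export
skeletonize_tube <- function(mask, spacing = c(1, 1, 1)) {
  m <- as_mask(mask)
  d <- dim(m)
  pts <- list()
  for (x in seq_len(d[3])) {
    sl <- m[, , x]
    if (!any(sl)) next
    w <- which(sl, arr.ind = TRUE)  # (z, y)
    pts[[length(pts) + 1L]] <- c(mean(w[, 1]), mean(w[, 2]), x)
  }
  if (length(pts) == 0L) stop("mask is empty; nothing to skeletonize")
  nodes <- do.call(rbind, pts)
  skeleton_from_nodes(sweep(nodes, 2, spacing, `*`),
                      parent = c(-1L, seq_len(nrow(nodes) - 1L)))
}
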