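#' Read a neuronal skeleton from SWC
#'
#' Standard 7-column SWC (`id type x y z radius parent`, parent `-1` at
#' the root, `#` comments). Coordinates are interpreted in nanometres
#' unless `scale` converts them (e.g. `scale = 1000` for SWC in microns).
#' The node graph must be a single connected tree: exactly one root,
#' every parent id present, no cycles.
#'
#' @param file Path to an SWC file.
#' @param scale Multiplier applied to coordinates to obtain nm.
#' @return An object of class `skeleton`: a list with `nodes` (data frame
#'   `node_id`, `x`, `y`, `z`, `parent`; `parent` is `NA` at the root) and
#'   `root_id`.
#' @export
read_skeleton <- function(file, scale = 1) {
  raw <- utils::read.table(file, header = FALSE, comment.char = "#",
                           col.names = c("node_id", "type", "x", "y", "z",
                                         "radius", "parent"))
  nodes <- data.frame(node_id = as.character(raw$node_id),
                      x = raw$x * scale, y = raw$y * scale, z = raw$z * scale,
                      parent = as.character(raw$parent),
                      stringsAsFactors = FALSE)
  nodes$parent[nodes$parent == "-1"] <- NA_character_
  skeleton(nodes)
}

#' Construct and validate a skeleton
#'
#' @param nodes Data frame with columns `node_id`, `x`, `y`, `z` (nm) and
#'   `parent` (`NA` for the root).
#' @return A `skeleton` object.
#' @export
skeleton <- function(nodes) {
  nodes <- as.data.frame(nodes)
  req <- setdiff(c("node_id", "x", "y", "z", "parent"), names(nodes))
  if (length(req))
    stop("skeleton nodes missing column(s): ", paste(req, collapse = ", "),
         call. = FALSE)
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent <- as.character(nodes$parent)
  if (anyDuplicated(nodes$node_id))
    stop("duplicated skeleton node id(s)", call. = FALSE)
  roots <- nodes$node_id[is.na(nodes$parent)]
  if (length(roots) != 1L)
    stop("skeleton must have exactly one root (parent = -1); found ",
         length(roots), call. = FALSE)
  has_parent <- !is.na(nodes$parent)
  missing_parent <- setdiff(nodes$parent[has_parent], nodes$node_id)
  if (length(missing_parent))
    stop("skeleton node(s) reference absent parent id(s): ",
         paste(missing_parent, collapse = ", "), call. = FALSE)
  # connectivity + acyclicity: walking parent pointers from every node
  # must reach the root without revisiting
  idx <- match(nodes$parent, nodes$node_id)
  n <- nrow(nodes)
  depth <- rep.int(NA_integer_, n)
  depth[is.na(idx)] <- 0L
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    newly <- which(is.na(depth) & !is.na(depth[idx]))
    if (length(newly)) {
      depth[newly] <- depth[idx[newly]] + 1L
      changed <- TRUE
    }
  }
  if (anyNA(depth))
    stop("skeleton is not a connected tree: ", sum(is.na(depth)),
         " node(s) unreachable from the root (cycle or disconnection)",
         call. = FALSE)
  elen <- edge_lengths(nodes, idx)
  if (any(elen <= 0))
    stop("skeleton has zero-length edge(s): child node(s) ",
         paste(nodes$node_id[has_parent][elen <= 0], collapse = ", "),
         call. = FALSE)
  structure(list(nodes = nodes, root_id = roots), class = "skeleton")
}

edge_lengths <- function(nodes, idx = match(nodes$parent, nodes$node_id)) {
  ii <- which(!is.na(idx))
  sqrt((nodes$x[ii] - nodes$x[idx[ii]])^2 +
       (nodes$y[ii] - nodes$y[idx[ii]])^2 +
       (nodes$z[ii] - nodes$z[idx[ii]])^2)
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton> ", nrow(x$nodes), " nodes, root ", x$root_id,
      ", cable ", format(cable_length(x), digits = 4), " um\n", sep = "")
  invisible(x)
}

#' Total cable length of a skeleton
#'
#' Sum of Euclidean edge lengths, in microns.
#' @param skel A `skeleton`.
#' @return Numeric scalar (um).
#' @export
cable_length <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  sum(edge_lengths(skel$nodes)) / 1000
}
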