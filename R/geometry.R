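#' Geodesic distance from the root to every skeleton node
#'
#' Path length along the tree from `root_node` to each node, as the sum
#' of Euclidean edge lengths (reported in microns). The root is the
#' point where the dendrites collect into a single axonal fiber — an
#' anatomical judgment supplied by the caller, defaulting to the SWC
#' root.
#'
#' @param skel A `skeleton`.
#' @param root_node Node id to measure from (default the skeleton root).
#' @return Named numeric vector of distances (um), one per node.
#' @export
geodesic_from_root <- function(skel, root_node = skel$root_id) {
  stopifnot(inherits(skel, "skeleton"))
  nodes <- skel$nodes
  if (!root_node %in% nodes$node_id)
    stop("root node ", root_node, " is not in the skeleton", call. = FALSE)
  n <- nrow(nodes)
  idx <- match(nodes$parent, nodes$node_id)
  # undirected adjacency so any node can serve as the measuring root
  ii <- which(!is.na(idx))
  elen <- edge_lengths(nodes, idx)
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (k in seq_along(ii)) {
    a <- ii[k]; b <- idx[ii[k]]
    adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], elen[k])
    adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], elen[k])
  }
  dist <- rep.int(NA_real_, n)
  start <- match(root_node, nodes$node_id)
  dist[start] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- adj[[v]]
      new <- nb[is.na(dist[nb])]
      if (length(new)) {
        dist[new] <- dist[v] + wts[[v]][match(new, nb)]
        nxt <- c(nxt, new)
      }
    }
    frontier <- nxt
  }
  out <- dist / 1000
  names(out) <- nodes$node_id
  out
}

#' Input-position profile along a dendritic arbor
#'
#' Maps each synaptic input onto `post_neuron` to its nearest skeleton
#' node (Euclidean snap, excluding contacts farther than `snap_tol` from
#' any node, with the excluded count reported), measures the distance
#' from the root along the arbor, and bins the distances in log-spaced
#' bins. `metric = "euclidean"` measures straight-line distance from the
#' root instead of the geodesic.
#'
#' @param x A `connectome` carrying a skeleton for `post_neuron`.
#' @param post_neuron Postsynaptic neuron id.
#' @param pre_selector Optional presynaptic selector (type class, token,
#'   or ids); default all inputs.
#' @param root_node Root node id (default the skeleton root).
#' @param n_bins Number of log-spaced histogram bins.
#' @param snap_tol Snap tolerance, nm (default 500; contacts sit on the
#'   membrane while the skeleton follows the centerline).
#' @param metric `"geodesic"` (default) or `"euclidean"`.
#' @return List of class `input_profile`: `post_neuron`, `root_node`,
#'   `distances_um` (one per mapped contact), `histogram` (data frame
#'   `bin_lo_um`, `bin_hi_um`, `count`), `mean_distance_um`,
#'   `n_excluded`.
#' @export
input_profile <- function(x, post_neuron, pre_selector = NULL,
                          root_node = NULL, n_bins = 20L, snap_tol = 500,
                          metric = c("geodesic", "euclidean")) {
  stopifnot(inherits(x, "connectome"))
  metric <- match.arg(metric)
  skel <- x$skeletons[[post_neuron]]
  if (is.null(skel))
    stop("no skeleton available for ", post_neuron, call. = FALSE)
  if (is.null(root_node)) root_node <- skel$root_id
  ct <- contact_table(x)
  keep <- ct$post_neuron == post_neuron
  if (!is.null(pre_selector))
    keep <- keep & ct$pre_neuron %in% resolve_neurons(x, pre_selector)
  sel <- ct[keep, , drop = FALSE]
  node_xyz <- as.matrix(skel$nodes[, c("x", "y", "z")])
  nn <- nn_nearest(site_xyz(sel), node_xyz)
  ok <- nn$dist <= snap_tol
  n_excluded <- sum(!ok)
  if (n_excluded)
    message(n_excluded, " contact(s) farther than ", snap_tol,
            " nm from any skeleton node; excluded")
  if (metric == "geodesic") {
    g <- geodesic_from_root(skel, root_node)
    d <- unname(g[nn$index[ok]])
  } else {
    r <- node_xyz[match(root_node, skel$nodes$node_id), ]
    d <- sqrt(rowSums(sweep(node_xyz[nn$index[ok], , drop = FALSE],
                            2, r)^2)) / 1000
  }
  hist_df <- log_binned_histogram(d, n_bins)
  structure(
    list(post_neuron = post_neuron, root_node = root_node,
         distances_um = d, histogram = hist_df,
         mean_distance_um = if (length(d)) mean(d) else NA_real_,
         n_excluded = n_excluded),
    class = "input_profile")
}

# base-10 log-spaced bins from 0.1 um up to the max distance; distances
# below the first edge (including exact zeros) are pooled into the first
# bin
log_binned_histogram <- function(d, n_bins) {
  if (!length(d))
    return(data.frame(bin_lo_um = numeric(0), bin_hi_um = numeric(0),
                      count = integer(0)))
  top <- max(d, 0.2)
  edges <- 10^seq(log10(0.1), log10(top * 1.0001),
                  length.out = n_bins + 1L)
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  data.frame(bin_lo_um = edges[-length(edges)], bin_hi_um = edges[-1],
             count = tabulate(idx, nbins = n_bins))
}

#' @export
print.input_profile <- function(x, ...) {
  cat("<input_profile> ", length(x$distances_um), " inputs onto ",
      x$post_neuron, " (root ", x$root_node, ")\n", sep = "")
  cat(sprintf("  mean distance from root: %.2f um; %d excluded\n",
              x$mean_distance_um, x$n_excluded))
  invisible(x)
}
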