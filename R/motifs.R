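#' Detect convergences: clustered KC inputs onto a common target
#'
#' A convergence is a tight spatial grouping — within `radius` (default
#' 300 nm) — of presynaptic sites from at least two distinct KCs, all
#' presynaptic to the same postsynaptic neuron. Clusters are the
#' single-linkage components of the KC presynaptic sites sharing the
#' postsynaptic neuron (every member joined by a chain of pairwise
#' distances at most `radius`; distances are Euclidean site-to-site, and
#' ties at exactly the threshold count as within), filtered to components
#' with >= 2 distinct KCs. Each site belongs to at most one cluster per
#' postsynaptic neuron.
#'
#' @param x A `connectome`.
#' @param post_selector Postsynaptic cells to analyse: type class,
#'   cell-type token, or neuron ids. Default `"MBON"`.
#' @param radius Single-linkage threshold, nm.
#' @param pre_class Presynaptic class forming the clusters (default KC).
#' @return Object of class `convergence_set`: a data frame of cluster
#'   members with columns `post_neuron`, `cluster_id`, `site_id`,
#'   `pre_neuron`, `x`, `y`, `z`, plus attributes `radius` and
#'   `is_rosette` (filled by [find_rosettes()]).
#' @export
find_convergences <- function(x, post_selector = "MBON", radius = 300,
                              pre_class = "KC") {
  stopifnot(inherits(x, "connectome"))
  post_cells <- resolve_neurons(x, post_selector)
  ct <- contact_table(x)
  pre_ok <- x$neurons$neuron_id[x$neurons$type_class == pre_class]
  keep <- ct$post_neuron %in% post_cells & ct$pre_neuron %in% pre_ok
  sel <- ct[keep, , drop = FALSE]
  if (anyNA(sel$x) || anyNA(sel$y) || anyNA(sel$z))
    stop("missing coordinates for site(s): ",
         paste(utils::head(sel$site_id[is.na(sel$x) | is.na(sel$y) |
                                         is.na(sel$z)], 5L), collapse = ", "),
         call. = FALSE)
  # one row per (post neuron, site): a polyadic site contributes once
  sel <- sel[!duplicated(paste(sel$post_neuron, sel$site_id, sep = "\r")), ,
             drop = FALSE]
  out <- list()
  next_id <- 0L
  for (p in unique(sel$post_neuron)) {
    s <- sel[sel$post_neuron == p, , drop = FALSE]
    comp <- radius_components(site_xyz(s), radius)
    sizes <- table(comp)
    for (cid in names(sizes)) {
      rows <- which(comp == as.integer(cid))
      if (length(unique(s$pre_neuron[rows])) < 2L) next
      next_id <- next_id + 1L
      out[[next_id]] <- data.frame(
        post_neuron = p, cluster_id = next_id,
        site_id = s$site_id[rows], pre_neuron = s$pre_neuron[rows],
        x = s$x[rows], y = s$y[rows], z = s$z[rows],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(post_neuron = character(0), cluster_id = integer(0),
               site_id = character(0), pre_neuron = character(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  rownames(res) <- NULL
  attr(res, "radius") <- radius
  attr(res, "is_rosette") <- NULL
  class(res) <- c("convergence_set", "data.frame")
  res
}

#' Flag rosettes among detected convergences
#'
#' A rosette is a convergence that additionally contains a KC-to-KC
#' synaptic contact between member KCs: a contact whose presynaptic site
#' lies within the cluster radius of a member site and whose presynaptic
#' and postsynaptic neurons are both member KCs of that cluster.
#'
#' @param clusters A `convergence_set` from [find_convergences()].
#' @param x The `connectome` the clusters came from.
#' @return `clusters` with attribute `is_rosette` (named logical by
#'   cluster id) and attribute `kc_kc_contacts` (data frame `cluster_id`,
#'   `site_id`, `pre_neuron`, `post_neuron`).
#' @export
find_rosettes <- function(clusters, x) {
  stopifnot(inherits(clusters, "convergence_set"), inherits(x, "connectome"))
  radius <- attr(clusters, "radius")
  ct <- contact_table(x)
  kc <- x$neurons$neuron_id[x$neurons$type_class == "KC"]
  kk <- ct[ct$pre_neuron %in% kc & ct$post_neuron %in% kc &
             ct$pre_neuron != ct$post_neuron, , drop = FALSE]
  ids <- unique(clusters$cluster_id)
  ros <- logical(length(ids))
  names(ros) <- ids
  support <- list()
  if (nrow(kk)) {
    for (i in seq_along(ids)) {
      mem <- clusters[clusters$cluster_id == ids[i], , drop = FALSE]
      mkc <- unique(mem$pre_neuron)
      cand <- kk[kk$pre_neuron %in% mkc & kk$post_neuron %in% mkc, ,
                 drop = FALSE]
      if (!nrow(cand)) next
      nn <- nn_nearest(site_xyz(cand), site_xyz(mem))
      hit <- nn$dist <= radius
      if (any(hit)) {
        ros[i] <- TRUE
        support[[length(support) + 1L]] <- data.frame(
          cluster_id = ids[i], site_id = cand$site_id[hit],
          pre_neuron = cand$pre_neuron[hit],
          post_neuron = cand$post_neuron[hit])
      }
    }
  }
  attr(clusters, "is_rosette") <- ros
  attr(clusters, "kc_kc_contacts") <-
    if (length(support)) do.call(rbind, support) else
      data.frame(cluster_id = integer(0), site_id = character(0),
                 pre_neuron = character(0), post_neuron = character(0))
  clusters
}

#' Fraction of presynaptic sites participating in convergences/rosettes
#'
#' Denominator: all KC presynaptic sites with at least one contact onto a
#' cell of `post_type`. Numerators: those participating in a detected
#' convergence (resp. rosette) targeting such a cell.
#'
#' @param x A `connectome`.
#' @param post_type Postsynaptic type class or cell-type token.
#' @param clusters Optional precomputed `convergence_set` (with rosette
#'   flags); computed at `radius` otherwise.
#' @param radius Single-linkage threshold, nm.
#' @return List with `percent_in_convergence`, `percent_in_rosette`,
#'   `n_sites` (the denominator). Percentages are `NA` when the
#'   denominator is zero.
#' @export
motif_fractions <- function(x, post_type = "MBON", clusters = NULL,
                            radius = 300) {
  stopifnot(inherits(x, "connectome"))
  if (is.null(clusters))
    clusters <- find_rosettes(find_convergences(x, post_type, radius), x)
  if (is.null(attr(clusters, "is_rosette")))
    clusters <- find_rosettes(clusters, x)
  ct <- contact_table(x)
  kc <- x$neurons$neuron_id[x$neurons$type_class == "KC"]
  post_cells <- resolve_neurons(x, post_type)
  denom_sites <- unique(ct$site_id[ct$pre_neuron %in% kc &
                                     ct$post_neuron %in% post_cells])
  if (!length(denom_sites))
    return(list(percent_in_convergence = NA_real_,
                percent_in_rosette = NA_real_, n_sites = 0L))
  in_conv <- denom_sites %in% clusters$site_id
  ros_ids <- names(which(attr(clusters, "is_rosette")))
  ros_sites <- clusters$site_id[clusters$cluster_id %in% as.integer(ros_ids)]
  in_ros <- denom_sites %in% ros_sites
  list(percent_in_convergence = 100 * mean(in_conv),
       percent_in_rosette = 100 * mean(in_ros),
       n_sites = length(denom_sites))
}

#' Enumerate KC<>KC>MBON triangle motifs
#'
#' Triples `(kc_a, kc_b, mbon)` such that a KC-to-KC contact exists
#' between the two KCs (in either direction) and both KCs synapse onto
#' the same MBON within the same convergence cluster. The KC pair is
#' unordered; each (pair, MBON) triple is reported once.
#'
#' @param x A `connectome`.
#' @param clusters Optional precomputed `convergence_set`; computed at
#'   `radius` otherwise.
#' @param radius Single-linkage threshold, nm.
#' @return Data frame with columns `kc_a`, `kc_b`, `mbon`.
#' @export
triangle_motifs <- function(x, clusters = NULL, radius = 300) {
  stopifnot(inherits(x, "connectome"))
  if (is.null(clusters)) clusters <- find_convergences(x, "MBON", radius)
  ct <- contact_table(x)
  kc <- x$neurons$neuron_id[x$neurons$type_class == "KC"]
  kk <- ct[ct$pre_neuron %in% kc & ct$post_neuron %in% kc &
             ct$pre_neuron != ct$post_neuron, , drop = FALSE]
  if (!nrow(kk) || !nrow(clusters))
    return(data.frame(kc_a = character(0), kc_b = character(0),
                      mbon = character(0)))
  kk_key <- unique(paste(pmin(kk$pre_neuron, kk$post_neuron),
                         pmax(kk$pre_neuron, kk$post_neuron), sep = "\r"))
  out <- list()
  for (cid in unique(clusters$cluster_id)) {
    mem <- clusters[clusters$cluster_id == cid, , drop = FALSE]
    mkc <- sort(unique(mem$pre_neuron))
    if (length(mkc) < 2L) next
    cmb <- utils::combn(mkc, 2L)
    key <- paste(cmb[1, ], cmb[2, ], sep = "\r")
    hit <- key %in% kk_key
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        kc_a = cmb[1, hit], kc_b = cmb[2, hit],
        mbon = mem$post_neuron[1], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kc_a = character(0), kc_b = character(0), mbon = character(0))
  res <- res[!duplicated(paste(res$kc_a, res$kc_b, res$mbon, sep = "\r")), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
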