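# Builders and independent oracles used across the suite. Oracles are
# deliberately naive (all-pairs, hclust, direct enumeration) and share no
# code with the package implementation.

# connectome from sites/contacts alone; cell_type inferred from the id
# prefix before the final ".", e.g. "KC-ab-s.7" -> "KC-ab-s"
build_connectome <- function(sites, contacts, skeletons = list()) {
  ids <- unique(c(sites$pre_neuron, contacts$post_neuron))
  neurons <- data.frame(neuron_id = ids,
                        cell_type = sub("\\.[^.]*$", "", ids),
                        stringsAsFactors = FALSE)
  connectome(neurons, sites, contacts, skeletons = skeletons)
}

site_row <- function(id, pre, x, y, z, comp = "a1") {
  data.frame(site_id = id, pre_neuron = pre, x = x, y = y, z = z,
             compartment = comp, stringsAsFactors = FALSE)
}

# single-linkage components at a radius via hclust (independent of the
# package's grid union-find)
oracle_single_linkage <- function(xyz, radius) {
  n <- nrow(xyz)
  if (n == 1L) return(1L)
  cutree(hclust(dist(xyz), method = "single"), h = radius)
}

# all-pairs nearest-reference distance
oracle_nn_dist <- function(query, ref) {
  apply(query, 1, function(q) sqrt(min(colSums((t(ref) - q)^2))))
}

# partitions compared as sets of member sets (labels are arbitrary)
partition_signature <- function(keys, groups) {
  sig <- vapply(split(keys, groups),
                function(k) paste(sort(k), collapse = "|"), character(1))
  sort(unname(sig))
}

# volume of a radius-r ball centred at axial position z, clipped to the
# slab z_lo..z_hi (no lateral clipping)
slab_ball_volume <- function(r, z, z_lo, z_hi) {
  cap <- function(h) pi * h^2 * (3 * r - h) / 3
  h1 <- pmin(pmax(r - (z - z_lo), 0), 2 * r)
  h2 <- pmin(pmax(r - (z_hi - z), 0), 2 * r)
  4 / 3 * pi * r^3 - cap(h1) - cap(h2)
}

# a straight-path skeleton along +z with the given edge lengths (nm)
path_skeleton <- function(edge_nm, origin = c(0, 0, 0)) {
  zs <- cumsum(c(0, edge_nm))
  skeleton(data.frame(
    node_id = as.character(seq_along(zs)),
    x = origin[1], y = origin[2], z = origin[3] + zs,
    parent = c(NA, as.character(seq_len(length(zs) - 1L)))))
}

# small generator config used by several tests
small_config <- function(seed, n_s = 20L, lambda = 2, convergence_rate = 0,
                         rosette_rate = 0, min_sep = 0, n_mbon = 1L,
                         lobe_radius = 8000, axon_fraction = 0.85,
                         extra_wiring = NULL, extra_extrinsic = NULL,
                         kc_jitter = 300) {
  wiring <- data.frame(pre_type = "KC-ab-s", post_type = "MBON-a3",
                       compartment = "a3", lambda = lambda)
  if (!is.null(extra_wiring)) wiring <- rbind(wiring, extra_wiring)
  extrinsic <- data.frame(cell_type = "MBON-a3", compartment = "a3",
                          n = n_mbon)
  if (!is.null(extra_extrinsic)) extrinsic <- rbind(extrinsic, extra_extrinsic)
  generator_config(
    n_kc = c("KC-ab-s" = as.integer(n_s)),
    extrinsic = extrinsic, wiring = wiring,
    lobe_radius = lobe_radius, axon_fraction = axon_fraction,
    kc_jitter = kc_jitter,
    convergence_rate = convergence_rate, rosette_rate = rosette_rate,
    min_cluster_separation = min_sep, seed = seed)
}
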