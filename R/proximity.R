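# Dopamine volume-transmission geometry: proximity of KC>MBON synapses
# to DAN release sites, purely geometric (no diffusion PDE) — coverage
# within a radius stands in for the effective range of dopamine action.

# KC>MBON contacts with their site coordinates and compartments
kc_mbon_contacts <- function(x) {
  ct <- contact_table(x)
  kc <- x$neurons$neuron_id[x$neurons$type_class == "KC"]
  mbon <- x$neurons$neuron_id[x$neurons$type_class == "MBON"]
  ct[ct$pre_neuron %in% kc & ct$post_neuron %in% mbon, , drop = FALSE]
}

dan_sites <- function(x) {
  dan <- x$neurons$neuron_id[x$neurons$type_class == "DAN"]
  x$sites[x$sites$pre_neuron %in% dan, , drop = FALSE]
}

#' Fraction of KC>MBON synapses with a DAN terminal nearby
#'
#' For each KC>MBON contact, the Euclidean distance from its presynaptic
#' site to the nearest DAN presynaptic site is compared to `radius`
#' (closed ball: ties count as within). Returns the fraction of contacts
#' covered; 0 when no DAN sites exist.
#'
#' @param x A `connectome`.
#' @param radius Coverage radius, nm (default 300).
#' @return Numeric fraction in `[0, 1]`.
#' @export
dan_proximity_fraction <- function(x, radius = 300) {
  stopifnot(inherits(x, "connectome"))
  km <- kc_mbon_contacts(x)
  if (!nrow(km)) return(NA_real_)
  ds <- dan_sites(x)
  if (!nrow(ds)) return(0)
  nn <- nn_nearest(site_xyz(km), site_xyz(ds))
  mean(nn$dist <= radius)
}

#' Volume-transmission coverage curves
#'
#' For each radius, the fraction of KC>MBON contacts having at least one
#' DAN presynaptic site within that radius, computed separately for DAN
#' sites of the contact's own compartment and for DAN sites of adjacent
#' compartments (a1-a2, a2-a3). Both curves are nondecreasing in the
#' radius. The default grid covers 0-5000 nm in 100 nm steps, spanning
#' the 2-2.5 um range discussed for the effective reach of dopamine.
#'
#' @param x A `connectome`.
#' @param radii Increasing numeric vector of radii, nm.
#' @return Data frame of class `coverage_curve`: `radius_nm`,
#'   `same_compartment_fraction`, `adjacent_compartment_fraction`.
#' @export
coverage_curve <- function(x, radii = seq(0, 5000, by = 100)) {
  stopifnot(inherits(x, "connectome"), !is.unsorted(radii))
  km <- kc_mbon_contacts(x)
  if (!nrow(km))
    return(structure(data.frame(radius_nm = radii,
                                same_compartment_fraction = NA_real_,
                                adjacent_compartment_fraction = NA_real_),
                     class = c("coverage_curve", "data.frame")))
  ds <- dan_sites(x)
  n <- nrow(km)
  d_same <- rep.int(Inf, n)
  d_adj <- rep.int(Inf, n)
  for (comp in unique(km$compartment)) {
    rows <- which(km$compartment == comp)
    q <- site_xyz(km[rows, , drop = FALSE])
    same_ref <- ds[ds$compartment == comp, , drop = FALSE]
    adj <- adjacent_compartments(x, comp)
    adj_ref <- ds[ds$compartment %in% adj, , drop = FALSE]
    if (nrow(same_ref)) d_same[rows] <- nn_nearest(q, site_xyz(same_ref))$dist
    if (nrow(adj_ref)) d_adj[rows] <- nn_nearest(q, site_xyz(adj_ref))$dist
  }
  out <- data.frame(
    radius_nm = radii,
    same_compartment_fraction =
      vapply(radii, function(r) mean(d_same <= r), numeric(1)),
    adjacent_compartment_fraction =
      vapply(radii, function(r) mean(d_adj <= r), numeric(1)))
  class(out) <- c("coverage_curve", "data.frame")
  out
}

#' Distance to, and traffic in front of, the nearest DAN>KC synapse
#'
#' For each KC>MBON contact: the Euclidean distance from its presynaptic
#' site to the nearest DAN>KC synapse (a DAN presynaptic site with at
#' least one KC postsynaptic partner), and the number of other
#' presynaptic sites lying strictly closer than that nearest DAN>KC
#' synapse (the synapses "interspersed" between a KC>MBON synapse and its
#' closest source of dopamine).
#'
#' @param x A `connectome`.
#' @return List with `mean_distance_nm`, `mean_interspersed`, and the
#'   per-contact vectors `distance_nm` and `interspersed`.
#' @export
nearest_modulation_stats <- function(x) {
  stopifnot(inherits(x, "connectome"))
  km <- kc_mbon_contacts(x)
  if (!nrow(km))
    return(list(mean_distance_nm = NA_real_, mean_interspersed = NA_real_,
                distance_nm = numeric(0), interspersed = numeric(0)))
  ct <- contact_table(x)
  kc <- x$neurons$neuron_id[x$neurons$type_class == "KC"]
  dan <- x$neurons$neuron_id[x$neurons$type_class == "DAN"]
  dankc_sites <- unique(ct$site_id[ct$pre_neuron %in% dan &
                                     ct$post_neuron %in% kc])
  if (!length(dankc_sites))
    stop("no DAN>KC synapses in the connectome", call. = FALSE)
  ref <- x$sites[x$sites$site_id %in% dankc_sites, , drop = FALSE]
  q <- site_xyz(km)
  nn <- nn_nearest(q, site_xyz(ref))
  allsites <- site_xyz(x$sites)
  n_within <- nn_count_within(q, allsites, nn$dist, strict = TRUE)
  # a site at distance 0 from itself is never strictly closer than a
  # positive threshold minus itself; subtract the self site when its
  # distance (0) falls below the threshold
  self_hit <- as.integer(nn$dist > 0)
  interspersed <- pmax(n_within - self_hit, 0L)
  list(mean_distance_nm = mean(nn$dist),
       mean_interspersed = mean(interspersed),
       distance_nm = nn$dist, interspersed = interspersed)
}
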