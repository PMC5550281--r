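#' Construct and validate a connectome
#'
#' A connectome bundles neurons, polyadic presynaptic sites, synaptic
#' contacts, and (optionally) skeletons. The synapse-counting convention
#' is: one synapse = one (presynaptic site, postsynaptic neuron) contact,
#' so a polyadic site with four postsynaptic partners contributes four
#' synapses. Positions are in nanometres. Compartments are the serial
#' zones `a1`, `a2`, `a3` traversed by the Kenyon-cell axon bundle (plus
#' `outside` for sites beyond them); adjacency is a1-a2 and a2-a3 only.
#'
#' @param neurons Data frame with columns `neuron_id`, `cell_type`,
#'   `instance_label` (optional; defaults to `""`). `type_class` is derived
#'   from the cell-type registry.
#' @param sites Data frame with columns `site_id`, `pre_neuron`, `x`, `y`,
#'   `z` (nm, non-negative), `compartment`.
#' @param contacts Data frame with columns `site_id`, `post_neuron`.
#' @param skeletons Named list of [skeleton] objects, keyed by neuron id.
#' @param compartment_order Character vector giving the axial order of
#'   compartments; defines adjacency.
#' @return An object of class `connectome`.
#' @examples
#' nn <- data.frame(neuron_id = c("kc1", "m1"),
#'                  cell_type = c("KC-ab-s", "MBON-a3"))
#' ss <- data.frame(site_id = "s1", pre_neuron = "kc1",
#'                  x = 0, y = 0, z = 100, compartment = "a3")
#' cc <- data.frame(site_id = "s1", post_neuron = "m1")
#' connectome(nn, ss, cc)
#' @export
connectome <- function(neurons, sites, contacts, skeletons = list(),
                       compartment_order = c("a1", "a2", "a3")) {
  neurons <- as.data.frame(neurons)
  sites <- as.data.frame(sites)
  contacts <- as.data.frame(contacts)

  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  req(neurons, c("neuron_id", "cell_type"), "neurons")
  req(sites, c("site_id", "pre_neuron", "x", "y", "z", "compartment"), "sites")
  req(contacts, c("site_id", "post_neuron"), "contacts")

  neurons$neuron_id <- as.character(neurons$neuron_id)
  if (anyDuplicated(neurons$neuron_id))
    stop("duplicated neuron_id: ",
         paste(unique(neurons$neuron_id[duplicated(neurons$neuron_id)]),
               collapse = ", "), call. = FALSE)
  neurons$type_class <- type_class_of(neurons$cell_type)
  if (is.null(neurons$instance_label)) neurons$instance_label <- ""

  sites$site_id <- as.character(sites$site_id)
  sites$pre_neuron <- as.character(sites$pre_neuron)
  if (anyDuplicated(sites$site_id))
    stop("duplicated site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "), call. = FALSE)
  for (ax in c("x", "y", "z")) {
    v <- sites[[ax]]
    if (nrow(sites) == 0L) {
      sites[[ax]] <- numeric(0)
      next
    }
    if (!is.numeric(v) || anyNA(v))
      stop("malformed coordinate in sites$", ax, call. = FALSE)
    if (any(v < 0))
      stop("negative coordinate in sites$", ax, " at row(s) ",
           paste(utils::head(which(v < 0), 5L), collapse = ", "),
           call. = FALSE)
  }
  ok_comp <- c(compartment_order, "outside")
  bad <- setdiff(unique(sites$compartment), ok_comp)
  if (length(bad))
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unknown_pre <- setdiff(sites$pre_neuron, neurons$neuron_id)
  if (length(unknown_pre))
    stop("sites reference unknown presynaptic neuron(s): ",
         paste(utils::head(unknown_pre, 5L), collapse = ", "), call. = FALSE)

  contacts$site_id <- as.character(contacts$site_id)
  contacts$post_neuron <- as.character(contacts$post_neuron)
  if (nrow(contacts)) {
    orphan <- !(contacts$site_id %in% sites$site_id)
    if (any(orphan))
      stop("contact row(s) ", paste(utils::head(which(orphan), 5L), collapse = ", "),
           " reference unknown site_id: ",
           paste(utils::head(unique(contacts$site_id[orphan]), 5L), collapse = ", "),
           call. = FALSE)
    unknown_post <- !(contacts$post_neuron %in% neurons$neuron_id)
    if (any(unknown_post))
      stop("contact row(s) ", paste(utils::head(which(unknown_post), 5L), collapse = ", "),
           " reference unknown postsynaptic neuron: ",
           paste(utils::head(unique(contacts$post_neuron[unknown_post]), 5L),
                 collapse = ", "), call. = FALSE)
    key <- paste(contacts$site_id, contacts$post_neuron, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (site_id, post_neuron) pair(s) at contact row(s) ",
           paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
           call. = FALSE)
  }

  if (length(skeletons)) {
    if (is.null(names(skeletons)) || any(!nzchar(names(skeletons))))
      stop("skeletons must be a named list keyed by neuron_id", call. = FALSE)
    unk <- setdiff(names(skeletons), neurons$neuron_id)
    if (length(unk))
      stop("skeletons for unknown neuron(s): ", paste(unk, collapse = ", "),
           call. = FALSE)
  }

  structure(
    list(neurons = neurons,
         sites = sites,
         contacts = contacts,
         skeletons = skeletons,
         compartment_order = compartment_order),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>\n")
  cat("  neurons:  ", nrow(x$neurons), " (",
      paste(sprintf("%s=%d", names(table(x$neurons$type_class)),
                    as.integer(table(x$neurons$type_class))), collapse = ", "),
      ")\n", sep = "")
  cat("  sites:    ", nrow(x$sites), "\n", sep = "")
  cat("  synapses: ", nrow(x$contacts), " contacts\n", sep = "")
  cat("  skeletons:", length(x$skeletons), "\n")
  invisible(x)
}

#' Total synapse count of a connectome
#'
#' One synapse = one (site, postsynaptic neuron) contact.
#' @param x A `connectome`.
#' @return Integer count.
#' @export
n_synapses <- function(x) {
  stopifnot(inherits(x, "connectome"))
  nrow(x$contacts)
}

# neuron ids of a class or cell type; selector may be a type_class value,
# a cell_type token, or a vector of neuron ids
resolve_neurons <- function(x, selector) {
  if (is.null(selector)) return(x$neurons$neuron_id)
  selector <- as.character(selector)
  if (length(selector) == 1L) {
    if (selector %in% x$neurons$type_class)
      return(x$neurons$neuron_id[x$neurons$type_class == selector])
    if (selector %in% x$neurons$cell_type)
      return(x$neurons$neuron_id[x$neurons$cell_type == selector])
  }
  if (all(selector %in% x$neurons$neuron_id)) return(selector)
  if (all(selector %in% x$neurons$cell_type))
    return(x$neurons$neuron_id[x$neurons$cell_type %in% selector])
  stop("selector does not resolve to any neurons: ",
       paste(utils::head(selector, 5L), collapse = ", "), call. = FALSE)
}

# contacts joined with their site attributes (pre_neuron, xyz, compartment)
contact_table <- function(x) {
  idx <- match(x$contacts$site_id, x$sites$site_id)
  data.frame(
    site_id = x$contacts$site_id,
    post_neuron = x$contacts$post_neuron,
    pre_neuron = x$sites$pre_neuron[idx],
    x = x$sites$x[idx], y = x$sites$y[idx], z = x$sites$z[idx],
    compartment = x$sites$compartment[idx],
    stringsAsFactors = FALSE)
}

# compartment adjacency from the declared axial order
adjacent_compartments <- function(x, compartment) {
  ord <- x$compartment_order
  i <- match(compartment, ord)
  out <- character(0)
  if (!is.na(i)) {
    if (i > 1L) out <- c(out, ord[i - 1L])
    if (i < length(ord)) out <- c(out, ord[i + 1L])
  }
  out
}
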