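#' Per-presynaptic-cell synapse counts onto a target
#'
#' Counts, for every presynaptic cell in the selection, its synapses
#' (contacts) onto `post_cell`, optionally restricted to one compartment.
#' Cells with no contacts appear as explicit zeros; the Poisson fits
#' require those zeros.
#'
#' @param x A `connectome`.
#' @param pre_selector Type class (e.g. `"KC"`), cell-type token, or
#'   vector of neuron ids.
#' @param post_cell A single postsynaptic neuron id.
#' @param compartment Optional compartment label.
#' @return Named integer vector, one entry per selected presynaptic cell.
#' @export
per_cell_counts <- function(x, pre_selector, post_cell, compartment = NULL) {
  stopifnot(inherits(x, "connectome"))
  pre <- resolve_neurons(x, pre_selector)
  if (!length(pre)) stop("empty presynaptic selection", call. = FALSE)
  if (!post_cell %in% x$neurons$neuron_id)
    stop("unknown postsynaptic cell: ", post_cell, call. = FALSE)
  ct <- contact_table(x)
  keep <- ct$post_neuron == post_cell & ct$pre_neuron %in% pre
  if (!is.null(compartment)) keep <- keep & ct$compartment %in% compartment
  counts <- table(factor(ct$pre_neuron[keep], levels = pre))
  out <- as.integer(counts)
  names(out) <- pre
  out
}

#' Aggregate wiring summary for one connection
#'
#' The per-(pre type, post, compartment) aggregate of the wiring tables:
#' number of connected presynaptic cells, total synapses, mean synapses
#' per *connected* presynaptic cell, and (for KC presynaptic selections) a
#' per-subtype breakdown of synapse counts with percentages computed on
#' synapse counts. Zero-inclusive means are available via
#' `connected_only = FALSE`.
#'
#' @param x A `connectome`.
#' @param pre_type Presynaptic type class or cell-type token.
#' @param post Postsynaptic neuron id, cell-type token, or type class.
#' @param compartment Optional compartment restriction.
#' @param connected_only Mean over connected cells (default) or over all
#'   selected cells.
#' @return A list of class `wiring_summary`.
#' @export
wiring_summary <- function(x, pre_type, post, compartment = NULL,
                           connected_only = TRUE) {
  stopifnot(inherits(x, "connectome"))
  pre <- resolve_neurons(x, pre_type)
  post_cells <- resolve_neurons(x, post)
  if (!length(pre) || !length(post_cells))
    stop("empty selection", call. = FALSE)
  ct <- contact_table(x)
  keep <- ct$pre_neuron %in% pre & ct$post_neuron %in% post_cells
  if (!is.null(compartment)) keep <- keep & ct$compartment %in% compartment
  sel <- ct[keep, , drop = FALSE]
  per_pre <- table(factor(sel$pre_neuron, levels = pre))
  n_pre_connected <- sum(per_pre > 0)
  total <- nrow(sel)
  denom <- if (connected_only) n_pre_connected else length(pre)
  mean_per_pre <- if (denom > 0) total / denom else NA_real_
  subtype <- NULL
  pre_types <- x$neurons$cell_type[match(pre, x$neurons$neuron_id)]
  if (all(pre_types %in% kc_subtypes())) {
    st_of <- pre_types[match(sel$pre_neuron, pre)]
    cnt <- table(factor(st_of, levels = kc_subtypes()))
    subtype <- data.frame(
      subtype = kc_subtypes(),
      n_synapses = as.integer(cnt),
      percent = if (total > 0) 100 * as.integer(cnt) / total else
        rep(NA_real_, length(cnt)))
  }
  structure(
    list(pre_type = if (length(pre_type) == 1L) pre_type else "(ids)",
         post = if (length(post) == 1L) post else "(ids)",
         compartment = compartment,
         n_pre_connected = n_pre_connected,
         n_post_connected = sum(post_cells %in% sel$post_neuron),
         total_synapses = total,
         mean_per_connected_pre = mean_per_pre,
         subtype_breakdown = subtype),
    class = "wiring_summary")
}

#' @export
print.wiring_summary <- function(x, ...) {
  cat("<wiring_summary> ", x$pre_type, " > ", x$post,
      if (!is.null(x$compartment)) paste0(" [", x$compartment, "]"), "\n",
      sep = "")
  cat(sprintf("  connected pre cells: %d   total synapses: %d   mean/connected: %.2f\n",
              x$n_pre_connected, x$total_synapses, x$mean_per_connected_pre))
  if (!is.null(x$subtype_breakdown)) {
    b <- x$subtype_breakdown
    cat(paste(sprintf("  %-10s %6d (%.1f%%)", b$subtype, b$n_synapses,
                      b$percent), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' KC sampling profile of a postsynaptic cell
#'
#' For each KC subtype: `connected` (A) of `available` (B) cells make
#' synapses onto `post_cell`, with `mean_connected` (C) synapses among
#' those connected — the "A/B x C" form of the published sampling table.
#' The weighted recombination sum(A*C) equals the cell's total KC input.
#'
#' @param x A `connectome`.
#' @param post_cell Postsynaptic neuron id.
#' @param compartment Optional compartment restriction.
#' @return Data frame with one row per KC subtype, class
#'   `sampling_profile`.
#' @export
sampling_profile <- function(x, post_cell, compartment = NULL) {
  stopifnot(inherits(x, "connectome"))
  if (!post_cell %in% x$neurons$neuron_id)
    stop("unknown postsynaptic cell: ", post_cell, call. = FALSE)
  out <- lapply(kc_subtypes(), function(st) {
    ids <- x$neurons$neuron_id[x$neurons$cell_type == st]
    if (!length(ids))
      return(data.frame(post_cell = post_cell, subtype = st, connected = 0L,
                        available = 0L, mean_connected = NA_real_))
    cnt <- per_cell_counts(x, ids, post_cell, compartment)
    a <- sum(cnt > 0)
    data.frame(post_cell = post_cell, subtype = st, connected = a,
               available = length(ids),
               mean_connected = if (a > 0) mean(cnt[cnt > 0]) else NA_real_)
  })
  out <- do.call(rbind, out)
  class(out) <- c("sampling_profile", "data.frame")
  out
}

#' Cell-type connectivity matrix
#'
#' Synapse counts aggregated to (presynaptic cell type, postsynaptic cell
#' type), stratified by compartment. The grand total equals the global
#' contact count, and the matrix is invariant under permutation of neuron
#' ids.
#'
#' @param x A `connectome`.
#' @param compartment Optional single compartment; default pools all and
#'   returns per-compartment strata too.
#' @return A list of matrices, one per compartment present plus `"all"`
#'   (rows = presynaptic cell types, columns = postsynaptic cell types).
#' @export
type_matrix <- function(x, compartment = NULL) {
  stopifnot(inherits(x, "connectome"))
  ct <- contact_table(x)
  tmap <- x$neurons$cell_type
  names(tmap) <- x$neurons$neuron_id
  ct$pre_type <- unname(tmap[ct$pre_neuron])
  ct$post_type <- unname(tmap[ct$post_neuron])
  types <- sort(unique(c(ct$pre_type, ct$post_type)))
  mk <- function(rows) {
    m <- table(factor(ct$pre_type[rows], levels = types),
               factor(ct$post_type[rows], levels = types))
    unclass(as.matrix(m))
  }
  if (!is.null(compartment))
    return(mk(ct$compartment %in% compartment))
  comps <- intersect(x$compartment_order, unique(ct$compartment))
  out <- lapply(comps, function(cc) mk(ct$compartment == cc))
  names(out) <- comps
  out$all <- mk(rep(TRUE, nrow(ct)))
  out
}

#' Write a wiring summary table for several postsynaptic cells
#'
#' Convenience batch form: one row per postsynaptic cell, mirroring the
#' published table layout (connected presynaptic cells, total synapses,
#' mean per connected cell, per-subtype counts and percentages).
#'
#' @param x A `connectome`.
#' @param pre_type Presynaptic selector (e.g. `"KC"`).
#' @param post_cells Vector of postsynaptic neuron ids.
#' @param compartment Optional compartment restriction.
#' @return Data frame, one row per postsynaptic cell.
#' @export
wiring_table <- function(x, pre_type, post_cells, compartment = NULL) {
  rows <- lapply(post_cells, function(pc) {
    ws <- wiring_summary(x, pre_type, pc, compartment)
    row <- data.frame(post_cell = pc,
                      n_pre_connected = ws$n_pre_connected,
                      total_synapses = ws$total_synapses,
                      mean_per_connected = ws$mean_per_connected_pre)
    if (!is.null(ws$subtype_breakdown)) {
      b <- ws$subtype_breakdown
      for (i in seq_len(nrow(b))) {
        row[[paste0("n_", b$subtype[i])]] <- b$n_synapses[i]
        row[[paste0("pct_", b$subtype[i])]] <- b$percent[i]
      }
    }
    row
  })
  do.call(rbind, rows)
}
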