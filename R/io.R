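# Delimited-text readers/writers for synapse tables and edge lists.
# Dialect: comma- or tab-delimited with a header row, UTF-8. The delimiter
# is sniffed from the header line.

read_delim_auto <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    encoding = "UTF-8")
}

#' Read a connectome from delimited synapse tables
#'
#' Expects three delimited files (comma- or tab-separated, with header):
#' * `site_file`: one row per presynaptic site, columns `site_id`,
#'   `pre_neuron`, `x`, `y`, `z` (nm), `compartment`;
#' * `contact_file`: one row per postsynaptic contact, columns `site_id`,
#'   `post_neuron`;
#' * `annotation_file`: one row per neuron, columns `neuron_id`,
#'   `cell_type`, and optionally `instance_label`.
#'
#' Every contact must reference a known site and neuron, cell types must
#' come from [cell_type_registry()], and duplicate (site, post) pairs are
#' rejected. Counts of sites, contacts and neurons per class are reported
#' as a message.
#'
#' @param site_file,contact_file,annotation_file Paths to delimited files.
#' @param quiet Suppress the ingest summary message.
#' @return A validated [connectome()].
#' @export
read_synapse_table <- function(site_file, contact_file, annotation_file,
                               quiet = FALSE) {
  sites <- read_delim_auto(site_file)
  contacts <- read_delim_auto(contact_file)
  neurons <- read_delim_auto(annotation_file)
  if (nrow(contacts) == 0L)
    contacts <- data.frame(site_id = character(0), post_neuron = character(0))
  x <- connectome(neurons, sites, contacts)
  if (!quiet) {
    cls <- table(x$neurons$type_class)
    message("read ", nrow(x$sites), " sites, ", nrow(x$contacts),
            " contacts, ", nrow(x$neurons), " neurons (",
            paste(sprintf("%s=%d", names(cls), as.integer(cls)),
                  collapse = ", "), ")")
  }
  x
}

#' Write a connectome back to delimited synapse tables
#'
#' Inverse of [read_synapse_table()]: writes the three tables in the same
#' schema, so that reading them back reproduces the sites, contacts and
#' neuron annotations exactly.
#'
#' @param x A `connectome`.
#' @param site_file,contact_file,annotation_file Output paths.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `x`, invisibly.
#' @export
write_synapse_table <- function(x, site_file, contact_file, annotation_file,
                                sep = ",") {
  stopifnot(inherits(x, "connectome"))
  w <- function(df, file)
    utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  w(x$sites[, c("site_id", "pre_neuron", "x", "y", "z", "compartment")],
    site_file)
  w(x$contacts[, c("site_id", "post_neuron")], contact_file)
  w(x$neurons[, c("neuron_id", "cell_type", "instance_label")],
    annotation_file)
  invisible(x)
}

#' Export an aggregated edge list
#'
#' Aggregates contacts into rows `(pre, post, compartment, n_synapses)`,
#' grouped either by individual neuron or by cell type. The sum of
#' `n_synapses` always equals the total contact count.
#'
#' @param x A `connectome`.
#' @param group_by `"neuron"` or `"cell_type"`.
#' @param file Optional path; when given, the edge list is also written as
#'   a delimited file.
#' @param sep Field delimiter used when `file` is given.
#' @return Data frame with columns `pre`, `post`, `compartment`,
#'   `n_synapses`.
#' @export
export_edges <- function(x, group_by = c("neuron", "cell_type"),
                         file = NULL, sep = ",") {
  stopifnot(inherits(x, "connectome"))
  group_by <- match.arg(group_by)
  ct <- contact_table(x)
  if (group_by == "cell_type") {
    tmap <- x$neurons$cell_type
    names(tmap) <- x$neurons$neuron_id
    pre <- unname(tmap[ct$pre_neuron])
    post <- unname(tmap[ct$post_neuron])
  } else {
    pre <- ct$pre_neuron
    post <- ct$post_neuron
  }
  if (!nrow(ct)) {
    out <- data.frame(pre = character(0), post = character(0),
                      compartment = character(0), n_synapses = integer(0))
  } else {
    agg <- stats::aggregate(
      list(n_synapses = rep.int(1L, nrow(ct))),
      by = list(pre = pre, post = post, compartment = ct$compartment),
      FUN = sum)
    out <- agg[order(agg$pre, agg$post, agg$compartment), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(file))
    utils::write.table(out, file, sep = sep, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  out
}

#' Export the cell-type graph as GraphML
#'
#' Writes the cell-type-aggregated edge list as a minimal GraphML document
#' with `n_synapses` as an edge attribute, readable by igraph, Gephi and
#' Cytoscape.
#'
#' @param x A `connectome`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
export_graphml <- function(x, file) {
  ed <- export_edges(x, group_by = "cell_type")
  ed <- stats::aggregate(n_synapses ~ pre + post, data = ed, FUN = sum)
  nodes <- sort(unique(c(ed$pre, ed$post)))
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"w\" for=\"edge\" attr.name=\"n_synapses\" attr.type=\"int\"/>",
    "  <graph edgedefault=\"directed\">"), con)
  writeLines(sprintf("    <node id=\"%s\"/>", esc(nodes)), con)
  writeLines(sprintf(
    "    <edge source=\"%s\" target=\"%s\"><data key=\"w\">%d</data></edge>",
    esc(ed$pre), esc(ed$post), ed$n_synapses), con)
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(file)
}
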