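# Transcriptions of the published alpha-lobe wiring tables, shipped as
# plain-text fixtures, plus the cross-table derivations computed from
# them. These helpers operate on any table with the same columns, so the
# same derivations run on summaries of synthetic connectomes.

#' Load a transcribed published wiring table
#'
#' Available tables: `"kc_mbon"` (KC>MBON totals per MBON),
#' `"kc_mbon_sampling"` (per-subtype A/B x C sampling profiles),
#' `"dan_kc"`, `"kc_dan"` (DAN<->KC totals per DAN cell), and
#' `"dan_mbon"` (DAN>MBON totals per MBON). Cell-type tokens use the
#' package's ASCII vocabulary (a for alpha, e.g. `MBON-a2sc`).
#'
#' @param name Table name.
#' @return Data frame.
#' @export
printed_table <- function(name = c("kc_mbon", "kc_mbon_sampling", "dan_kc",
                                   "kc_dan", "dan_mbon")) {
  name <- match.arg(name)
  f <- system.file("extdata", "printed-tables", paste0(name, ".csv"),
                   package = "mbwiring", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Mean synapses per connected presynaptic cell
#'
#' The derivation behind the "mean per KC" column of the wiring tables:
#' total synapse count divided by the number of connected presynaptic
#' cells (not by all candidates).
#'
#' @param total_synapses,n_connected Numeric vectors.
#' @return Numeric vector of means.
#' @export
mean_per_connected <- function(total_synapses, n_connected) {
  total_synapses / n_connected
}

#' Recombine a sampling profile into a total synapse count
#'
#' sum over subtypes of (connected cells A) x (mean among connected C);
#' equals the cell's total input up to the rounding of the printed C
#' values.
#'
#' @param profile Data frame with columns `connected` and
#'   `mean_connected` (as [sampling_profile()] or the
#'   `"kc_mbon_sampling"` fixture).
#' @return Numeric scalar.
#' @export
recombine_sampling <- function(profile) {
  m <- profile$mean_connected
  m[is.na(m)] <- 0
  sum(profile$connected * m)
}

#' DAN>MBON input as a percentage of KC>MBON input
#'
#' For each MBON, the number of synapses it receives from its
#' compartment's DANs as a percentage of the synapses it receives from
#' KCs. The percentage is defined as `100 * dan_synapses / kc_synapses`
#' with the KC>MBON totals as denominator; the published table's alpha1
#' and alpha2p3p percent entries differ slightly from this derivation
#' (their denominator is ambiguous), which is why the computed column is
#' returned alongside any printed one.
#'
#' @param dan_mbon Data frame with columns `post_mbon`, `total_synapses`
#'   (defaults to the transcribed published table).
#' @param kc_mbon Data frame with columns `post_mbon`, `total_synapses`.
#' @return `dan_mbon` with an added `percent_of_kc_input` column; the
#'   whole-lobe percentage is attached as attribute `whole_lobe`.
#' @export
dan_mbon_percent <- function(dan_mbon = printed_table("dan_mbon"),
                             kc_mbon = printed_table("kc_mbon")) {
  idx <- match(dan_mbon$post_mbon, kc_mbon$post_mbon)
  if (anyNA(idx))
    stop("MBON(s) missing from kc_mbon table: ",
         paste(dan_mbon$post_mbon[is.na(idx)], collapse = ", "),
         call. = FALSE)
  kc_tot <- kc_mbon$total_synapses[idx]
  dan_mbon$percent_of_kc_input <- 100 * dan_mbon$total_synapses / kc_tot
  attr(dan_mbon, "whole_lobe") <-
    100 * sum(dan_mbon$total_synapses) / sum(kc_mbon$total_synapses)
  dan_mbon
}

#' Whole-lobe KC>DAN to DAN>KC synapse ratio
#'
#' Axo-axonal KC>DAN synapses outnumber the reciprocal DAN>KC synapses;
#' this computes the ratio of the two whole-lobe totals.
#'
#' @param kc_dan Data frame with a `total_synapses` column (defaults to
#'   the transcribed published table).
#' @param dan_kc Likewise for DAN>KC.
#' @return Numeric scalar ratio.
#' @export
kc_dan_ratio <- function(kc_dan = printed_table("kc_dan"),
                         dan_kc = printed_table("dan_kc")) {
  sum(kc_dan$total_synapses) / sum(dan_kc$total_synapses)
}
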