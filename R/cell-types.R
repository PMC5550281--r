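#' Controlled vocabulary of alpha-lobe cell types
#'
#' Every neuron in a [connectome()] carries a `cell_type` token from this
#' registry, which maps deterministically to one of five classes:
#' `KC` (Kenyon cells, by alpha/beta subtype), `MBON` (output neurons with
#' dendrites inside the lobe), `DAN` (dopaminergic neurons), `modulatory`
#' (the lobe-wide intrinsic neurons APL and DPM, and the SIFamide neuron),
#' and `feedforward` (MBONs projecting into the alpha lobe from other
#' lobes, which are presynaptic here).
#'
#' @return A data frame with columns `cell_type` and `type_class`.
#' @examples
#' cell_type_registry()
#' @export
cell_type_registry <- function() {
  data.frame(
    cell_type = c(
      "KC-ab-s", "KC-ab-c-i", "KC-ab-c-o", "KC-ab-p",
      "MBON-a3", "MBON-a2sc", "MBON-a2p3p", "MBON-a2sp", "MBON-a1",
      "PPL1-a3", "PPL1-ap2a2", "PAM-a1",
      "APL", "DPM", "SIFamide",
      "MBON-b1-ff", "MBON-g1pedc-ff"
    ),
    type_class = c(
      rep("KC", 4),
      rep("MBON", 5),
      rep("DAN", 3),
      rep("modulatory", 3),
      rep("feedforward", 2)
    ),
    stringsAsFactors = FALSE
  )
}

#' Map cell-type tokens to their class
#'
#' @param cell_type Character vector of cell-type tokens.
#' @return Character vector of classes (`KC`, `MBON`, `DAN`, `modulatory`,
#'   `feedforward`).
#' @examples
#' type_class_of(c("KC-ab-p", "PPL1-a3"))
#' @export
type_class_of <- function(cell_type) {
  reg <- cell_type_registry()
  idx <- match(cell_type, reg$cell_type)
  if (anyNA(idx)) {
    bad <- unique(cell_type[is.na(idx)])
    stop("unknown cell_type token(s): ", paste(bad, collapse = ", "),
         "; valid tokens are: ", paste(reg$cell_type, collapse = ", "),
         call. = FALSE)
  }
  reg$type_class[idx]
}

# KC subtype order used for sampling profiles and subtype breakdowns
kc_subtypes <- function() c("KC-ab-s", "KC-ab-c-o", "KC-ab-c-i", "KC-ab-p")
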