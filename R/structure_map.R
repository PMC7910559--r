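#' Map a divergence scale onto a structural model
#'
#' Writes per-residue divergence values into the temperature-factor
#' (B-factor) column of a PDB file, the standard vehicle for coloring a
#' structure by an external per-residue scale. Scale values are multiplied
#' by 100 and rounded to 2 decimals (the B-factor column's precision);
#' residues of the chain not covered by the scale are reported and left at
#' 0, and atoms of other chains are zeroed.
#'
#' @param scale numeric vector from [divergence_scale()]; element `i` maps
#'   to residue number `i + numbering_offset`.
#' @param model_file input PDB path.
#' @param chain chain identifier to annotate.
#' @param numbering_offset added to the scale index to obtain the PDB
#'   residue number.
#' @param out_file output PDB path.
#' @return `out_file` invisibly, with attributes `matched` and `unmatched`
#'   (residue numbers).
#' @export
map_scale_to_structure <- function(scale, model_file, chain = "A",
                                   numbering_offset = 0, out_file) {
  pdb <- bio3d::read.pdb(model_file)
  at <- pdb$atom
  if (!chain %in% unique(at$chain)) stop("chain '", chain, "' absent from model")
  resno_scale <- seq_along(scale) + numbering_offset
  sel <- at$chain == chain
  chain_resno <- unique(at$resno[sel])
  matched <- intersect(chain_resno, resno_scale)
  if (!length(matched)) stop("no residues matched the scale numbering (check numbering_offset)")
  b <- numeric(nrow(at))
  idx <- sel & at$resno %in% matched
  b[idx] <- round(100 * scale[at$resno[idx] - numbering_offset], 2)
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = out_file)
  invisible(structure(out_file, matched = matched,
                      unmatched = setdiff(chain_resno, resno_scale)))
}

#' Read per-residue B-factors from a PDB file
#'
#' Companion to [map_scale_to_structure()]: returns one value per residue of
#' a chain (the B-factor of its first atom), useful for round-trip checks
#' and downstream tabulation.
#'
#' @param model_file PDB path.
#' @param chain chain identifier.
#' @return named numeric vector, names are residue numbers.
#' @export
read_bfactors <- function(model_file, chain = "A") {
  pdb <- bio3d::read.pdb(model_file)
  at <- pdb$atom[pdb$atom$chain == chain, ]
  if (!nrow(at)) stop("chain '", chain, "' absent from model")
  first <- !duplicated(at$resno)
  stats::setNames(at$b[first], at$resno[first])
}
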