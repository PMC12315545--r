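# Canonicalization is delegated to OpenBabel through ChemmineOB. The package
# writer produces a valid (non-canonical) SMILES; OpenBabel maps isomorphic
# structures to one canonical string, which is what vocabulary keys require.

.pt_ob_canonical_batch <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = paste(smiles, collapse = "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("[ \t].*$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(smiles)) {
    stop(sprintf(
      "canonicalization returned %d records for %d inputs; invalid SMILES in batch?",
      length(lines), length(smiles)
    ))
  }
  lines
}

#' Canonical structure key of a molecule or induced subgraph
#'
#' Returns a canonical SMILES string such that isomorphic (sub)structures map
#' to the same key, deterministically across runs. Cut bonds of a subgraph are
#' capped with implicit hydrogens. Tetrahedral stereocentres whose
#' substituents are all retained keep their configuration and affect the key;
#' centres that lost a substituent to a cut are emitted without configuration.
#'
#' @param mol a `pep_mol`.
#' @param subset optional atom indices (1-based) of a connected induced
#'   subgraph; default: the whole molecule.
#' @return a single canonical SMILES string.
#' @examples
#' \dontrun{
#' m1 <- pep_mol("OC(=O)CN")
#' m2 <- pep_mol("NCC(O)=O")
#' canonical_key(m1) == canonical_key(m2)  # TRUE
#' }
#' @export
canonical_key <- function(mol, subset = seq_len(n_atoms(mol))) {
  stopifnot(inherits(mol, "pep_mol"))
  .pt_ob_canonical_batch(pt_write_smiles(mol, subset))
}

# vectorized over a list of (mol, subset) pairs; one OpenBabel round-trip
.pt_canonical_keys <- function(mols, subsets = NULL) {
  sm <- if (is.null(subsets)) {
    vapply(mols, pt_write_smiles, character(1))
  } else {
    vapply(seq_along(mols), function(i) pt_write_smiles(mols[[i]], subsets[[i]]), character(1))
  }
  .pt_ob_canonical_batch(sm)
}
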