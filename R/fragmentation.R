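# Fragmentations are exact partitions of the heavy atoms together with the
# list of cut bonds; the partition plus the cut bonds carry full information,
# so every fragmentation can be reassembled into the original molecule.

#' Construct a fragmentation object from fragment atom sets
#'
#' Validates the partition law (fragments pairwise disjoint, union = all
#' atoms, each connected) and derives `cut_bonds` as every molecule bond that
#' joins two different fragments. Fragment canonical keys are computed in one
#' canonicalization batch.
#'
#' @param mol a `pep_mol`.
#' @param fragments list of atom-index vectors (1-based).
#' @param method method tag.
#' @return a `pep_fragmentation`.
#' @keywords internal
pt_fragmentation <- function(mol, fragments, method) {
  fragments <- lapply(fragments, function(f) sort(unique(as.integer(f))))
  fragments <- fragments[order(vapply(fragments, min, integer(1)))]
  n <- n_atoms(mol)
  all_idx <- unlist(fragments)
  if (length(all_idx) != n || anyDuplicated(all_idx) ||
      any(all_idx < 1L | all_idx > n)) {
    stop("fragments must form an exact partition of the heavy atoms")
  }
  frag_of <- integer(n)
  for (i in seq_along(fragments)) frag_of[fragments[[i]]] <- i
  for (i in seq_along(fragments)) {
    if (length(.pt_components(mol, fragments[[i]])) != 1L) {
      stop("each fragment must induce a connected subgraph")
    }
  }
  b <- mol$bonds
  cut_idx <- which(frag_of[b$a] != frag_of[b$b])
  cut_bonds <- data.frame(
    a = b$a[cut_idx], b = b$b[cut_idx], order = b$order[cut_idx],
    stringsAsFactors = FALSE
  )
  keys <- .pt_canonical_keys(rep(list(mol), length(fragments)), fragments)
  structure(
    list(
      fragments = fragments, cut_bonds = cut_bonds,
      fragment_keys = keys, method = method,
      fragment_of_atom = frag_of, mol_n_atoms = n
    ),
    class = "pep_fragmentation"
  )
}

#' @export
print.pep_fragmentation <- function(x, ...) {
  cat(sprintf(
    "<pep_fragmentation> method=%s: %d fragments, %d cut bonds over %d atoms\n",
    x$method, length(x$fragments), nrow(x$cut_bonds), x$mol_n_atoms
  ))
  invisible(x)
}

# amide single C(=O)-N bonds of a molecule (bond row indices)
.pt_amide_bonds <- function(mol) {
  b <- mol$bonds
  at <- mol$atoms
  carbonyl <- logical(n_atoms(mol))
  dbl <- which(b$order == "double")
  ca <- b$a[dbl]; cb <- b$b[dbl]
  carbonyl[ca[at$element[ca] == "C" & !at$aromatic[ca] & at$element[cb] == "O"]] <- TRUE
  carbonyl[cb[at$element[cb] == "C" & !at$aromatic[cb] & at$element[ca] == "O"]] <- TRUE
  which(
    b$order == "single" &
      ((carbonyl[b$a] & at$element[b$b] == "N") |
       (carbonyl[b$b] & at$element[b$a] == "N"))
  )
}

#' Do two molecules share a canonical key?
#'
#' Fast path: the package writer is deterministic, so identical writer output
#' implies an identical canonical key; OpenBabel canonicalization is only
#' consulted when the raw strings differ.
#' @keywords internal
pt_same_structure <- function(mol_a, mol_b) {
  wa <- pt_write_smiles(mol_a)
  wb <- pt_write_smiles(mol_b)
  if (identical(wa, wb)) return(TRUE)
  identical(.pt_ob_canonical_batch(wa), .pt_ob_canonical_batch(wb))
}

#' Amide-preserving domain-knowledge fragmentation (Amiibo)
#'
#' Cuts every acyclic single bond between an amide nitrogen and its alpha
#' carbon (a carbon that itself bears an acyl carbon); the amide C(=O)-N bond
#' itself is never cut, and ring bonds are never cut. For an n-residue
#' proline-free linear canonical peptide this yields exactly n fragments.
#' Proline's N-Calpha bond lies in the pyrrolidine ring, so proline merges
#' with the preceding fragment.
#'
#' @param mol a `pep_mol`.
#' @return a `pep_fragmentation` with `method = "amiibo"`.
#' @export
amiibo_fragment <- function(mol) {
  stopifnot(inherits(mol, "pep_mol"))
  cut <- pt_amiibo_cut_bonds(mol)
  comps <- .pt_components(mol, drop_bonds = cut)
  pt_fragmentation(mol, comps, "amiibo")
}

#' Bond indices cut by the Amiibo rule
#' @keywords internal
pt_amiibo_cut_bonds <- function(mol) {
  b <- mol$bonds
  at <- mol$atoms
  amides <- .pt_amide_bonds(mol)
  amide_n <- unique(ifelse(at$element[b$a[amides]] == "N", b$a[amides], b$b[amides]))
  amide_c <- unique(ifelse(at$element[b$a[amides]] == "C", b$a[amides], b$b[amides]))
  # alpha carbon: aliphatic C attached to an acyl carbon (C with =O)
  acyl <- rep(FALSE, n_atoms(mol))
  acyl[amide_c] <- TRUE
  # terminal carboxyl carbons count as acyl anchors too
  dbl_o <- which(b$order == "double" &
    ((at$element[b$a] == "C" & at$element[b$b] == "O") |
     (at$element[b$b] == "C" & at$element[b$a] == "O")))
  acyl[ifelse(at$element[b$a[dbl_o]] == "C", b$a[dbl_o], b$b[dbl_o])] <- TRUE
  adj <- .pt_adjacency(mol)
  is_alpha <- vapply(seq_len(n_atoms(mol)), function(v) {
    at$element[v] == "C" && !at$aromatic[v] && any(acyl[adj[[v]]])
  }, logical(1))
  which(
    b$order == "single" & !b$in_ring &
      (((b$a %in% amide_n) & is_alpha[b$b] & !acyl[b$b]) |
       ((b$b %in% amide_n) & is_alpha[b$a] & !acyl[b$a]))
  )
}

#' Baseline fragmentations
#'
#' `atoms_only` places every atom in its own fragment (the plain molecular
#' graph baseline); `principal_subgraph` is a purely data-driven
#' fragmentation with no amide protection: the whole molecule is recursively
#' BRICS-split against a vocabulary learned without the domain-knowledge
#' stage (see [learn_vocabulary()] with `seed_method = "whole"`).
#'
#' @param mol a `pep_mol`.
#' @param mode `"atoms_only"` or `"principal_subgraph"`.
#' @param vocab a `fragment_vocabulary` (required for `principal_subgraph`).
#' @return a `pep_fragmentation`.
#' @export
baseline_fragment <- function(mol, mode = c("atoms_only", "principal_subgraph"),
                              vocab = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(mol, "pep_mol"))
  if (mode == "atoms_only") {
    return(pt_fragmentation(mol, as.list(seq_len(n_atoms(mol))), "atoms_only"))
  }
  if (is.null(vocab)) {
    stop("principal_subgraph mode requires a vocabulary learned without the Amiibo stage")
  }
  start <- unlist(lapply(.pt_components(mol), function(cp) brics_split(mol, cp)),
                  recursive = FALSE)
  frags <- .pt_vocab_guided_split(mol, start, vocab)
  pt_fragmentation(mol, frags, "principal_subgraph")
}

#' Reassemble a molecule from a fragmentation (round-trip oracle)
#'
#' Rebuilds the molecular graph from the fragment-induced subgraphs plus the
#' recorded cut bonds and returns it as a new `pep_mol`. By construction the
#' result has the same canonical key as the input; this is used as the
#' information-preservation oracle for all fragmentation methods.
#'
#' @param mol a `pep_mol`.
#' @param frag a `pep_fragmentation` produced from `mol`.
#' @return a `pep_mol`.
#' @export
reassemble <- function(mol, frag) {
  stopifnot(inherits(mol, "pep_mol"), inherits(frag, "pep_fragmentation"))
  n <- n_atoms(mol)
  if (frag$mol_n_atoms != n) stop("fragmentation does not belong to this molecule")
  all_idx <- unlist(frag$fragments)
  if (length(all_idx) != n || anyDuplicated(all_idx) ||
      any(all_idx < 1L | all_idx > n)) {
    stop("fragmentation integrity error: atom partition is invalid")
  }
  if (nrow(frag$cut_bonds) > 0L &&
      (any(frag$cut_bonds$a < 1L | frag$cut_bonds$a > n) ||
       any(frag$cut_bonds$b < 1L | frag$cut_bonds$b > n))) {
    stop("fragmentation integrity error: cut bond references a missing atom")
  }
  frag_of <- integer(n)
  for (i in seq_along(frag$fragments)) frag_of[frag$fragments[[i]]] <- i
  if (nrow(frag$cut_bonds) > 0L &&
      any(frag_of[frag$cut_bonds$a] == frag_of[frag$cut_bonds$b])) {
    stop("fragmentation integrity error: cut bond joins atoms of one fragment")
  }
  b <- mol$bonds
  internal <- which(frag_of[b$a] == frag_of[b$b])
  at <- mol$atoms
  bracket <- .pt_was_bracket(mol)
  pep_mol_from_parts(
    element = at$element, aromatic = at$aromatic, charge = at$charge,
    h_explicit = ifelse(bracket, at$n_h, NA_integer_),
    chirality = at$chirality, map = at$map, chiral_ref = mol$chiral_ref,
    bond_a = c(b$a[internal], frag$cut_bonds$a),
    bond_b = c(b$b[internal], frag$cut_bonds$b),
    bond_order = c(b$order[internal], frag$cut_bonds$order),
    source = mol$source, residue_of_atom = mol$residue_of_atom
  )
}
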