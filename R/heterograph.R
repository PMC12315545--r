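# The multi-view heterogeneous graph: atom nodes with chemical features,
# fragment nodes carrying vocabulary ids, atom-atom edges with bond features,
# fragment-fragment edges (one pair per cut bond), and junction edges linking
# every atom to its containing fragment. All edges are stored in both
# directions so message passing needs no symmetrization.

.pt_n_element_classes <- function() length(.pt_element_alphabet) # 12; mask = 13th

#' Build the atom/fragment/junction heterogeneous graph
#'
#' Feature encoding (all deterministic):
#' atom rows = (element class over \{C,N,O,S,P,F,Cl,Br,I,B,Se,other\},
#' degree bucket 0-5, formal charge bucket -2..+2, aromatic flag,
#' implicit-H bucket 0-4, chirality index none/CW/CCW); bond rows =
#' (order index, conjugated flag, in-ring flag); fragment nodes carry 0-based
#' vocabulary ids. Elements outside the alphabet map to the reserved
#' "other" class with a warning.
#'
#' @param mol a `pep_mol`.
#' @param frag a `pep_fragmentation` of `mol`.
#' @param vocab a `fragment_vocabulary` covering all fragment keys (use
#'   [adafrag_fragment()] to guarantee coverage).
#' @param mol_ref identifier stored on the graph.
#' @return a `hetero_graph` object.
#' @export
build_heterograph <- function(mol, frag, vocab, mol_ref = NA_character_) {
  stopifnot(inherits(mol, "pep_mol"), inherits(frag, "pep_fragmentation"),
            inherits(vocab, "fragment_vocabulary"))
  if (frag$mol_n_atoms != n_atoms(mol)) stop("fragmentation does not match molecule")
  at <- mol$atoms
  if (any(!at$element %in% .pt_element_alphabet)) {
    warning(sprintf(
      "element(s) %s outside the fixed alphabet mapped to 'other'",
      paste(unique(setdiff(at$element, .pt_element_alphabet)), collapse = ", ")
    ))
  }
  frag_ids <- .pt_fragment_ids(vocab, mol, frag)
  if (anyNA(frag_ids)) {
    stop("fragment key missing from vocabulary; encode with adafrag_fragment()")
  }

  atom_features <- cbind(
    element = .pt_element_class(at$element),                      # 1..12
    degree = pmin(at$degree, 5L),                                 # 0..5
    charge = pmax(pmin(at$charge, 2L), -2L) + 3L,                 # 1..5
    aromatic = as.integer(at$aromatic) + 1L,                      # 1..2
    n_h = pmin(at$n_h, 4L) + 1L,                                  # 1..5
    chirality = match(at$chirality, c("none", "cw", "ccw"))       # 1..3
  )
  atom_features[, "degree"] <- atom_features[, "degree"] + 1L     # 1..6

  b <- mol$bonds
  nb <- nrow(b)
  edges_aa <- if (nb > 0L) {
    cbind(from = c(b$a, b$b), to = c(b$b, b$a))
  } else matrix(integer(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  bond_features <- if (nb > 0L) {
    f <- cbind(
      order = match(b$order, c("single", "double", "triple", "aromatic")),
      conjugated = as.integer(b$conjugated) + 1L,
      in_ring = as.integer(b$in_ring) + 1L
    )
    rbind(f, f)
  } else matrix(integer(0), ncol = 3, dimnames = list(NULL, c("order", "conjugated", "in_ring")))

  cb <- frag$cut_bonds
  edges_ff <- if (nrow(cb) > 0L) {
    fa <- frag$fragment_of_atom[cb$a]; fb <- frag$fragment_of_atom[cb$b]
    cbind(from = c(fa, fb), to = c(fb, fa))
  } else matrix(integer(0), ncol = 2, dimnames = list(NULL, c("from", "to")))

  n <- n_atoms(mol)
  edges_junction <- rbind(
    cbind(atom = seq_len(n), fragment = frag$fragment_of_atom, dir = 1L),
    cbind(atom = seq_len(n), fragment = frag$fragment_of_atom, dir = 2L)
  )

  structure(
    list(
      atom_features = atom_features,
      fragment_ids = frag_ids,                 # 0-based vocabulary ids
      edges_aa = edges_aa, bond_features = bond_features,
      edges_ff = edges_ff,
      edges_junction = edges_junction,
      frag_of_atom = frag$fragment_of_atom,
      fragment_sizes = vapply(frag$fragments, length, integer(1)),
      n_atoms = n, n_fragments = length(frag$fragments),
      n_vocab = n_vocab(vocab),
      method = frag$method, mol_ref = mol_ref
    ),
    class = "hetero_graph"
  )
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf(
    "<hetero_graph> %d atom nodes, %d fragment nodes (%s); %d aa-, %d ff-, %d junction edges\n",
    x$n_atoms, x$n_fragments, x$method,
    nrow(x$edges_aa), nrow(x$edges_ff), nrow(x$edges_junction)
  ))
  invisible(x)
}

#' Dump a heterogeneous graph as JSON (debugging aid)
#'
#' All indices in the dump are 0-based.
#' @param graph a `hetero_graph`.
#' @param path output path.
#' @export
dump_heterograph <- function(graph, path) {
  obj <- list(
    mol_ref = graph$mol_ref,
    atom_features = unname(apply(graph$atom_features, 1, as.list)),
    fragment_ids = graph$fragment_ids,
    edges_aa = unname(apply(graph$edges_aa - 1L, 1, as.list)),
    edges_ff = unname(apply(graph$edges_ff - 1L, 1, as.list)),
    junction = unname(lapply(seq_len(graph$n_atoms), function(i) {
      list(atom = i - 1L, fragment = graph$frag_of_atom[i] - 1L)
    }))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Identify side-chain atoms of a peptide molecule
#'
#' The backbone is detected structurally: amide C(=O)-N units, the alpha
#' carbons linking an amide (or terminal amine) nitrogen to a carbonyl
#' carbon, carbonyl oxygens, terminal carboxyl oxygens and the terminal
#' amine nitrogen. Side chain = complement. Molecules with no identifiable
#' backbone return all atoms as side chain with a warning.
#'
#' @param mol a `pep_mol`.
#' @return integer vector of side-chain atom indices (1-based), with
#'   attributes `backbone` (the complement) and `no_backbone` (flag).
#' @export
side_chain_atoms <- function(mol) {
  stopifnot(inherits(mol, "pep_mol"))
  at <- mol$atoms
  b <- mol$bonds
  n <- n_atoms(mol)
  adj <- .pt_adjacency(mol)

  dbl_o_of <- vector("list", n) # carbonyl C -> its double-bonded O(s)
  for (k in which(b$order == "double")) {
    a <- b$a[k]; bb <- b$b[k]
    if (at$element[a] == "C" && at$element[bb] == "O") {
      dbl_o_of[[a]] <- c(dbl_o_of[[a]], bb)
    } else if (at$element[bb] == "C" && at$element[a] == "O") {
      dbl_o_of[[bb]] <- c(dbl_o_of[[bb]], a)
    }
  }
  carbonyl <- which(vapply(dbl_o_of, length, integer(1)) > 0L & !at$aromatic)

  backbone <- rep(FALSE, n)
  # alpha carbons first: aliphatic C adjacent to both a carbonyl C and a
  # non-aromatic N; pull in that N (amide or terminal amine) and the carbonyl
  # group including terminal hydroxyls
  for (v in seq_len(n)) {
    if (at$element[v] != "C" || at$aromatic[v]) next
    nbrs <- adj[[v]]
    cs <- intersect(nbrs, carbonyl)
    ns <- nbrs[at$element[nbrs] == "N" & !at$aromatic[nbrs]]
    if (length(cs) == 0L || length(ns) == 0L) next
    backbone[v] <- TRUE
    backbone[ns] <- TRUE
    for (cC in cs) {
      backbone[cC] <- TRUE
      backbone[dbl_o_of[[cC]]] <- TRUE
      oh <- adj[[cC]][at$element[adj[[cC]]] == "O" & at$degree[adj[[cC]]] == 1L]
      backbone[oh] <- TRUE
    }
  }
  # chain amide units anchored to the backbone (leaves side-chain amides of
  # Asn/Gln alone); covers capping groups on either terminus
  for (k in .pt_amide_bonds(mol)) {
    cC <- if (at$element[b$a[k]] == "C") b$a[k] else b$b[k]
    nN <- if (cC == b$a[k]) b$b[k] else b$a[k]
    if (backbone[cC] || backbone[nN]) {
      backbone[c(cC, nN, dbl_o_of[[cC]])] <- TRUE
    }
  }

  if (!any(backbone)) {
    warning("no peptide backbone identified; returning all atoms as side chain")
    out <- seq_len(n)
    attr(out, "backbone") <- integer(0)
    attr(out, "no_backbone") <- TRUE
    return(out)
  }
  out <- which(!backbone)
  attr(out, "backbone") <- which(backbone)
  attr(out, "no_backbone") <- FALSE
  out
}
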