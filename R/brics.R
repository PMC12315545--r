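# Native implementation of BRICS bond finding (Degen et al., ChemMedChem 2008,
# with the revised unified amine environment L5 used by standard toolkits).
# Each environment is an atom-centred predicate on the molecular graph; a
# BRICS bond is a non-ring single bond (double for the alkene rule 7) whose
# two ends match a compatible environment pair.

.pt_brics_pairs_single <- list(
  c(1, 3), c(1, 5), c(1, 10),
  c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
  c(4, 5), c(4, 11),
  c(5, 12), c(5, 13), c(5, 14), c(5, 15), c(5, 16),
  c(6, 13), c(6, 14), c(6, 15), c(6, 16),
  c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
  c(9, 13), c(9, 14), c(9, 15), c(9, 16),
  c(10, 13), c(10, 14), c(10, 15), c(10, 16),
  c(11, 13), c(11, 14), c(11, 15), c(11, 16),
  c(13, 14), c(13, 15), c(13, 16),
  c(14, 14), c(14, 15), c(14, 16),
  c(15, 16),
  c(16, 16)
)

# per-atom incident-bond view: list of lists (nbr, order, ring vectors)
.pt_bond_env <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  nb <- nrow(b)
  inc <- unname(split(c(seq_len(nb), seq_len(nb)),
                      factor(c(b$a, b$b), levels = seq_len(n))))
  lapply(seq_len(n), function(v) {
    ks <- inc[[v]]
    list(nbr = ifelse(b$a[ks] == v, b$b[ks], b$a[ks]),
         order = b$order[ks], ring = b$in_ring[ks])
  })
}

# environment membership matrix: n_atoms x 16 logical
.pt_brics_envs <- function(mol) {
  at <- mol$atoms
  n <- nrow(at)
  be <- .pt_bond_env(mol)
  ring_atom <- mol$atom_in_ring
  el <- at$element
  arom <- at$aromatic

  env <- matrix(FALSE, n, 16)
  for (v in seq_len(n)) {
    nb <- be[[v]]
    nbr <- nb$nbr; ord <- nb$order; rng <- nb$ring
    deg <- length(nbr)
    is_c <- el[v] == "C" && !arom[v]
    is_n <- el[v] == "N" && !arom[v]
    dbl_o <- ord == "double" & el[nbr] == "O"

    if (is_c && deg == 3L && any(dbl_o)) {
      oth <- !dbl_o
      if (any(el[nbr[oth]] %in% c("C", "N", "O"))) env[v, 1] <- TRUE        # L1
      if (!ring_atom[v] &&
          any(oth & ord == "single" & !rng &
              el[nbr] %in% c("C", "N", "O"))) env[v, 6] <- TRUE             # L6
    }
    if (el[v] == "O" && !arom[v] && deg == 2L &&
        any(ord == "single" & !rng & el[nbr] == "C")) env[v, 3] <- TRUE     # L3
    if (is_c && deg >= 2L && !any(ord == "double") &&
        any(ord == "single" & !rng & el[nbr] == "C")) env[v, 4] <- TRUE     # L4
    if (is_n && deg >= 2L && !any(ord == "double")) {
      singles <- nbr[ord == "single"]
      ok_elem <- all(el[singles] %in% c("C", "S"))
      lactam <- FALSE
      if (ring_atom[v]) {
        ring_c <- nbr[rng & el[nbr] == "C"]
        for (w in ring_c) {
          wb <- be[[w]]
          if (ring_atom[w] &&
              any(wb$order == "double" & el[wb$nbr] == "O")) lactam <- TRUE
        }
      }
      if (ok_elem && !lactam) env[v, 5] <- TRUE                             # L5
    }
    if (is_c && deg %in% c(2L, 3L) &&
        any(ord == "single" & el[nbr] == "C")) env[v, 7] <- TRUE            # L7
    if (is_c && !ring_atom[v] && deg >= 2L && all(ord == "single")) env[v, 8] <- TRUE
    if (el[v] == "N" && arom[v] && at$charge[v] == 0L &&
        sum(ord == "aromatic" & arom[nbr] &
            el[nbr] %in% c("C", "N", "O", "S")) >= 2L) env[v, 9] <- TRUE    # L9
    if (is_n && ring_atom[v]) {
      ring_nb <- nbr[rng]
      cand <- ring_nb[el[ring_nb] == "C" & !arom[ring_nb]]
      lact_c <- cand[vapply(cand, function(w) {
        any(be[[w]]$order == "double" & el[be[[w]]$nbr] == "O")
      }, logical(1))]
      if (length(lact_c) >= 1L) {
        others <- setdiff(ring_nb, lact_c[[1]])
        if (any(el[others] %in% c("C", "N", "O", "S") & !arom[others])) env[v, 10] <- TRUE
      }
    }
    if (el[v] == "S" && !arom[v] && deg == 2L &&
        any(ord == "single" & !rng & el[nbr] == "C")) env[v, 11] <- TRUE    # L11
    if (el[v] == "S" && deg == 4L &&
        sum(ord == "double" & el[nbr] == "O") == 2L &&
        any(el[nbr] == "C")) env[v, 12] <- TRUE                             # L12
    if (is_c) {
      rs <- rng & ord == "single" & !arom[nbr]
      s1 <- nbr[rs & el[nbr] %in% c("C", "N", "O", "S")]
      s2 <- nbr[rs & el[nbr] %in% c("N", "O", "S")]
      if (length(s1) >= 2L && length(s2) >= 1L) env[v, 13] <- TRUE          # L13
      if (sum(rs & el[nbr] == "C") >= 2L) env[v, 15] <- TRUE                # L15
    }
    if (el[v] == "C" && arom[v]) {
      ar <- ord == "aromatic" & arom[nbr]
      a1 <- nbr[ar & el[nbr] %in% c("C", "N", "O", "S")]
      a2 <- nbr[ar & el[nbr] %in% c("N", "O", "S")]
      if (length(a1) >= 2L && length(a2) >= 1L) env[v, 14] <- TRUE          # L14
      if (sum(el[nbr[ar]] == "C") >= 2L) env[v, 16] <- TRUE                 # L16
    }
  }
  env
}

#' Find BRICS-cleavable bonds of a molecule
#'
#' @param mol a `pep_mol`.
#' @return integer vector of bond row indices into `mol$bonds`.
#' @keywords internal
pt_find_brics_bonds <- function(mol) {
  env <- .pt_brics_envs(mol)
  b <- mol$bonds
  out <- integer(0)
  for (k in seq_len(nrow(b))) {
    if (b$in_ring[k]) next
    a <- b$a[k]; bb <- b$b[k]
    if (b$order[k] == "single") {
      hit <- FALSE
      for (p in .pt_brics_pairs_single) {
        if ((env[a, p[1]] && env[bb, p[2]]) || (env[a, p[2]] && env[bb, p[1]])) {
          hit <- TRUE; break
        }
      }
      if (hit) out <- c(out, k)
    } else if (b$order[k] == "double") {
      if (env[a, 7] && env[bb, 7]) out <- c(out, k)                          # L7=L7
    }
  }
  out
}

# induced subgraph as a standalone molecule (attributes copied, hydrogens and
# perception recomputed); returns list(mol, parent_idx)
.pt_induced_submol <- function(mol, subset) {
  subset <- sort(unique(as.integer(subset)))
  keep <- rep(FALSE, n_atoms(mol)); keep[subset] <- TRUE
  remap <- rep(NA_integer_, n_atoms(mol)); remap[subset] <- seq_along(subset)
  b <- mol$bonds
  use <- which(keep[b$a] & keep[b$b])
  at <- mol$atoms
  sm <- pep_mol_from_parts(
    element = at$element[subset], aromatic = at$aromatic[subset],
    charge = at$charge[subset], h_explicit = rep(NA_integer_, length(subset)),
    chirality = rep("none", length(subset)), map = rep(0L, length(subset)),
    chiral_ref = rep(list(integer(0)), length(subset)),
    bond_a = remap[b$a[use]], bond_b = remap[b$b[use]],
    bond_order = b$order[use], source = mol$source
  )
  list(mol = sm, parent_idx = subset)
}

#' Split an atom subset at its internal BRICS bonds
#'
#' The subset is treated as a standalone molecule (its induced subgraph, cut
#' bonds capped); all BRICS-rule bonds internal to it are cut and the
#' resulting connected components returned. A subset with no BRICS bonds is
#' returned unchanged as a singleton list.
#'
#' @param mol a `pep_mol`.
#' @param atom_subset atom indices (1-based) inducing a connected subgraph.
#' @return list of sorted atom-index vectors (parent indexing).
#' @export
brics_split <- function(mol, atom_subset) {
  stopifnot(inherits(mol, "pep_mol"))
  comps <- .pt_components(mol, atom_subset)
  if (length(comps) != 1L) stop("atom_subset induces a disconnected subgraph")
  sub <- .pt_induced_submol(mol, atom_subset)
  cut <- pt_find_brics_bonds(sub$mol)
  if (length(cut) == 0L) return(list(sort(unique(as.integer(atom_subset)))))
  pieces <- .pt_components(sub$mol, seq_len(n_atoms(sub$mol)), drop_bonds = cut)
  lapply(pieces, function(p) sub$parent_idx[p])
}
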