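# Valence model used for implicit-hydrogen completion. S and P are allowed the
# usual hypervalent states; everything else has a single default valence.
.pt_default_valences <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Se = 2
)

.pt_organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "*")

.pt_bond_orders <- c(single = 1, double = 2, triple = 3, aromatic = 1)

#' Parse a SMILES string into a molecular graph
#'
#' A self-contained SMILES reader producing the heavy-atom graph used
#' throughout the package: element, formal charge, aromatic flag, implicit
#' hydrogen count, tetrahedral chirality (with the neighbour ordering needed
#' to re-emit it), and typed bonds. Hydrogens are implicit; explicit bracket
#' hydrogen counts are honoured. E/Z markers (`/`, `\`) are read as plain
#' single bonds. Ring membership and conjugation are perceived after parsing.
#'
#' This reader is strict: unbalanced brackets, unclosed rings, dangling bond
#' symbols or unknown element symbols raise errors rather than being patched,
#' which makes it the package's validation front-end for user input.
#'
#' @param smiles a single SMILES string.
#' @param source provenance tag stored on the molecule, `"smiles"` or
#'   `"sequence"`.
#' @return an object of class `pep_mol`; see [pep_mol()].
#' @keywords internal
pt_parse_smiles <- function(smiles, source = "smiles") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single string")
  }
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)

  # growing atom store
  elem <- character(0); arom <- logical(0); chg <- integer(0)
  hexp <- integer(0)   # NA_integer_ -> implicit fill
  chir <- character(0) # "none", "cw" (@@), "ccw" (@)
  amap <- integer(0)
  events <- list()     # per atom: ordered neighbour tokens (atom id, 0 = implicit H,
                       # negative = unresolved ring-closure placeholder)
  bonds_a <- integer(0); bonds_b <- integer(0); bonds_o <- character(0)

  branch_stack <- integer(0)
  prev <- NA_integer_
  pending <- NULL          # explicit bond symbol awaiting its second atom
  ring_open <- list()      # digit -> list(atom, bond, ph)
  ph_counter <- 0L
  multi <- FALSE

  bond_name <- function(sym) switch(sym,
    "-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic",
    "/" = "single", "\\" = "single",
    stop(sprintf("unsupported bond symbol '%s'", sym)))

  add_atom <- function(el, aromatic, charge, h, chirality, map) {
    elem[[length(elem) + 1L]] <<- el
    arom[[length(arom) + 1L]] <<- aromatic
    chg[[length(chg) + 1L]] <<- charge
    hexp[[length(hexp) + 1L]] <<- h
    chir[[length(chir) + 1L]] <<- chirality
    amap[[length(amap) + 1L]] <<- map
    events[[length(events) + 1L]] <<- integer(0)
    length(elem)
  }

  add_bond <- function(a, b, order) {
    if (a == b) stop("self-bond in SMILES")
    bonds_a[[length(bonds_a) + 1L]] <<- a
    bonds_b[[length(bonds_b) + 1L]] <<- b
    bonds_o[[length(bonds_o) + 1L]] <<- order
  }

  resolve_default <- function(a, b) {
    if (arom[[a]] && arom[[b]]) "aromatic" else "single"
  }

  close_ring <- function(digit, atom_id) {
    entry <- ring_open[[digit]]
    if (is.null(entry)) {
      # opening a ring bond: placeholder in this atom's event list
      ph_counter <<- ph_counter + 1L
      ph <- -ph_counter
      events[[atom_id]] <<- c(events[[atom_id]], ph)
      ring_open[[digit]] <<- list(atom = atom_id, bond = pending, ph = ph)
      pending <<- NULL
    } else {
      other <- entry$atom
      if (other == atom_id) stop("ring closure to the same atom")
      ob <- entry$bond; cb <- pending; pending <<- NULL
      ordsym <- if (!is.null(ob) && !is.null(cb)) {
        if (bond_name(ob) != bond_name(cb)) stop("conflicting ring-closure bond orders")
        ob
      } else if (!is.null(ob)) ob else cb
      order <- if (is.null(ordsym)) resolve_default(other, atom_id) else bond_name(ordsym)
      add_bond(other, atom_id, order)
      ev <- events[[other]]
      ev[ev == entry$ph] <- atom_id
      events[[other]] <<- ev
      events[[atom_id]] <<- c(events[[atom_id]], other)
      ring_open[[digit]] <<- NULL
    }
  }

  new_atom_common <- function(id) {
    if (!is.na(prev)) {
      order <- if (is.null(pending)) resolve_default(prev, id) else bond_name(pending)
      add_bond(prev, id, order)
      events[[prev]] <<- c(events[[prev]], id)
      events[[id]] <<- c(events[[id]], prev)
      pending <<- NULL
    } else if (!is.null(pending)) {
      stop("bond symbol with no preceding atom")
    }
    # bracket implicit H of a chiral atom acts as a neighbour right after the
    # preceding atom (OpenSMILES convention)
    if (chir[[id]] != "none" && !is.na(hexp[[id]]) && hexp[[id]] > 0L) {
      events[[id]] <<- c(events[[id]], 0L)
    }
    prev <<- id
  }

  i <- 1L
  while (i <= n_ch) {
    ch <- chars[[i]]
    if (ch == "(") {
      if (is.na(prev)) stop("branch start with no current atom")
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L) stop("unbalanced ')' in SMILES")
      prev <- branch_stack[[length(branch_stack)]]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.null(pending)) stop("two consecutive bond symbols")
      pending <- ch
      i <- i + 1L
    } else if (ch == ".") {
      multi <- TRUE
      prev <- NA_integer_
      if (!is.null(pending)) stop("bond symbol before '.'")
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      if (is.na(prev)) stop("ring-closure digit with no current atom")
      close_ring(ch, prev)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n_ch || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop("malformed %nn ring closure")
      }
      if (is.na(prev)) stop("ring-closure digit with no current atom")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), prev)
      i <- i + 3L
    } else if (ch == "[") {
      j <- i
      while (j <= n_ch && chars[[j]] != "]") j <- j + 1L
      if (j > n_ch) stop("unclosed '[' in SMILES")
      body <- substr(s, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]*)(se|as|[A-Z][a-z]?|[bcnops]|\\*)(@{1,2})?(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])?(?::([0-9]+))?$",
        body))[[1]]
      if (length(m) == 0L) stop(sprintf("cannot parse bracket atom '[%s]'", body))
      sym <- m[[3]]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      el <- if (sym == "*") "*" else {
        e <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
        if (aromatic && nchar(sym) == 1L) toupper(sym) else e
      }
      chirality <- if (m[[4]] == "@") "ccw" else if (m[[4]] == "@@") "cw" else "none"
      h <- if (m[[5]] == "") 0L
           else if (m[[5]] == "H") 1L
           else as.integer(sub("H", "", m[[5]], fixed = TRUE))
      charge <- 0L
      cg <- m[[6]]
      if (nzchar(cg)) {
        charge <- if (grepl("^[+-][0-9]$", cg)) {
          as.integer(substr(cg, 2, 2)) * (if (substr(cg, 1, 1) == "+") 1L else -1L)
        } else nchar(cg) * (if (substr(cg, 1, 1) == "+") 1L else -1L)
      }
      map <- if (nzchar(m[[7]])) as.integer(m[[7]]) else 0L
      id <- add_atom(el, aromatic, charge, h, chirality, map)
      new_atom_common(id)
      i <- j + 1L
    } else {
      # organic-subset atom, possibly two characters (Cl, Br)
      two <- if (i < n_ch) paste0(ch, chars[[i + 1L]]) else ""
      if (two %in% c("Cl", "Br")) {
        id <- add_atom(two, FALSE, 0L, NA_integer_, "none", 0L)
        new_atom_common(id); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        id <- add_atom(ch, FALSE, 0L, NA_integer_, "none", 0L)
        new_atom_common(id); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        id <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, "none", 0L)
        new_atom_common(id); i <- i + 1L
      } else if (ch == "*") {
        id <- add_atom("*", FALSE, 0L, NA_integer_, "none", 0L)
        new_atom_common(id); i <- i + 1L
      } else if (ch %in% c(" ", "\t")) {
        break # SMILES line titles
      } else {
        stop(sprintf("unexpected character '%s' at position %d in SMILES", ch, i))
      }
    }
  }
  if (length(branch_stack) > 0L) stop("unbalanced '(' in SMILES")
  if (length(ring_open) > 0L && any(!vapply(ring_open, is.null, logical(1)))) {
    stop("unclosed ring bond in SMILES")
  }
  if (!is.null(pending)) stop("dangling bond symbol at end of SMILES")
  if (length(elem) == 0L) stop("SMILES contains no atoms")

  dup <- paste(pmin(bonds_a, bonds_b), pmax(bonds_a, bonds_b))
  if (anyDuplicated(dup)) stop("duplicate bond in SMILES")

  pep_mol_from_parts(
    element = elem, aromatic = arom, charge = chg, h_explicit = hexp,
    chirality = chir, map = amap, chiral_ref = events,
    bond_a = bonds_a, bond_b = bonds_b, bond_order = bonds_o,
    source = source, smiles = s, multi_component = multi
  )
}

#' Assemble a `pep_mol` from raw atom/bond vectors
#'
#' Completes implicit hydrogens from the valence model, perceives ring
#' membership (bridge detection) and conjugation, and freezes the result as a
#' `pep_mol`. Used by the SMILES reader and by the monomer condensation code.
#' @keywords internal
pep_mol_from_parts <- function(element, aromatic, charge, h_explicit, chirality,
                               map, chiral_ref, bond_a, bond_b, bond_order,
                               source, smiles = NA_character_,
                               multi_component = FALSE,
                               residue_of_atom = NULL) {
  n <- length(element)
  nb <- length(bond_a)
  deg <- tabulate(c(bond_a, bond_b), nbins = n)

  ordv <- .pt_bond_orders[bond_order]
  bondsum <- numeric(n)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      bondsum[bond_a[k]] <- bondsum[bond_a[k]] + ordv[k]
      bondsum[bond_b[k]] <- bondsum[bond_b[k]] + ordv[k]
    }
  }
  bondsum <- bondsum + as.numeric(aromatic) # aromatic system contributes one

  n_h <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(h_explicit[i])) { n_h[i] <- h_explicit[i]; next }
    el <- element[i]
    if (el == "*" || is.null(.pt_default_valences[[el]])) { n_h[i] <- 0L; next }
    vals <- .pt_default_valences[[el]]
    adj <- if (el %in% c("N", "O", "P", "S")) charge[i] else -abs(charge[i])
    vals <- vals + adj
    bs <- bondsum[i]
    fit <- vals[vals >= bs]
    n_h[i] <- if (length(fit) == 0L) 0L else as.integer(round(fit[[1]] - bs))
  }

  in_ring_bond <- if (nb > 0L) !.pt_find_bridges(n, bond_a, bond_b) else logical(0)
  atom_ring <- logical(n)
  if (nb > 0L) {
    for (k in which(in_ring_bond)) {
      atom_ring[bond_a[k]] <- TRUE; atom_ring[bond_b[k]] <- TRUE
    }
  }

  # conjugation: a bond is conjugated if aromatic, or if both endpoints can
  # take part in a pi system (carry a multiple/aromatic bond, or are N/O/S
  # with a lone pair) and at least one end carries a multiple/aromatic bond.
  has_pi <- logical(n)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      if (bond_order[k] %in% c("double", "triple", "aromatic")) {
        has_pi[bond_a[k]] <- TRUE; has_pi[bond_b[k]] <- TRUE
      }
    }
  }
  lone <- element %in% c("N", "O", "S") & charge >= 0L
  conj <- logical(nb)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      a <- bond_a[k]; b <- bond_b[k]
      if (bond_order[k] == "aromatic") { conj[k] <- TRUE; next }
      ok_a <- has_pi[a] || lone[a]; ok_b <- has_pi[b] || lone[b]
      conj[k] <- ok_a && ok_b && (has_pi[a] || has_pi[b])
    }
  }

  atoms <- data.frame(
    element = element, charge = charge, aromatic = aromatic,
    degree = deg, n_h = n_h, chirality = chirality, map = map,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    a = bond_a, b = bond_b, order = bond_order,
    in_ring = in_ring_bond, conjugated = conj,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      atoms = atoms, bonds = bonds, chiral_ref = chiral_ref,
      atom_in_ring = atom_ring,
      residue_of_atom = residue_of_atom,
      source = source, smiles = smiles, multi_component = multi_component
    ),
    class = "pep_mol"
  )
}

# Tarjan bridge finding (iterative); returns logical per bond: TRUE if bridge.
.pt_find_bridges <- function(n, bond_a, bond_b) {
  nb <- length(bond_a)
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[bond_a[k]]] <- c(adj[[bond_a[k]]], k)
    adj[[bond_b[k]]] <- c(adj[[bond_b[k]]], k)
  }
  disc <- integer(n); low <- integer(n)
  bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack_v <- root; stack_pe <- 0L; stack_ci <- 1L
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack_v) > 0L) {
      top <- length(stack_v)
      v <- stack_v[top]; pe <- stack_pe[top]; ci <- stack_ci[top]
      edges <- adj[[v]]
      if (ci <= length(edges)) {
        stack_ci[top] <- ci + 1L
        e <- edges[ci]
        if (e == pe) next
        w <- if (bond_a[e] == v) bond_b[e] else bond_a[e]
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack_v <- c(stack_v, w); stack_pe <- c(stack_pe, e); stack_ci <- c(stack_ci, 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        stack_v <- stack_v[-top]; stack_pe <- stack_pe[-top]; stack_ci <- stack_ci[-top]
        if (length(stack_v) > 0L) {
          p <- stack_v[length(stack_v)]
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) bridge[pe] <- TRUE
        }
      }
    }
  }
  bridge
}

#' Number of heavy atoms in a molecule
#' @param mol a `pep_mol`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Number of bonds in a molecule
#' @param mol a `pep_mol`.
#' @return integer bond count.
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

#' @export
print.pep_mol <- function(x, ...) {
  cat(sprintf(
    "<pep_mol> %d heavy atoms, %d bonds%s (source: %s)\n",
    n_atoms(x), n_bonds(x),
    if (!is.null(x$residue_of_atom)) sprintf(", %d residues", max(x$residue_of_atom)) else "",
    x$source
  ))
  invisible(x)
}

# adjacency list (atom id -> integer vector of neighbour atom ids)
.pt_adjacency <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  unname(split(c(b$b, b$a), factor(c(b$a, b$b), levels = seq_len(n))))
}

# connected components over an atom subset; returns list of sorted index sets
.pt_components <- function(mol, subset = seq_len(n_atoms(mol)), drop_bonds = integer(0)) {
  n <- n_atoms(mol)
  keep <- rep(FALSE, n); keep[subset] <- TRUE
  b <- mol$bonds
  use <- keep[b$a] & keep[b$b]
  if (length(drop_bonds) > 0L) use[drop_bonds] <- FALSE
  ua <- b$a[use]; ub <- b$b[use]
  adj <- unname(split(c(ub, ua), factor(c(ua, ub), levels = seq_len(n))))
  seen <- rep(FALSE, n)
  out <- list()
  for (s0 in subset) {
    if (seen[s0]) next
    comp <- integer(0); queue <- s0; seen[s0] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[[length(queue)]]; queue <- queue[-length(queue)]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}
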