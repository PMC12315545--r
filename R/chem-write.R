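# SMILES emission. The writer is deterministic (children visited in atom-index
# order) but makes no attempt to be canonical: canonical form is delegated to
# OpenBabel (see canonical_key()). Cut bonds of a subset are capped with
# implicit hydrogens by valence refill.

#' Write a molecule (or an induced subgraph) as SMILES
#'
#' @param mol a `pep_mol`.
#' @param subset atom indices (1-based, default all). The induced subgraph
#'   must be connected unless the full molecule is written.
#' @param keep_stereo keep tetrahedral tags where every reference neighbour of
#'   the chiral atom is still present; tags on atoms that lost a neighbour to
#'   a cut are dropped (their stereochemistry is no longer defined).
#' @return a SMILES string.
#' @keywords internal
pt_write_smiles <- function(mol, subset = seq_len(n_atoms(mol)), keep_stereo = TRUE) {
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) stop("empty atom subset")
  n <- n_atoms(mol)
  if (any(subset < 1L | subset > n)) stop("atom subset out of range")
  keep <- rep(FALSE, n); keep[subset] <- TRUE

  at <- mol$atoms
  b <- mol$bonds
  internal <- which(keep[b$a] & keep[b$b])
  # hydrogen caps owed per atom for bonds leaving the subset; a cut double
  # bond is capped with two hydrogens, a triple with three
  cuts <- integer(n)
  n_cut_bonds <- integer(n)
  half <- which(xor(keep[b$a], keep[b$b]))
  for (k in half) {
    v <- if (keep[b$a[k]]) b$a[k] else b$b[k]
    cuts[v] <- cuts[v] + as.integer(.pt_bond_orders[[b$order[k]]])
    n_cut_bonds[v] <- n_cut_bonds[v] + 1L
  }

  adj <- vector("list", n)       # neighbour -> bond id within subset
  for (k in internal) {
    adj[[b$a[k]]] <- rbind(adj[[b$a[k]]], c(b$b[k], k))
    adj[[b$b[k]]] <- rbind(adj[[b$b[k]]], c(b$a[k], k))
  }

  # DFS spanning tree, children in ascending atom index
  root <- subset[[1]]
  parent <- rep(NA_integer_, n)
  order_children <- vector("list", n)
  visited <- rep(FALSE, n)
  ring_bonds <- list() # each: c(bond_id, a, b)
  tree_edge <- rep(FALSE, nrow(b))
  stack <- root; visited[root] <- TRUE
  # iterative DFS preserving child order
  dfs_stack <- list(list(v = root, nbrs = NULL, i = 1L))
  get_nbrs <- function(v) {
    m <- adj[[v]]
    if (is.null(m)) return(matrix(integer(0), ncol = 2))
    m[order(m[, 1]), , drop = FALSE]
  }
  dfs_stack[[1]]$nbrs <- get_nbrs(root)
  seen_bond <- rep(FALSE, nrow(b))
  while (length(dfs_stack) > 0L) {
    fr <- dfs_stack[[length(dfs_stack)]]
    if (fr$i > nrow(fr$nbrs)) { dfs_stack[[length(dfs_stack)]] <- NULL; next }
    dfs_stack[[length(dfs_stack)]]$i <- fr$i + 1L
    w <- fr$nbrs[fr$i, 1]; e <- fr$nbrs[fr$i, 2]
    if (seen_bond[e]) next
    seen_bond[e] <- TRUE
    if (!visited[w]) {
      visited[w] <- TRUE
      parent[w] <- fr$v
      tree_edge[e] <- TRUE
      order_children[[fr$v]] <- c(order_children[[fr$v]], w)
      fr2 <- list(v = w, nbrs = get_nbrs(w), i = 1L)
      dfs_stack[[length(dfs_stack) + 1L]] <- fr2
    } else {
      ring_bonds[[length(ring_bonds) + 1L]] <- c(e, fr$v, w)
    }
  }
  if (!all(visited[subset])) stop("atom subset induces a disconnected subgraph")

  # ring-closure digits: assign in DFS discovery order of the second-seen end
  ring_digit <- list() # atom id -> list of c(partner, bond_id, digit)
  digit_ctr <- 0L
  for (rb in ring_bonds) {
    digit_ctr <- digit_ctr + 1L
    d <- if (digit_ctr < 10L) as.character(digit_ctr) else sprintf("%%%02d", digit_ctr)
    for (end in c(rb[2], rb[3])) {
      other <- if (end == rb[2]) rb[3] else rb[2]
      ring_digit[[as.character(end)]] <- c(
        ring_digit[[as.character(end)]],
        list(list(partner = other, bond = rb[1], digit = d))
      )
    }
  }

  # aromaticity survives a cut only as a whole system: an aromatic atom stays
  # aromatic iff it keeps >= 2 aromatic bonds inside the subset; keeping
  # exactly one is a partially dismembered ring and cannot be capped
  n_arom_sub <- integer(n)
  for (k in internal) {
    if (b$order[k] == "aromatic") {
      n_arom_sub[b$a[k]] <- n_arom_sub[b$a[k]] + 1L
      n_arom_sub[b$b[k]] <- n_arom_sub[b$b[k]] + 1L
    }
  }
  arom_sub <- at$aromatic & n_arom_sub >= 2L
  if (any(at$aromatic[subset] & !arom_sub[subset] & n_arom_sub[subset] == 1L)) {
    stop("cannot cap a partially retained aromatic system")
  }

  bond_sym <- function(k, from_arom, to_arom) {
    switch(b$order[k],
      single = if (from_arom && to_arom) "-" else "",
      double = "=", triple = "#",
      aromatic = "")
  }

  bondsum_sub <- numeric(n)
  for (k in internal) {
    o <- .pt_bond_orders[[b$order[k]]]
    bondsum_sub[b$a[k]] <- bondsum_sub[b$a[k]] + o
    bondsum_sub[b$b[k]] <- bondsum_sub[b$b[k]] + o
  }
  bondsum_sub <- bondsum_sub + as.numeric(arom_sub)

  refill_h <- function(v) {
    el <- at$element[v]
    if (el == "*" || is.null(.pt_default_valences[[el]])) return(0L)
    vals <- .pt_default_valences[[el]]
    adj_v <- if (el %in% c("N", "O", "P", "S")) at$charge[v] else -abs(at$charge[v])
    vals <- vals + adj_v
    fit <- vals[vals >= bondsum_sub[v]]
    if (length(fit) == 0L) 0L else as.integer(round(fit[[1]] - bondsum_sub[v]))
  }

  # desired H counts: stored implicit H plus one cap per cut bond; atoms that
  # lost their aromatic system are capped by plain valence refill
  desired_h <- at$n_h + cuts
  dearom <- which(at$aromatic & !arom_sub)
  for (v in dearom) desired_h[v] <- refill_h(v)

  stereo_kept <- rep(FALSE, n)
  if (keep_stereo) {
    for (v in subset) {
      if (at$chirality[v] == "none") next
      ref <- mol$chiral_ref[[v]]
      nb_ids <- ref[ref > 0L]
      if (cuts[v] == 0L && all(keep[nb_ids])) stereo_kept[v] <- TRUE
    }
  }

  atom_token <- function(v, out_order) {
    el <- at$element[v]
    aromatic <- arom_sub[v]
    sym <- if (aromatic) tolower(el) else el
    h <- desired_h[v]
    need_bracket <- at$charge[v] != 0L || el == "*" ||
      !(el %in% .pt_organic_subset) ||
      stereo_kept[v] ||
      (is.na(match(el, "*")) && refill_h(v) != h)
    if (aromatic && el %in% c("N", "O", "S", "P") && h > 0L) need_bracket <- TRUE
    if (aromatic && nchar(el) == 2L) need_bracket <- TRUE # [se]
    if (!need_bracket) return(sym)
    tag <- ""
    if (stereo_kept[v]) {
      ref <- mol$chiral_ref[[v]]
      par <- .pt_perm_parity(ref, out_order)
      cw <- at$chirality[v] == "cw"
      if (par %% 2L == 1L) cw <- !cw
      tag <- if (cw) "@@" else "@"
    }
    hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- at$charge[v]
    cstr <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
            else sprintf("%+d", ch)
    paste0("[", sym, tag, hstr, cstr, "]")
  }

  emit <- function(v, parent_v, parent_bond) {
    # output neighbour order: parent, implicit H (if bracketed w/ H & stereo),
    # ring closures in digit order, children in written order
    rd <- ring_digit[[as.character(v)]]
    kids <- order_children[[v]]
    out_order <- integer(0)
    if (!is.na(parent_v)) out_order <- parent_v
    if (stereo_kept[v] && desired_h[v] > 0L) out_order <- c(out_order, 0L)
    if (!is.null(rd)) out_order <- c(out_order, vapply(rd, function(z) z$partner, integer(1)))
    out_order <- c(out_order, kids)
    tok <- atom_token(v, out_order)
    s <- tok
    if (!is.null(rd)) {
      for (z in rd) {
        bs <- bond_sym(z$bond, arom_sub[v], arom_sub[z$partner])
        s <- paste0(s, bs, z$digit)
      }
    }
    if (length(kids) > 0L) {
      for (i in seq_along(kids)) {
        w <- kids[[i]]
        e <- tree_bond_id(v, w)
        bs <- bond_sym(e, arom_sub[v], arom_sub[w])
        child_s <- paste0(bs, emit(w, v, e))
        if (i < length(kids)) s <- paste0(s, "(", child_s, ")")
        else s <- paste0(s, child_s)
      }
    }
    s
  }

  tree_bond_map <- new.env(hash = TRUE)
  for (k in which(tree_edge)) {
    assign(paste(b$a[k], b$b[k]), k, envir = tree_bond_map)
    assign(paste(b$b[k], b$a[k]), k, envir = tree_bond_map)
  }
  tree_bond_id <- function(v, w) get(paste(v, w), envir = tree_bond_map)

  emit(root, NA_integer_, NA_integer_)
}

# parity (number of inversions mod 2) of the permutation taking `ref` to `out`;
# both are neighbour-id sequences, 0 denoting the implicit hydrogen.
.pt_perm_parity <- function(ref, out) {
  ref <- as.integer(ref); out <- as.integer(out)
  if (length(ref) != length(out) || !setequal(ref, out)) return(0L)
  perm <- match(out, ref)
  inv <- 0L
  np <- length(perm)
  for (i in seq_len(np - 1L)) {
    for (j in seq(i + 1L, np)) if (perm[i] > perm[j]) inv <- inv + 1L
  }
  inv %% 2L
}
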