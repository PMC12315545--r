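# The four masking strategies. Random masking of single atoms is nearly
# trivial in peptides (amide repetition); bulk, side-chain and fragment
# masking hide chemically coherent regions instead. Masks are planned against
# a graph and applied as a separate step so labels are recorded before any
# feature is overwritten.

#' Plan a mask over a heterogeneous graph
#'
#' Strategies: `random` samples atoms uniformly without replacement; `bulk`
#' grows a breadth-first ball from a uniformly chosen seed atom to the target
#' size (the masked set is connected); `sidechain` samples uniformly from
#' side-chain atoms, falling back to random with a warning when side chains
#' are fewer than the target; `fragment` samples whole fragments uniformly
#' without replacement until their union reaches the target atom count
#' (overshoot at most one fragment), and records the masked fragments'
#' vocabulary labels.
#'
#' Sampling uses R's RNG; seed it (or use the seeded training entry points)
#' for reproducibility.
#'
#' @param graph a `hetero_graph`.
#' @param mol the underlying `pep_mol` (needed for `sidechain`).
#' @param strategy one of `"random"`, `"bulk"`, `"sidechain"`, `"fragment"`.
#' @param ratio target masked-atom fraction in (0,1).
#' @return a `mask_plan`.
#' @export
plan_mask <- function(graph, mol = NULL,
                      strategy = c("random", "bulk", "sidechain", "fragment"),
                      ratio = 0.15) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(graph, "hetero_graph"))
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) stop("ratio must be in (0,1)")
  n <- graph$n_atoms
  if (n < 1L) stop("empty graph")
  target <- max(1L, as.integer(ceiling(ratio * n)))

  masked_fragments <- integer(0)
  if (strategy == "random") {
    masked_atoms <- sort(sample.int(n, target))
  } else if (strategy == "bulk") {
    adj <- vector("list", n)
    e <- graph$edges_aa
    for (k in seq_len(nrow(e))) adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    seedv <- sample.int(n, 1L)
    visited <- rep(FALSE, n); visited[seedv] <- TRUE
    ball <- seedv; queue <- seedv
    while (length(ball) < target) {
      if (length(queue) == 0L) {
        rest <- which(!visited)
        if (length(rest) == 0L) break
        nxt <- rest[sample.int(length(rest), 1L)] # disconnected input guard
        visited[nxt] <- TRUE; ball <- c(ball, nxt); queue <- nxt
        next
      }
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!visited[w] && length(ball) < target) {
          visited[w] <- TRUE; ball <- c(ball, w); queue <- c(queue, w)
        }
      }
    }
    masked_atoms <- sort(ball)
  } else if (strategy == "sidechain") {
    if (is.null(mol)) stop("sidechain masking needs the molecule")
    sc <- suppressWarnings(side_chain_atoms(mol))
    if (length(sc) < target) {
      warning("fewer side-chain atoms than the mask target; falling back to random masking")
      masked_atoms <- sort(sample.int(n, target))
    } else {
      masked_atoms <- sort(sc[sample.int(length(sc), target)])
    }
  } else { # fragment
    perm <- sample.int(graph$n_fragments)
    sizes <- graph$fragment_sizes
    tot <- 0L; chosen <- integer(0)
    for (fi in perm) {
      chosen <- c(chosen, fi); tot <- tot + sizes[fi]
      if (tot >= target) break
    }
    masked_fragments <- sort(chosen)
    masked_atoms <- sort(which(graph$frag_of_atom %in% masked_fragments))
  }

  structure(
    list(
      masked_atoms = masked_atoms,
      masked_fragments = masked_fragments,
      atom_labels = stats::setNames(
        graph$atom_features[masked_atoms, "element"], masked_atoms
      ),
      fragment_labels = stats::setNames(
        graph$fragment_ids[masked_fragments], masked_fragments
      ),
      strategy = strategy, target_ratio = ratio, target_atoms = target
    ),
    class = "mask_plan"
  )
}

#' Apply a mask plan to a graph
#'
#' Masked atoms have their element class replaced by the reserved MASK class
#' (one past the element alphabet); masked fragments have their vocabulary id
#' replaced by the reserved MASK id. All other features are untouched; the
#' operation is idempotent.
#'
#' @param graph a `hetero_graph`.
#' @param plan a `mask_plan` for this graph.
#' @return list with `graph` (masked copy), `atom_labels` (element class by
#'   atom index), `fragment_labels` (0-based vocab id by fragment index).
#' @export
apply_mask <- function(graph, plan) {
  stopifnot(inherits(graph, "hetero_graph"), inherits(plan, "mask_plan"))
  if (length(plan$masked_atoms) > 0L &&
      (max(plan$masked_atoms) > graph$n_atoms || min(plan$masked_atoms) < 1L)) {
    stop("mask plan atom index out of range")
  }
  if (length(plan$masked_fragments) > 0L &&
      (max(plan$masked_fragments) > graph$n_fragments || min(plan$masked_fragments) < 1L)) {
    stop("mask plan fragment index out of range")
  }
  g <- graph
  g$atom_features[plan$masked_atoms, "element"] <- .pt_n_element_classes() + 1L
  g$fragment_ids[plan$masked_fragments] <- g$n_vocab # reserved MASK id (0-based)
  list(graph = g, atom_labels = plan$atom_labels, fragment_labels = plan$fragment_labels)
}
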