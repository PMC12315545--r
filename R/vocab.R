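# Fragment vocabulary: corpus-derived map from canonical fragment structure
# keys to dense integer ids with exact frequencies. Per-element single-atom
# entries are always reserved (ids 0..E-1), which guarantees that every
# molecule can be encoded: any out-of-vocabulary fragment can at worst be
# decomposed into single atoms.

.pt_element_alphabet <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Se", "other")

.pt_reserved_keys <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toks <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "[Se]")
      keys <- .pt_ob_canonical_batch(toks)
      cache <<- c(stats::setNames(keys, .pt_element_alphabet[1:11]), other = "*")
    }
    cache
  }
})

.pt_element_class <- function(elements) {
  i <- match(elements, .pt_element_alphabet)
  i[is.na(i)] <- match("other", .pt_element_alphabet)
  i # 1-based index into the alphabet
}

.pt_new_vocab <- function(entries, reserved_freq, params) {
  E <- length(.pt_element_alphabet)
  reserved <- data.frame(
    element = .pt_element_alphabet,
    key = unname(.pt_reserved_keys()[.pt_element_alphabet]),
    id = 0:(E - 1L),
    freq = as.integer(reserved_freq),
    stringsAsFactors = FALSE
  )
  if (nrow(entries) > 0L) entries$id <- E - 1L + seq_len(nrow(entries))
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(reserved))) assign(reserved$key[i], reserved$id[i], envir = lookup)
  for (i in seq_len(nrow(entries))) assign(entries$key[i], entries$id[i], envir = lookup)
  structure(
    list(reserved = reserved, entries = entries, params = params, lookup = lookup),
    class = "fragment_vocabulary"
  )
}

#' Number of entries (reserved + learned) in a vocabulary
#' @param vocab a `fragment_vocabulary`.
#' @return integer.
#' @export
n_vocab <- function(vocab) nrow(vocab$reserved) + nrow(vocab$entries)

#' Reserved id used for masked fragments (one past the last vocabulary id)
#' @param vocab a `fragment_vocabulary`.
#' @return integer (0-based id).
#' @export
vocab_mask_id <- function(vocab) n_vocab(vocab)

#' @export
print.fragment_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<fragment_vocabulary> %d entries (%d reserved single-atom, %d learned); min_freq=%d, max_vocab=%d, max_fragment_atoms=%d, seed=%s\n",
    n_vocab(x), nrow(x$reserved), nrow(x$entries),
    x$params$min_freq, x$params$max_vocab, x$params$max_fragment_atoms,
    x$params$seed_method
  ))
  invisible(x)
}

#' Look up vocabulary ids for canonical keys
#'
#' @param vocab a `fragment_vocabulary`.
#' @param keys character vector of canonical keys.
#' @return integer vector of 0-based ids; `NA` for out-of-vocabulary keys.
#' @export
vocab_lookup <- function(vocab, keys) {
  vapply(keys, function(k) {
    if (exists(k, envir = vocab$lookup, inherits = FALSE)) {
      get(k, envir = vocab$lookup)
    } else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

# vocabulary ids for the fragments of a fragmentation; single-atom fragments
# resolve through the reserved per-element entries
.pt_fragment_ids <- function(vocab, mol, frag) {
  sizes <- vapply(frag$fragments, length, integer(1))
  ids <- vocab_lookup(vocab, frag$fragment_keys)
  single <- which(sizes == 1L)
  if (length(single) > 0L) {
    els <- mol$atoms$element[vapply(frag$fragments[single], `[[`, integer(1), 1L)]
    ids[single] <- vocab$reserved$id[.pt_element_class(els)]
  }
  ids
}

# enumerate the counting pipeline's final fragments for one molecule:
# seed fragments, then recursive BRICS splitting of oversized pieces
.pt_count_fragments <- function(mol, max_fragment_atoms, seed_method) {
  seeds <- if (seed_method == "amiibo") {
    amiibo_fragment(mol)$fragments
  } else {
    # purely data-driven seed: BRICS pieces of the whole molecule
    unlist(lapply(.pt_components(mol), function(cp) brics_split(mol, cp)),
           recursive = FALSE)
  }
  final <- list()
  pending <- seeds
  while (length(pending) > 0L) {
    f <- pending[[1]]; pending <- pending[-1]
    if (length(f) <= max_fragment_atoms) { final[[length(final) + 1L]] <- f; next }
    parts <- brics_split(mol, f)
    if (length(parts) == 1L) final[[length(final) + 1L]] <- f
    else pending <- c(parts, pending)
  }
  final
}

#' Learn a fragment vocabulary from a corpus
#'
#' Pipeline: fragment every molecule with the seed operator (Amiibo by
#' default; `seed_method = "whole"` skips the domain-knowledge stage and
#' starts from whole molecules, the purely data-driven baseline), recursively
#' BRICS-split any fragment larger than `max_fragment_atoms`, canonical-key
#' every resulting fragment, and count keys across the corpus. The vocabulary
#' is the reserved single-atom entries plus the up-to-`max_vocab` most
#' frequent keys with frequency at least `min_freq` (ties broken by frequency
#' descending, then lexicographic key). Frequencies are stored exactly.
#'
#' @param corpus list of `pep_mol`.
#' @param min_freq minimum corpus frequency for a learned entry.
#' @param max_vocab maximum number of learned (non-reserved) entries.
#' @param max_fragment_atoms fragments larger than this are BRICS-split.
#' @param seed_method `"amiibo"` or `"whole"`.
#' @return a `fragment_vocabulary`.
#' @export
learn_vocabulary <- function(corpus, min_freq = 2L, max_vocab = 2000L,
                             max_fragment_atoms = 20L,
                             seed_method = c("amiibo", "whole")) {
  seed_method <- match.arg(seed_method)
  if (!is.list(corpus) || length(corpus) == 0L) {
    stop("corpus must be a non-empty list of molecules")
  }
  counts <- new.env(hash = TRUE, parent = emptyenv())
  E <- length(.pt_element_alphabet)
  reserved_freq <- integer(E)
  for (mol in corpus) {
    frags <- .pt_count_fragments(mol, max_fragment_atoms, seed_method)
    sizes <- vapply(frags, length, integer(1))
    single <- which(sizes == 1L)
    if (length(single) > 0L) {
      cls <- .pt_element_class(mol$atoms$element[unlist(frags[single])])
      for (ci in cls) reserved_freq[ci] <- reserved_freq[ci] + 1L
    }
    multi <- which(sizes > 1L)
    if (length(multi) > 0L) {
      keys <- .pt_canonical_keys(rep(list(mol), length(multi)), frags[multi])
      for (k in keys) {
        assign(k, (if (exists(k, envir = counts, inherits = FALSE)) get(k, envir = counts) else 0L) + 1L,
               envir = counts)
      }
    }
  }
  keys <- ls(counts)
  freqs <- vapply(keys, function(k) get(k, envir = counts), integer(1), USE.NAMES = FALSE)
  rk <- .pt_reserved_keys()
  is_res <- keys %in% rk
  if (any(is_res)) {
    for (i in which(is_res)) {
      ci <- which(rk == keys[i])[[1]]
      reserved_freq[ci] <- reserved_freq[ci] + freqs[i]
    }
    keys <- keys[!is_res]; freqs <- freqs[!is_res]
  }
  keep <- freqs >= min_freq
  keys <- keys[keep]; freqs <- freqs[keep]
  # radix = C-locale byte order: the tie-break is independent of the session
  # locale, so learned ids are stable across platforms
  ord <- order(-freqs, keys, method = "radix")
  if (length(ord) > max_vocab) ord <- ord[seq_len(max_vocab)]
  entries <- data.frame(
    key = keys[ord], id = rep(NA_integer_, length(ord)),
    freq = as.integer(freqs[ord]), stringsAsFactors = FALSE
  )
  .pt_new_vocab(entries, reserved_freq, list(
    min_freq = as.integer(min_freq), max_vocab = as.integer(max_vocab),
    max_fragment_atoms = as.integer(max_fragment_atoms),
    seed_method = seed_method
  ))
}

# shared recursion of the vocabulary-guided operators: any piece whose key is
# unknown (or which exceeds max_fragment_atoms) is BRICS-split; irreducible
# unknown multi-atom pieces fall back to single atoms (reserved entries)
.pt_vocab_guided_split <- function(mol, seeds, vocab) {
  maxa <- vocab$params$max_fragment_atoms
  final <- list()
  pending <- seeds
  while (length(pending) > 0L) {
    keys <- .pt_canonical_keys(rep(list(mol), length(pending)), pending)
    ids <- vocab_lookup(vocab, keys)
    nxt <- list()
    for (i in seq_along(pending)) {
      f <- pending[[i]]
      if (length(f) == 1L ||
          (!is.na(ids[i]) && length(f) <= maxa)) {
        final[[length(final) + 1L]] <- f
        next
      }
      parts <- brics_split(mol, f)
      if (length(parts) > 1L) {
        nxt <- c(nxt, parts)
      } else {
        final <- c(final, as.list(f)) # terminal fallback: single atoms
      }
    }
    pending <- nxt
  }
  final
}

#' Data-driven fragmentation with out-of-vocabulary fallback (AdaFrag)
#'
#' Starts from the Amiibo fragmentation; every fragment whose canonical key
#' is not in the vocabulary (or which exceeds the vocabulary's
#' `max_fragment_atoms`) is recursively BRICS-split, and any remaining
#' irreducible unknown fragment is decomposed into single atoms, which the
#' reserved entries always cover. All final fragment keys are therefore
#' encodable. Deterministic for a fixed (molecule, vocabulary) pair.
#'
#' @param mol a `pep_mol`.
#' @param vocab a `fragment_vocabulary`.
#' @return a `pep_fragmentation` with `method = "adafrag"`.
#' @export
adafrag_fragment <- function(mol, vocab) {
  stopifnot(inherits(mol, "pep_mol"), inherits(vocab, "fragment_vocabulary"))
  seeds <- amiibo_fragment(mol)$fragments
  pt_fragmentation(mol, .pt_vocab_guided_split(mol, seeds, vocab), "adafrag")
}

#' Fragment a molecule by any supported method
#'
#' @param mol a `pep_mol`.
#' @param method one of `"amiibo"`, `"adafrag"`, `"atoms_only"`,
#'   `"principal_subgraph"`.
#' @param vocab vocabulary, required for `adafrag` and `principal_subgraph`.
#' @return a `pep_fragmentation`.
#' @export
fragment_molecule <- function(mol, method = c("amiibo", "adafrag", "atoms_only",
                                              "principal_subgraph"),
                              vocab = NULL) {
  method <- match.arg(method)
  switch(method,
    amiibo = amiibo_fragment(mol),
    adafrag = {
      if (is.null(vocab)) stop("adafrag requires a vocabulary")
      adafrag_fragment(mol, vocab)
    },
    atoms_only = baseline_fragment(mol, "atoms_only"),
    principal_subgraph = baseline_fragment(mol, "principal_subgraph", vocab)
  )
}

#' Serialize a vocabulary to JSON
#'
#' The file reloads bit-exactly via [load_vocabulary()].
#' @param vocab a `fragment_vocabulary`.
#' @param path output path.
#' @export
save_vocabulary <- function(vocab, path) {
  obj <- list(
    params = vocab$params,
    reserved = vocab$reserved[, c("element", "key", "id", "freq")],
    entries = vocab$entries[, c("key", "id", "freq")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a vocabulary from JSON
#' @param path path written by [save_vocabulary()].
#' @return a `fragment_vocabulary`.
#' @export
load_vocabulary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- if (length(obj$entries) == 0L) {
    data.frame(key = character(0), id = integer(0), freq = integer(0))
  } else {
    data.frame(key = obj$entries$key, id = as.integer(obj$entries$id),
               freq = as.integer(obj$entries$freq), stringsAsFactors = FALSE)
  }
  params <- obj$params
  params$min_freq <- as.integer(params$min_freq)
  params$max_vocab <- as.integer(params$max_vocab)
  params$max_fragment_atoms <- as.integer(params$max_fragment_atoms)
  v <- .pt_new_vocab(entries, as.integer(obj$reserved$freq), params)
  stopifnot(identical(v$entries$id, entries$id)) # dense id invariant
  v
}
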