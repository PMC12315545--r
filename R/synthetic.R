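# Synthetic corpora with known structure: random peptides over configurable
# monomer pools (canonical and/or non-canonical), an optional planted
# contiguous motif occurring in an exact fraction of sequences, and property
# labels that are linear in fragment counts (plus Gaussian noise) so that
# embedding quality is directly measurable by parameter recovery.

.pt_canonical_codes <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.pt_noncanonical_codes <- c("dA", "dF", "Aib", "Sar", "MeF", "Nle", "Nva",
                            "Hse", "Orn")

#' Specification of a synthetic peptide corpus
#'
#' Defaults emulate short therapeutic-scale peptides: lengths 2-30 residues
#' (sequences longer than 30 residues are outside the modelled envelope).
#'
#' @param n_molecules number of peptides.
#' @param length_range integer range of residue counts (default 2-30).
#' @param pool monomer codes to sample from (default: the 20 canonical
#'   amino acids).
#' @param planted_motif optional character vector of monomer codes planted as
#'   a contiguous subsequence.
#' @param motif_fraction exact fraction of sequences carrying the motif.
#' @param seed RNG seed.
#' @return a `corpus_spec`.
#' @export
corpus_spec <- function(n_molecules = 100L, length_range = c(2L, 30L),
                        pool = .pt_canonical_codes, planted_motif = NULL,
                        motif_fraction = 0, seed = 1L) {
  stopifnot(n_molecules >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2],
            motif_fraction >= 0, motif_fraction <= 1)
  if (!is.null(planted_motif) && length(planted_motif) > length_range[1]) {
    stop("planted motif is longer than the minimum sequence length")
  }
  structure(list(
    n_molecules = as.integer(n_molecules),
    length_range = as.integer(length_range),
    pool = pool, planted_motif = planted_motif,
    motif_fraction = motif_fraction, seed = as.integer(seed)
  ), class = "corpus_spec")
}

.pt_has_motif <- function(seq, motif) {
  lm <- length(motif)
  if (length(seq) < lm) return(FALSE)
  for (s in seq_len(length(seq) - lm + 1L)) {
    if (all(seq[s:(s + lm - 1L)] == motif)) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic peptide corpus
#'
#' Sequences are sampled uniformly over the pool and the length range; the
#' planted motif is written into exactly
#' `round(motif_fraction * n_molecules)` sequences at a uniform position
#' (sequences not selected for planting are resampled if they contain the
#' motif by chance, so the occurrence count is exact). Fully reproducible
#' from the spec seed.
#'
#' @param spec a `corpus_spec`.
#' @param lib a `monomer_library` containing every pool code.
#' @return named list of entries `list(id, seq, mol, has_motif)`.
#' @export
generate_corpus <- function(spec, lib) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(lib, "monomer_library"))
  missing <- setdiff(spec$pool, names(lib$monomers))
  if (length(missing) > 0L) {
    stop(sprintf("pool codes absent from library: %s", paste(missing, collapse = ", ")))
  }
  set.seed(spec$seed)
  n <- spec$n_molecules
  n_mot <- if (is.null(spec$planted_motif)) 0L else round(spec$motif_fraction * n)
  with_motif <- if (n_mot > 0L) sample.int(n, n_mot) else integer(0)
  motif <- spec$planted_motif
  out <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
    for (try in 1:200) {
      sq <- sample(spec$pool, len, replace = TRUE)
      if (i %in% with_motif) {
        pos <- sample.int(len - length(motif) + 1L, 1L)
        sq[pos:(pos + length(motif) - 1L)] <- motif
        break
      }
      if (is.null(motif) || !.pt_has_motif(sq, motif)) break
      if (try == 200L) stop("could not sample a motif-free sequence; enlarge the pool")
    }
    out[[i]] <- list(
      id = sprintf("pep%04d", i), seq = sq,
      mol = sequence_to_molecule(sq, lib),
      has_motif = i %in% with_motif
    )
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Label specification for synthetic property labels
#'
#' @param mode `"linear_fragment_counts"` (label = weighted fragment counts +
#'   Gaussian noise) or `"binary_threshold"` (the linear score thresholded at
#'   its corpus median, ties counted positive).
#' @param weights named numeric vector: canonical fragment key -> weight; at
#'   least one nonzero.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed for the noise.
#' @return a `label_spec`.
#' @export
label_spec <- function(mode = c("linear_fragment_counts", "binary_threshold"),
                       weights, noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(weights), length(weights) > 0L, !is.null(names(weights)),
            noise_sd >= 0)
  if (all(weights == 0)) stop("at least one weight must be nonzero")
  structure(list(mode = mode, weights = weights, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "label_spec")
}

#' Generate property labels with known fragment-composition structure
#'
#' @param corpus entries from [generate_corpus()] (or a plain list of
#'   `pep_mol`).
#' @param vocab a `fragment_vocabulary`; all weight keys must be encodable.
#' @param lspec a `label_spec`.
#' @param method fragmentation method used for the counts.
#' @return numeric vector (regression) or 0/1 integer vector (binary), with
#'   attribute `score` carrying the noiseless linear score.
#' @export
generate_labels <- function(corpus, vocab, lspec,
                            method = c("adafrag", "amiibo")) {
  method <- match.arg(method)
  stopifnot(inherits(lspec, "label_spec"))
  keys <- names(lspec$weights)
  if (anyNA(vocab_lookup(vocab, keys))) {
    stop("label weights reference keys absent from the vocabulary")
  }
  mols <- lapply(corpus, function(e) if (inherits(e, "pep_mol")) e else e$mol)
  score <- vapply(mols, function(m) {
    fr <- if (method == "adafrag") adafrag_fragment(m, vocab) else amiibo_fragment(m)
    sum(lspec$weights * vapply(keys, function(k) sum(fr$fragment_keys == k), numeric(1)))
  }, numeric(1))
  set.seed(lspec$seed)
  noisy <- score + stats::rnorm(length(score), sd = lspec$noise_sd)
  if (lspec$mode == "binary_threshold") {
    out <- as.integer(noisy >= stats::median(noisy))
  } else {
    out <- noisy
  }
  attr(out, "score") <- score
  out
}
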