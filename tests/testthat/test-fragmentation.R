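# Amiibo, BRICS, vocabulary learning, AdaFrag and the baselines.

expect_partition <- function(frag, mol) {
  idx <- sort(unlist(frag$fragments))
  expect_identical(idx, seq_len(n_atoms(mol)))
  # every inter-fragment bond appears exactly once in cut_bonds
  fo <- frag$fragment_of_atom
  b <- mol$bonds
  inter <- which(fo[b$a] != fo[b$b])
  expect_identical(nrow(frag$cut_bonds), length(inter))
}

test_that("Amiibo on diglycine preserves the amide and cuts N-Calpha", {
  gg <- sequence_to_molecule(c("G", "G"), fx_lib())
  fr <- amiibo_fragment(gg)
  expect_identical(sort(vapply(fr$fragments, length, integer(1))), c(4L, 5L))
  expect_identical(nrow(fr$cut_bonds), 1L)
  # the cut bond is N(2)-Calpha(2): nitrogen of residue 2, carbon of residue 2
  cb <- fr$cut_bonds
  els <- sort(gg$atoms$element[c(cb$a, cb$b)])
  expect_identical(els, c("C", "N"))
  expect_true(all(gg$residue_of_atom[c(cb$a, cb$b)] == 2L))
  # no amide bond is cut
  amide <- peptigraph:::.pt_amide_bonds(gg)
  amide_pairs <- paste(pmin(gg$bonds$a[amide], gg$bonds$b[amide]),
                       pmax(gg$bonds$a[amide], gg$bonds$b[amide]))
  cut_pairs <- paste(pmin(cb$a, cb$b), pmax(cb$a, cb$b))
  expect_length(intersect(amide_pairs, cut_pairs), 0L)
})

test_that("a single residue yields one fragment and no cuts", {
  g <- sequence_to_molecule("G", fx_lib())
  fr <- amiibo_fragment(g)
  expect_length(fr$fragments, 1L)
  expect_identical(nrow(fr$cut_bonds), 0L)
})

test_that("Amiibo fragment count equals residue count for proline-free peptides", {
  lib <- fx_lib()
  codes <- setdiff(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                     "L", "K", "M", "F", "S", "T", "W", "Y", "V"), "P")
  set.seed(21)
  for (n in 2:10) {
    seq <- sample(codes, n, replace = TRUE)
    mol <- sequence_to_molecule(seq, lib)
    fr <- amiibo_fragment(mol)
    expect_identical(length(fr$fragments), n)
    expect_identical(nrow(fr$cut_bonds), n - 1L)
    # independent oracle: count acyclic amide-N to alpha-carbon bonds
    expect_identical(nrow(fr$cut_bonds),
                     length(peptigraph:::pt_amiibo_cut_bonds(mol)))
  }
})

test_that("proline merges with the preceding fragment", {
  mol <- sequence_to_molecule(c("G", "P", "G"), fx_lib())
  fr <- amiibo_fragment(mol)
  expect_identical(length(fr$fragments), 2L) # Pro N-Calpha is a ring bond
})

test_that("BRICS splitting matches the RDKit reference on fixture molecules", {
  # independent oracle: RDKit's published BRICS implementation (available in
  # the environment's Python); both sides index atoms in SMILES order
  fixtures <- c(
    "CCOCCC", "CCCOCCC(=O)c1ccccc1", "CC=CC", "O=C1CCCN1", "CC1(C)CCCCC1",
    "CNC(=O)C", "NC(C(=O)NCC(=O)O)Cc1ccccc1",
    "CC(C[C@@H](C(=O)N1CCC[C@H]1C(=O)O)NC(=O)C)C",
    "NC(Cc1c[nH]c2ccccc12)C(=O)O", "CCSSCC", "CS(=O)(=O)NC"
  )
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import BRICS",
    "for s in sys.stdin.read().split():",
    "    m = Chem.MolFromSmiles(s)",
    "    cuts = sorted('%d-%d' % tuple(sorted(b)) for b, _ in BRICS.FindBRICSBonds(m))",
    "    print(';'.join(cuts))"
  ), script)
  ref <- system2("python", script, stdout = TRUE,
                 input = paste(fixtures, collapse = "\n"))
  expect_length(ref, length(fixtures))
  for (i in seq_along(fixtures)) {
    mol <- peptigraph:::pt_parse_smiles(fixtures[i])
    bb <- peptigraph:::pt_find_brics_bonds(mol)
    mine <- sort(sprintf("%d-%d",
                         pmin(mol$bonds$a[bb], mol$bonds$b[bb]) - 1L,
                         pmax(mol$bonds$a[bb], mol$bonds$b[bb]) - 1L))
    expect_identical(paste(mine, collapse = ";"), ref[i], label = fixtures[i])
  }
})

test_that("brics_split honours its contracts", {
  lib <- fx_lib()
  ff <- sequence_to_molecule(c("F", "F"), lib)
  fr <- amiibo_fragment(ff)
  # the phenylalanine-derived fragment contains BRICS bonds; the ring stays whole
  big <- fr$fragments[[which.max(vapply(fr$fragments, length, integer(1)))]]
  parts <- brics_split(ff, big)
  expect_gte(length(parts), 2L)
  ring_atoms <- which(ff$atom_in_ring)
  in_part <- vapply(parts, function(p) length(intersect(p, ring_atoms)), integer(1))
  expect_identical(sum(in_part > 0L), 1L) # one part holds a whole ring

  g <- sequence_to_molecule("G", lib)
  expect_identical(brics_split(g, 1L), list(1L))        # single atom
  eth <- pep_mol("CC")
  expect_identical(brics_split(eth, 1:2), list(1:2))    # no BRICS bond
  expect_error(brics_split(ff, c(1L, n_atoms(ff))), "disconnected")
})

test_that("vocabulary learning counts diglycine fragments exactly", {
  gg <- sequence_to_molecule(c("G", "G"), fx_lib())
  v <- learn_vocabulary(rep(list(gg), 50), min_freq = 2L)
  fr <- amiibo_fragment(gg)
  for (k in fr$fragment_keys) {
    expect_true(k %in% v$entries$key)
    expect_identical(v$entries$freq[v$entries$key == k], 50L)
  }
  # a threshold above the corpus size leaves only the reserved entries
  v2 <- learn_vocabulary(rep(list(gg), 50), min_freq = 100L)
  expect_identical(nrow(v2$entries), 0L)
  expect_identical(n_vocab(v2), nrow(v2$reserved))
})

test_that("vocabulary frequencies equal an independent naive counter", {
  mols <- fx_small_corpus()
  v <- learn_vocabulary(mols, min_freq = 2L, max_fragment_atoms = 12L)
  # naive counter: re-run the pipeline definition literally, counting keys
  # with table() over one flat vector
  all_keys <- character(0)
  for (mol in mols) {
    pending <- amiibo_fragment(mol)$fragments
    final <- list()
    while (length(pending) > 0L) {
      f <- pending[[1]]; pending <- pending[-1]
      if (length(f) <= 12L) { final <- c(final, list(f)); next }
      parts <- brics_split(mol, f)
      if (length(parts) == 1L) final <- c(final, list(f))
      else pending <- c(parts, pending)
    }
    all_keys <- c(all_keys,
                  vapply(final, function(f) canonical_key(mol, f), character(1)))
  }
  tab <- table(all_keys)
  for (i in seq_len(nrow(v$entries))) {
    expect_identical(v$entries$freq[i], as.integer(tab[[v$entries$key[i]]]),
                     label = v$entries$key[i])
  }
  # and no key above threshold was dropped (vocabulary cap not reached here)
  multi <- tab[tab >= 2L]
  multi <- multi[!names(multi) %in% v$reserved$key]
  expect_identical(sort(names(multi)), sort(v$entries$key))
})

test_that("a planted motif's fragment key enters the vocabulary", {
  lib <- fx_lib()
  spec <- corpus_spec(n_molecules = 30L, length_range = c(4L, 8L),
                      pool = c("A", "G", "S"), planted_motif = c("Nle", "Nle"),
                      motif_fraction = 0.4, seed = 31L)
  corpus <- generate_corpus(spec, lib)
  mols <- lapply(corpus, `[[`, "mol")
  v <- learn_vocabulary(mols, min_freq = 2L)
  # the norleucine residue fragment: appears in every planted molecule
  nle_frag <- amiibo_fragment(sequence_to_molecule(c("A", "Nle", "A"), lib))
  nle_key <- nle_frag$fragment_keys[[2]]
  expect_true(nle_key %in% v$entries$key)
  expect_gte(v$entries$freq[v$entries$key == nle_key], sum(vapply(corpus, `[[`, logical(1), "has_motif")))
})

test_that("adafrag is the identity when all Amiibo fragments are known", {
  mols <- fx_small_corpus()
  v <- learn_vocabulary(mols, min_freq = 1L)
  mol <- mols[[1]]
  am <- amiibo_fragment(mol)
  ad <- adafrag_fragment(mol, v)
  expect_identical(ad$fragments, am$fragments)
  expect_identical(ad$method, "adafrag")
})

test_that("adafrag splits out-of-vocabulary fragments and stays encodable", {
  lib <- fx_lib()
  gg <- sequence_to_molecule(c("G", "G"), lib)
  v <- learn_vocabulary(rep(list(gg), 3), min_freq = 2L) # knows only Gly keys
  target <- sequence_to_molecule(c("G", "F", "G"), lib)
  am <- amiibo_fragment(target)
  ad <- adafrag_fragment(target, v)
  expect_gt(length(ad$fragments), length(am$fragments))
  ids <- peptigraph:::.pt_fragment_ids(v, target, ad)
  expect_false(anyNA(ids)) # reserved entries guarantee total encodability
  # known fragments were left untouched
  known <- am$fragments[am$fragment_keys %in% c(v$entries$key, v$reserved$key)]
  for (f in known) expect_true(any(vapply(ad$fragments, identical, logical(1), f)))
  # determinism
  ad2 <- adafrag_fragment(target, v)
  expect_identical(ad$fragments, ad2$fragments)
  expect_identical(ad$fragment_keys, ad2$fragment_keys)
})

test_that("an exotic irreducible fragment decomposes into single atoms", {
  # cyclopentane has no amide and no BRICS bonds: one OOV fragment
  mol <- pep_mol("C1CCCC1")
  v <- learn_vocabulary(list(sequence_to_molecule(c("G", "G"), fx_lib())), min_freq = 1L)
  ad <- adafrag_fragment(mol, v)
  expect_identical(length(ad$fragments), n_atoms(mol))
  expect_true(all(vapply(ad$fragments, length, integer(1)) == 1L))
})

test_that("reassembly restores the canonical key for every method", {
  mols <- fx_small_corpus()[1:12]
  v <- fx_small_vocab()
  vw <- learn_vocabulary(mols, min_freq = 2L, seed_method = "whole")
  for (mol in mols) {
    for (method in c("amiibo", "adafrag", "atoms_only", "principal_subgraph")) {
      vv <- switch(method, adafrag = v, principal_subgraph = vw, NULL)
      fr <- fragment_molecule(mol, method, vv)
      expect_partition(fr, mol)
      expect_identical(canonical_key(reassemble(mol, fr)), canonical_key(mol))
    }
  }
})

test_that("reassemble rejects inconsistent fragmentations", {
  gg <- sequence_to_molecule(c("G", "G"), fx_lib())
  fr <- amiibo_fragment(gg)
  bad <- fr
  bad$cut_bonds$a[1] <- 99L
  expect_error(reassemble(gg, bad), "missing atom")
  bad2 <- fr
  bad2$fragments[[1]] <- bad2$fragments[[1]][-1]
  expect_error(reassemble(gg, bad2), "partition")
})

test_that("atoms_only gives one fragment per atom on diglycine", {
  gg <- sequence_to_molecule(c("G", "G"), fx_lib())
  ao <- baseline_fragment(gg, "atoms_only")
  expect_identical(length(ao$fragments), 9L)
  expect_identical(nrow(ao$cut_bonds), 8L)
  expect_error(baseline_fragment(gg, "principal_subgraph"), "vocabulary")
})

test_that("the data-driven baseline may cut amide bonds", {
  lib <- fx_lib()
  # corpus of one repeated dipeptide: whole-molecule BRICS pieces (which
  # separate the acyl and amine sides) become frequent vocabulary entries
  mol <- sequence_to_molecule(c("A", "A"), lib)
  vw <- learn_vocabulary(rep(list(mol), 20), min_freq = 2L, seed_method = "whole")
  ps <- baseline_fragment(mol, "principal_subgraph", vw)
  amide <- peptigraph:::.pt_amide_bonds(mol)
  amide_pairs <- paste(pmin(mol$bonds$a[amide], mol$bonds$b[amide]),
                       pmax(mol$bonds$a[amide], mol$bonds$b[amide]))
  cut_pairs <- paste(pmin(ps$cut_bonds$a, ps$cut_bonds$b),
                     pmax(ps$cut_bonds$a, ps$cut_bonds$b))
  expect_gt(length(intersect(amide_pairs, cut_pairs)), 0L)
})

test_that("vocabularies serialize to JSON and reload bit-exactly", {
  v <- fx_small_vocab()
  path <- tempfile(fileext = ".json")
  save_vocabulary(v, path)
  v2 <- load_vocabulary(path)
  expect_identical(v2$entries$key, v$entries$key)
  expect_identical(v2$entries$id, v$entries$id)
  expect_identical(v2$entries$freq, v$entries$freq)
  expect_identical(v2$reserved, v$reserved)
  expect_identical(v2$params[c("min_freq", "max_vocab", "max_fragment_atoms", "seed_method")],
                   v$params[c("min_freq", "max_vocab", "max_fragment_atoms", "seed_method")])
  expect_identical(vocab_lookup(v2, v$entries$key), v$entries$id)
})
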