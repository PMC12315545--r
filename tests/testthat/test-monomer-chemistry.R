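# Monomer library handling, peptide assembly and canonical keys.

test_that("monomer TSV loading validates rows, codes and SMILES", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "code\tsmiles\tis_canonical\tside_chain_atoms",
    "G\t[*:1]NCC(=O)[*:2]\ttrue\t"
  ), tsv)
  lib <- load_monomer_library(tsv)
  expect_s3_class(lib, "monomer_library")
  g <- lib$monomers[["G"]]
  expect_identical(g$code, "G")
  expect_true(g$is_canonical)
  expect_false(g$capping)
  expect_identical(lib$monomers[["G"]]$side_chain_atoms, integer(0))

  writeLines(c(
    "code\tsmiles\tis_canonical\tside_chain_atoms",
    "A\t[*:1]N[C@@H](C)C(=O)[*:2]\ttrue\t2",
    "A\t[*:1]NCC(=O)[*:2]\ttrue\t"
  ), tsv)
  expect_error(load_monomer_library(tsv), "duplicate monomer code")

  writeLines(c(
    "code\tsmiles\tis_canonical\tside_chain_atoms",
    "X\tC(C\tfalse\t"
  ), tsv)
  expect_error(load_monomer_library(tsv), "invalid monomer 'X'")
})

test_that("the built-in library covers the 20 canonical amino acids", {
  lib <- fx_lib()
  canon <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  expect_true(all(canon %in% names(lib$monomers)))
  expect_true(all(vapply(lib$monomers[canon], function(m) m$is_canonical, logical(1))))
})

test_that("glycine and diglycine assemble to the hand-drawn structures", {
  lib <- fx_lib()
  g <- sequence_to_molecule("G", lib)
  expect_identical(canonical_key(g), ob_canon("NCC(=O)O"))

  gg <- sequence_to_molecule(c("G", "G"), lib)
  expect_identical(n_atoms(gg), 9L)
  expect_identical(n_bonds(gg), 8L)
  expect_identical(canonical_key(gg), ob_canon("NCC(=O)NCC(=O)O"))
  # exactly one inter-residue amide C(=O)-N bond
  amide <- peptigraph:::.pt_amide_bonds(gg)
  inter <- sum(gg$residue_of_atom[gg$bonds$a[amide]] !=
               gg$residue_of_atom[gg$bonds$b[amide]])
  expect_identical(inter, 1L)

  expect_error(sequence_to_molecule(c("G", "X"), lib), "unknown monomer code")
  expect_error(sequence_to_molecule(character(0), lib), "at least one")
})

test_that("stereochemistry is carried into the canonical key", {
  lib <- fx_lib()
  la <- sequence_to_molecule(c("A", "G"), lib)
  da <- sequence_to_molecule(c("dA", "G"), lib)
  expect_false(canonical_key(la) == canonical_key(da))
  expect_identical(canonical_key(la), ob_canon("N[C@@H](C)C(=O)NCC(=O)O"))
  expect_identical(canonical_key(da), ob_canon("N[C@H](C)C(=O)NCC(=O)O"))
})

test_that("head-to-tail cyclization closes the macrocycle", {
  lib <- fx_lib()
  cyc <- sequence_to_molecule(c("G", "G", "G"), lib, cyclic = TRUE)
  expect_identical(canonical_key(cyc), ob_canon("O=C1CNC(=O)CNC(=O)CN1"))
  lin <- sequence_to_molecule(c("G", "G", "G"), lib)
  expect_identical(n_atoms(cyc), n_atoms(lin) - 1L) # hydroxyl oxygen lost
})

test_that("monomer condensation conserves heavy atoms", {
  lib <- fx_lib()
  set.seed(11)
  pool <- c("A", "G", "F", "W", "K", "S", "P", "Aib", "dA")
  for (i in 1:10) {
    seq <- sample(pool, sample(2:7, 1), replace = TRUE)
    mol <- sequence_to_molecule(seq, lib)
    mono_atoms <- vapply(seq, function(code) {
      g <- lib$monomers[[code]]$graph
      # dummies excluded, plus the terminal hydroxyl counted via [*:2] -> O
      sum(g$atoms$element != "*")
    }, integer(1))
    # each monomer contributes its heavy atoms; one O is added at the
    # C-terminus and none is lost because the library stores dehydrated
    # residues (the carboxyl hydroxyl lives on the attachment dummy)
    expect_identical(n_atoms(mol), sum(mono_atoms) + 1L)
  }
})

test_that("canonical keys identify isomorphic structures and subgraphs", {
  m1 <- pep_mol("OC(=O)CN")
  m2 <- pep_mol("NCC(O)=O")
  expect_identical(canonical_key(m1), canonical_key(m2))
  ala <- pep_mol("C[C@@H](N)C(=O)O")
  # methyl fragment capped with hydrogens is methane
  expect_identical(canonical_key(ala, subset = 1L), "C")
  # two atom orderings of one structure give one key (L-alanine both ways)
  alt <- pep_mol("N[C@@H](C)C(=O)O")
  ala <- pep_mol("C[C@H](N)C(=O)O")
  keyA <- canonical_key(ala)
  expect_identical(keyA, canonical_key(alt))
})

test_that("structure files round-trip in all three formats", {
  lib <- fx_lib()
  smi <- tempfile(fileext = ".smi")
  writeLines(c("NCC(=O)O", "NC(C)C(=O)O"), smi)
  mols <- read_structures(smi, "smiles_lines")
  expect_length(mols, 2L)
  expect_identical(vapply(mols, n_atoms, integer(1)), c(`1` = 5L, `2` = 6L))

  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "GA"), fa)
  fmols <- read_structures(fa, "fasta", lib = lib)
  expect_identical(names(fmols), "p1")
  expect_identical(canonical_key(fmols[[1]]),
                   canonical_key(sequence_to_molecule(c("G", "A"), lib)))

  sq <- tempfile(fileext = ".txt")
  writeLines("G[Aib]G", sq)
  smols <- read_structures(sq, "sequence_lines", lib = lib)
  expect_identical(max(smols[[1]]$residue_of_atom), 3L)
  expect_identical(canonical_key(smols[[1]]),
                   canonical_key(sequence_to_molecule(c("G", "Aib", "G"), lib)))

  empty <- tempfile()
  file.create(empty)
  expect_length(read_structures(empty, "smiles_lines"), 0L)
  writeLines("C(C", smi)
  expect_error(read_structures(smi, "smiles_lines"), "record 1")
})

test_that("write/read round-trip preserves the canonical key", {
  mols <- fx_small_corpus()
  out <- tempfile(fileext = ".smi")
  write_structures(mols, out)
  back <- read_structures(out, "smiles_lines")
  expect_identical(
    vapply(back, canonical_key, character(1), USE.NAMES = FALSE),
    vapply(mols, canonical_key, character(1), USE.NAMES = FALSE)
  )
})

test_that("the SMILES reader rejects malformed input", {
  expect_error(pep_mol("C(C"), "unbalanced")
  expect_error(pep_mol("C1CC"), "unclosed ring")
  expect_error(pep_mol("CC="), "dangling bond")
  expect_error(pep_mol(""), "empty")
  expect_error(pep_mol("C$C"), "unexpected character")
})
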