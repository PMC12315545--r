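# Shared fixtures, built lazily once per session and cached. Everything is
# generated in code from fixed seeds; no data files.

.fix <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

fx_lib <- function() fx("lib", function() builtin_monomer_library())

# OpenBabel canonicalization used directly as the independent chemistry
# oracle (the package's own path goes through its writer first)
ob_canon <- function(smiles) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = paste(smiles, collapse = "\n"))
  lines <- sub("[ \t].*$", "", strsplit(out, "\n", fixed = TRUE)[[1]])
  lines[nzchar(lines)]
}

# small random peptide corpus for unit-level property tests
fx_small_corpus <- function() {
  fx("small_corpus", function() {
    lib <- fx_lib()
    pool <- c("A", "G", "F", "S", "K", "P", "W", "dA", "Aib", "Sar", "Nle")
    set.seed(4001)
    lapply(1:40, function(i) {
      len <- sample(2:8, 1)
      sequence_to_molecule(sample(pool, len, replace = TRUE), lib)
    })
  })
}

fx_small_vocab <- function() {
  fx("small_vocab", function() learn_vocabulary(fx_small_corpus(), min_freq = 2L))
}

# the acceptance-scale corpus: 500 seeded synthetic peptides, canonical and
# non-canonical, lengths 2-30 (the generator's default envelope)
fx_acc_corpus <- function() {
  fx("acc_corpus", function() {
    lib <- fx_lib()
    canonical <- generate_corpus(corpus_spec(n_molecules = 300L, seed = 101L), lib)
    mixed <- generate_corpus(corpus_spec(
      n_molecules = 200L,
      pool = c(peptigraph:::.pt_canonical_codes, peptigraph:::.pt_noncanonical_codes),
      seed = 102L), lib)
    c(lapply(canonical, `[[`, "mol"), lapply(mixed, `[[`, "mol"))
  })
}

fx_acc_vocab <- function() {
  fx("acc_vocab", function() learn_vocabulary(fx_acc_corpus(), min_freq = 2L))
}

fx_acc_vocab_whole <- function() {
  fx("acc_vocab_whole", function() {
    learn_vocabulary(fx_acc_corpus(), min_freq = 2L, seed_method = "whole")
  })
}

fx_acc_frags <- function(method) {
  key <- paste0("acc_frags_", method)
  fx(key, function() {
    mols <- fx_acc_corpus()
    vocab <- switch(method,
      adafrag = fx_acc_vocab(),
      principal_subgraph = fx_acc_vocab_whole(),
      NULL)
    lapply(mols, fragment_molecule, method = method, vocab = vocab)
  })
}

# prepared graphs + a FragmentMasking pre-trained encoder at the acceptance
# study conditions (hidden 64, 3 layers, 5 epochs)
fx_acc_entries <- function() {
  fx("acc_entries", function() {
    mols <- fx_acc_corpus()
    vocab <- fx_acc_vocab()
    frags <- fx_acc_frags("adafrag")
    lapply(seq_along(mols), function(i) {
      list(graph = build_heterograph(mols[[i]], frags[[i]], vocab,
                                     mol_ref = as.character(i)),
           mol = mols[[i]])
    })
  })
}

fx_acc_model <- function() {
  fx("acc_model", function() {
    pretrain(fx_acc_entries(), fx_acc_vocab(),
             model_config(hidden_dim = 64L, n_layers = 3L, seed = 7L),
             pretrain_config(strategy = "fragment", seed = 7L,
                             epochs_stage1 = 5L, lr = 0.005))
  })
}
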