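# Masking strategies: mask-ratio laws, connectivity, whole-fragment unions,
# label recording and idempotent application.

.mk_graph <- function(mol, v = fx_small_vocab()) {
  build_heterograph(mol, adafrag_fragment(mol, v), v)
}

test_that("the mask fraction law holds for every strategy", {
  mols <- fx_small_corpus()[1:6]
  v <- fx_small_vocab()
  set.seed(501)
  for (mol in mols) {
    g <- .mk_graph(mol, v)
    target <- ceiling(0.15 * g$n_atoms)
    for (strat in c("random", "bulk", "sidechain", "fragment")) {
      for (rep in 1:10) {
        plan <- suppressWarnings(plan_mask(g, mol, strat, 0.15))
        got <- length(plan$masked_atoms)
        if (strat == "fragment") {
          # within one fragment of the target
          over <- got - target
          expect_gte(over, 0L)
          if (over > 0L) {
            last_sizes <- g$fragment_sizes[plan$masked_fragments]
            expect_lte(over, max(last_sizes))
          }
        } else {
          expect_lte(abs(got - target), 1L)
        }
        expect_gte(got, 1L)
      }
    }
  }
})

test_that("a 100-atom molecule at ratio 0.15 masks exactly 15 atoms", {
  lib <- fx_lib()
  mol <- sequence_to_molecule(rep("K", 11), lib) # 11 lysines = 100 heavy atoms
  expect_identical(n_atoms(mol), 100L)
  g <- .mk_graph(mol)
  set.seed(1)
  plan <- plan_mask(g, mol, "random", 0.15)
  expect_identical(length(plan$masked_atoms), 15L)
})

test_that("fragment masking masks only whole fragments", {
  mols <- fx_small_corpus()[1:8]
  v <- fx_small_vocab()
  set.seed(502)
  for (mol in mols) {
    g <- .mk_graph(mol, v)
    plan <- plan_mask(g, mol, "fragment", 0.3)
    union_atoms <- sort(which(g$frag_of_atom %in% plan$masked_fragments))
    expect_identical(plan$masked_atoms, union_atoms)
    expect_identical(unname(plan$fragment_labels),
                     g$fragment_ids[plan$masked_fragments])
  }
})

test_that("bulk masking produces a connected masked set", {
  mols <- fx_small_corpus()[1:8]
  set.seed(503)
  for (mol in mols) {
    g <- .mk_graph(mol)
    plan <- plan_mask(g, mol, "bulk", 0.3)
    comp <- peptigraph:::.pt_components(mol, plan$masked_atoms)
    expect_length(comp, 1L)
  }
})

test_that("sidechain masking stays on side chains or falls back with warning", {
  lib <- fx_lib()
  mol <- sequence_to_molecule(rep(c("F", "W", "K"), 3), lib)
  g <- .mk_graph(mol)
  sc <- side_chain_atoms(mol)
  set.seed(504)
  plan <- plan_mask(g, mol, "sidechain", 0.15)
  expect_true(all(plan$masked_atoms %in% sc))
  # all-glycine: no side chains -> fallback
  gly <- sequence_to_molecule(rep("G", 5), lib)
  gg <- .mk_graph(gly)
  expect_warning(plan2 <- plan_mask(gg, gly, "sidechain", 0.15), "falling back")
  expect_gte(length(plan2$masked_atoms), 1L)
})

test_that("apply_mask is local, label-preserving and idempotent", {
  mol <- fx_small_corpus()[[2]]
  v <- fx_small_vocab()
  g <- .mk_graph(mol, v)
  set.seed(505)
  plan <- plan_mask(g, mol, "fragment", 0.25)
  masked <- apply_mask(g, plan)
  mask_cls <- peptigraph:::.pt_n_element_classes() + 1L
  expect_true(all(masked$graph$atom_features[plan$masked_atoms, "element"] == mask_cls))
  untouched <- setdiff(seq_len(g$n_atoms), plan$masked_atoms)
  expect_identical(masked$graph$atom_features[untouched, ],
                   g$atom_features[untouched, ])
  # labels recorded before overwrite: they are the original classes/ids
  expect_identical(unname(masked$atom_labels),
                   unname(g$atom_features[plan$masked_atoms, "element"]))
  expect_identical(unname(masked$fragment_labels),
                   g$fragment_ids[plan$masked_fragments])
  # other feature columns untouched even on masked rows
  expect_identical(masked$graph$atom_features[plan$masked_atoms, -1],
                   g$atom_features[plan$masked_atoms, -1])
  # idempotent
  again <- apply_mask(masked$graph, plan)
  expect_identical(again$graph$atom_features, masked$graph$atom_features)
  expect_identical(again$graph$fragment_ids, masked$graph$fragment_ids)
  # empty mask = identity
  empty <- plan
  empty$masked_atoms <- integer(0); empty$masked_fragments <- integer(0)
  empty$atom_labels <- stats::setNames(integer(0), character(0))
  empty$fragment_labels <- stats::setNames(integer(0), character(0))
  same <- apply_mask(g, empty)
  expect_identical(same$graph$atom_features, g$atom_features)
  # out-of-range plans are integrity errors
  bad <- plan; bad$masked_atoms <- c(bad$masked_atoms, g$n_atoms + 5L)
  expect_error(apply_mask(g, bad), "out of range")
})

test_that("mask planning is deterministic under a fixed seed", {
  mol <- fx_small_corpus()[[1]]
  g <- .mk_graph(mol)
  set.seed(77); p1 <- plan_mask(g, mol, "fragment", 0.2)
  set.seed(77); p2 <- plan_mask(g, mol, "fragment", 0.2)
  expect_identical(p1, p2)
})
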