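---
title: "Fragment-based heterogeneous-graph representation learning for peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based heterogeneous-graph representation learning for peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Peptide therapeutics increasingly use non-canonical amino acids — D-stereoisomers,
N-methylated residues, Aib, homologated side chains — to tune stability,
permeability and binding. Sequence-level protein language models cannot see
these chemistries at all, and small-molecule models treat a peptide as an
undifferentiated atom soup, ignoring its strong repetitive structure.
`peptigraph` works at the molecular graph level but re-introduces peptide
domain knowledge through *fragmentation*: molecules are partitioned into
chemically meaningful fragments, and a heterogeneous graph couples the atom
view, the fragment view and the junction (membership) view. An encoder
pre-trained by masked-attribute prediction on this graph yields embeddings
for downstream property prediction, covering canonical and non-canonical
residues uniformly.

## Molecules

Peptides enter the package either as monomer sequences or as SMILES.

* **Monomer library.** A TSV maps codes to SMILES carrying attachment dummy
  atoms: `[*:1]` marks the amine-side attachment (bonded to the backbone N),
  `[*:2]` the carboxyl side (bonded to the carbonyl C). The built-in library
  holds the 20 canonical L-amino acids, a small non-canonical set (D-Ala,
  D-Phe, Aib, sarcosine, N-methyl-Phe, norleucine, norvaline, homoserine,
  ornithine) and acetyl/amide caps. Monomers are stored dehydrated: the
  carboxyl hydroxyl lives on the attachment dummy, so condensation is pure
  bond rewiring (the C-terminal dummy becomes a hydroxyl oxygen; the
  N-terminal dummy vanishes into implicit hydrogens).
* **Assembly.** `sequence_to_molecule()` joins residues N-to-C by amide
  bonds, records `residue_of_atom`, and optionally closes a head-to-tail
  macrocycle. Side-chain cyclization is out of scope.
* **SMILES handling.** The package contains its own strict SMILES reader and
  writer over heavy-atom graphs (implicit hydrogens by a standard valence
  model; tetrahedral stereo with full neighbour-order bookkeeping; aromatic
  ring notation). Canonicalization is *not* hand-rolled: `canonical_key()`
  writes the (sub)graph with the package writer and lets OpenBabel produce
  the canonical form. Arbitrary input SMILES are validated by the package
  reader first — OpenBabel silently repairs malformed strings, so validation
  cannot be delegated to it — then canonicalized (which also performs
  aromaticity perception) and re-parsed. E/Z double-bond markers are read as
  plain single-bond symbols and dropped; peptide chemistry in scope carries
  no configured C=C. Tetrahedral centres whose substituents are all retained
  keep their configuration in subgraph keys; a centre that loses a
  substituent to a cut is no longer a defined stereocentre and is emitted
  without configuration.

## Fragmentation

Two operators and two baselines, all producing an exact partition of the
heavy atoms plus the list of cut bonds (so every fragmentation reassembles
into the original molecule — `reassemble()` is the information-preservation
oracle used throughout the tests).

* **Amiibo (domain knowledge).** Cuts every *acyclic single* bond between an
  amide nitrogen and its alpha carbon. The amide C(=O)–N bond itself is never
  cut, and ring bonds are never cut. For an n-residue proline-free linear
  peptide this yields exactly n fragments; proline's N–Cα lies in the
  pyrrolidine ring, so proline merges with the preceding fragment. The main
  design requirement is amide integrity; this cut rule is the minimal rule
  that realizes it while giving per-residue granularity, and it is isolated
  behind the module interface so a different cut chemistry can be swapped in.
* **BRICS.** The published retrosynthetic rule set (16 atom environments and
  their compatibility pairs, with the revised unified amine environment used
  by standard toolkits) is implemented natively as graph predicates; ring
  bonds are never cleavable. `brics_split()` treats an atom subset as a
  standalone capped molecule and cuts all internal BRICS bonds. The
  implementation is cross-checked in the test suite against an independent
  reference implementation on fixture molecules, including dipeptides and
  heteroaromatics.
* **AdaFrag (data driven).** `learn_vocabulary()` fragments a corpus with
  Amiibo, recursively BRICS-splits any fragment larger than
  `max_fragment_atoms`, canonical-keys every piece and counts keys exactly.
  The vocabulary is the reserved per-element single-atom entries (ids 0..11
  over the alphabet C, N, O, S, P, F, Cl, Br, I, B, Se, other) plus the up to
  `max_vocab` most frequent keys with count at least `min_freq`.
  `adafrag_fragment()` starts from Amiibo and recursively BRICS-splits any
  out-of-vocabulary (or oversized) fragment; an irreducible unknown fragment
  falls back to single atoms, which the reserved entries always cover — so
  every molecule is encodable by construction.
* **Baselines.** `atoms_only` puts every atom in its own fragment (plain
  molecular graph). `principal_subgraph` is the purely data-driven
  comparator: whole molecules are BRICS-split with no amide protection and a
  vocabulary mined the same way but without the Amiibo stage
  (`seed_method = "whole"`); it stands in for principal-subgraph-style
  tokenizers without reproducing their iterative pairwise-merge algorithm.

Defaults `min_freq = 2`, `max_vocab = 2000`, `max_fragment_atoms = 20` are
configuration-exposed; they bound vocabulary noise, size and fragment
granularity at values appropriate for desk-scale corpora. Determinism is
enforced everywhere: vocabulary ties break by frequency then byte-order
(C-locale) key comparison, fragments are ordered by minimum atom index, and
identical inputs give identical fragmentations across runs and platforms.
Fragment keys are canonical SMILES of the hydrogen-capped induced subgraph;
attachment-labelled keys would multiply the vocabulary for no modelling
benefit here.

## The heterogeneous graph

`build_heterograph()` assembles three views:

* **Atom view** — one node per heavy atom with categorical features (element
  class over the fixed 12-letter alphabet, degree bucket 0–5, formal charge
  bucket −2..+2, aromatic flag, implicit-H bucket 0–4, chirality index) and
  directed atom–atom edges in both directions with bond features (order,
  conjugation, ring membership).
* **Fragment view** — one node per fragment carrying its vocabulary id, with
  one directed fragment–fragment edge pair per cut bond.
* **Junction view** — realized as typed membership *edges* between atoms and
  their containing fragment (both directions), not as a third node set: the
  junction perspective links the other two views, and membership edges are
  the minimal faithful realization. This decision is isolated behind the
  graph type.

Count invariants (atom nodes = heavy atoms, aa-edges = 2×bonds, ff-edges =
2×cut bonds, junction edges = 2×atoms, fragment view = quotient of the atom
view under the partition) are property-tested across methods and corpora.

## Masking strategies and pre-training

Random masking of atom types is nearly trivial in peptides — the amide
repeat makes most masked atoms predictable from local patterns — so four
strategies are provided: `random` (uniform atoms), `bulk` (a breadth-first
ball grown from a random seed atom; the masked set is connected),
`sidechain` (uniform over side-chain atoms, with a logged fallback to random
when side chains are fewer than the target), and `fragment` (whole fragments
until the target atom count is reached, overshoot at most one fragment).
The backbone/side-chain split is detected structurally (amide units, alpha
carbons, terminal groups), leaving side-chain amides of Asn/Gln on the
side-chain side.

Masking replaces only node attributes: the masked atom's element class and
the masked fragment's vocabulary id each become a reserved MASK class. Other
atom features stay visible, and edge attributes are not masked — the
simplest faithful masked-attribute objective. The loss is

  L = CE(masked-atom element class) + lambda_frag · CE(masked-fragment vocabulary id)

with `lambda_frag = 1` by default, optimized by Adam (`lr = 0.003`,
`batch_size = 16`), mask ratio 0.15. None of ratio, optimizer or schedule is
prescribed by the underlying method description; these are the package's
choices, standard for masked pre-training at this scale. Training is fully
seeded and bit-reproducible; an epoch-0 metrics row records the loss at the
initial parameters, which for the atom term sits at −log(1/12) (uniform
softmax over the element classes) up to initialization noise.

**Two-stage schedule.** Stage 1 trains on canonical-only peptides, stage 2
continues from the stage-1 parameters on non-canonical peptides, with no
re-initialization. Both stages share one vocabulary learned on the union of
corpora, so non-canonical fragments are representable from the start and no
embedding table is resized mid-training. `epochs_stage2 = 0` gives the
one-stage ablation, with parameters identical to the stage-1 checkpoint.

## Encoder, fusion and pooling

Each message-passing layer applies per-edge-type linear transforms with sum
aggregation, a shared tanh update and a residual connection:

  za = Ha·W_sa + Agg_aa(Ha + bond-emb)·W_aa + Lift_fa(Hf)·W_ja + b_a
  zf = Hf·W_sf + Agg_ff(Hf)·W_ff + Agg_af(Ha)·W_jf + b_f
  Ha ← Ha + tanh(za),  Hf ← Hf + tanh(zf)

Four node-embedding variants share these layers: A (aa-edges only), F
(ff-edges only), AJ (aa + junction) and FJ (ff + junction). The fusion
strategy picks the atom-side and fragment-side variants — A&F, AJ&F or AJ&FJ
(default) — and each side is pooled *separately*, then concatenated into a
graph embedding of length 2·hidden_dim. Per-side pooling matches the
pairwise naming of the fusion strategies; joint pooling of mixed node types
would need an arbitrary type alignment. Pre-training predicts masked atoms
from the atom-side variant and masked fragments from the fragment-side
variant, so fusion ablations carry through to the objective.

Pooling options: elementwise max, elementwise mean, and a gated recurrent
readout (final hidden state of a single-layer GRU run from a zero state over
the nodes in canonical order — atom index order of the parsed canonical
SMILES; fragments by minimum atom index). Max and mean are permutation
invariant; the recurrent readout is order-dependent but reproducible because
the canonical order is a function of the input. The GRU readout is the
package default, reflecting its strength in downstream fine-tuning when the
whole model (including the recurrence) is trained. For *frozen-probe*
evaluations against labels that are linear in fragment counts, the averaged
readout is the appropriate choice and is what the acceptance checks use:
mean pooling preserves composition linearly, whereas an untrained random
recurrence progressively forgets early nodes and encodes composition poorly.

All gradients — through the layers, both classifier heads, the perceptron
fine-tuning head and the GRU recurrence — are derived and implemented by
hand (no autodiff dependency exists in the target environment) and verified
against central-difference numerical gradients to ~1e-6 relative error in
the test suite.

## Fine-tuning and metrics

`finetune()` puts a 2-layer perceptron head on the graph embedding:
squared-error loss for regression, logistic for binary classification.
`frozen_probe` mode leaves the backbone untouched and fits only the head
(an ordinary small MLP fit, delegated to `nnet`; the head is deliberately
small — BFGS cost grows quadratically in the weight count). `full` mode
backpropagates through pooling and the encoder with the package's own
gradient machinery. Reported metrics are Spearman rank correlation
(regression; ties by average ranks; constant inputs are an error, not NaN)
and rank-based AUC with midrank tie correction (binary); both are
cross-checked against worked hand-computed values and, for AUC, against an
independent reference implementation.

## Synthetic data

`generate_corpus()` samples peptides uniformly over a monomer pool and a
length range (default 2–30 residues — the short-peptide envelope the
framework targets; longer sequences are out of the modelled range). A
planted contiguous motif can be written into an exact fraction of sequences
at uniform positions; non-planted sequences are resampled if they contain
the motif by chance, so occurrence counts are exact. `generate_labels()`
produces labels that are *linear in fragment counts* plus Gaussian noise
(or a median-thresholded binary version, ties positive). This is the
simplest label structure for which embedding quality is directly measurable:
an embedding that preserves fragment composition must recover such labels
under a frozen probe.

What the generator does *not* emulate: real membrane-permeability physics or
binding energetics, realistic residue usage frequencies, side-chain
cyclization, and long-range conformational effects. Passing the recovery
checks therefore demonstrates that the pipeline preserves and exposes
fragment-level composition — not that it predicts any particular laboratory
property.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path at statistically meaningful sizes: corpora of
300–500 molecules (canonical plus non-canonical, lengths 2–30) for the
fragmentation, graph and masking laws; hidden width 32–64, 3 layers and 4–5
epochs for pre-training sanity; 3–5 seeds for the stochastic comparisons.
Vocabulary learning, fragmentation and reassembly are exact operations, so
their checks use exact equality. Stochastic checks (masked-attribute
accuracy above the majority-element baseline, frozen-probe Spearman, the
masking and two-stage ablation directions) fix all seeds and compare against
pre-registered bounds; the ablation directions are reported as directions
rather than hard-failed, since at desk scale seed noise can overturn small
ordering effects.

Other numerical conventions: atom indices are 1-based internally (idiomatic
R) and 0-based in every serialized interface (fragment TSV, graph JSON);
vocabulary ids are 0-based with the reserved single-atom block first; all
string tie-breaks use byte order rather than locale collation; structure
equality at corpus scale short-circuits through the deterministic writer
(identical writer output implies identical canonical key) before consulting
OpenBabel.

## Known limitations

* The Amiibo cut chemistry and the vocabulary algorithm are this package's
  explicit realizations of their design goals (amide preservation;
  frequency-mined BRICS refinement); both are isolated behind the
  `fragmentation` module interface for replacement.
* Proline and other N-alkylated rings merge with the preceding fragment.
* Fragment keys drop the configuration of stereocentres broken by a cut.
* The data-driven baseline approximates principal-subgraph tokenizers by
  frequency-mined BRICS pieces; the iterative pairwise-merge algorithm is
  not reproduced.
* OpenBabel canonicalization dominates run time for large molecules; the
  package batches canonicalization and avoids it where determinism of its
  own writer suffices.
* Full-scale pre-training (millions of sequences) is out of scope; the
  package is a complete, testable desk-scale implementation of the method.
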