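# Encoder, pooling, metrics and fine-tuning heads.

test_that("max and avg pooling match hand arithmetic", {
  X <- rbind(c(1, 3), c(3, 5))
  expect_identical(pool(X, "avg"), c(2, 4))
  expect_identical(pool(X, "max"), c(3, 5))
  expect_error(pool(X[0, , drop = FALSE], "avg"), "at least one")
})

test_that("gru pooling matches an independently coded recurrence", {
  d <- 6L
  cfg <- model_config(hidden_dim = d, n_layers = 1L, seed = 42L)
  params <- init_model_params(cfg, n_vocab = 20L)
  sig <- function(x) 1 / (1 + exp(-x))
  # hand-rolled gated recurrence with the same parameters
  hand_gru <- function(X) {
    h <- numeric(d)
    for (t in seq_len(nrow(X))) {
      x <- X[t, ]
      z <- sig(x %*% params$gru_Wz + h %*% params$gru_Uz + params$gru_bz)
      r <- sig(x %*% params$gru_Wr + h %*% params$gru_Ur + params$gru_br)
      nn <- tanh(x %*% params$gru_Wn + (drop(r) * h) %*% params$gru_Un + params$gru_bn)
      h <- drop((1 - z) * nn + z * h)
    }
    h
  }
  set.seed(1)
  X1 <- matrix(rnorm(d), 1)
  expect_equal(pool(X1, "gru", params), hand_gru(X1), tolerance = 1e-12)
  X5 <- matrix(rnorm(5 * d), 5)
  expect_equal(pool(X5, "gru", params), hand_gru(X5), tolerance = 1e-12)
  expect_error(pool(X5, "gru"), "recurrent parameters")
})

test_that("encode is deterministic and sensitive to the fusion strategy", {
  mol <- fx_small_corpus()[[4]]
  v <- fx_small_vocab()
  g <- build_heterograph(mol, adafrag_fragment(mol, v), v)
  base <- model_config(hidden_dim = 16L, n_layers = 2L, seed = 1L)
  params <- init_model_params(base, n_vocab(v))
  e1 <- encode(g, params, base)
  e2 <- encode(g, params, base)
  expect_identical(e1$graph_embedding, e2$graph_embedding)
  expect_true(all(is.finite(e1$graph_embedding)))
  expect_length(e1$graph_embedding, 32L)
  # junction messages perturb the embedding for every tested seed
  for (s in 1:5) {
    cfgA <- model_config(hidden_dim = 16L, n_layers = 2L, fusion = "A_F", seed = s)
    cfgJ <- model_config(hidden_dim = 16L, n_layers = 2L, fusion = "AJ_FJ", seed = s)
    p <- init_model_params(cfgA, n_vocab(v))
    expect_false(isTRUE(all.equal(encode(g, p, cfgA)$graph_embedding,
                                  encode(g, p, cfgJ)$graph_embedding)))
  }
})

test_that("max/avg readouts are invariant to atom order, gru is not", {
  mol <- fx_small_corpus()[[5]]
  v <- fx_small_vocab()
  fr <- adafrag_fragment(mol, v)
  g <- build_heterograph(mol, fr, v)
  # permute atom indices of the graph wholesale
  set.seed(9)
  perm <- sample.int(g$n_atoms)
  inv <- order(perm)
  gp <- g
  gp$atom_features <- g$atom_features[inv, , drop = FALSE]
  gp$edges_aa <- cbind(from = perm[g$edges_aa[, 1]], to = perm[g$edges_aa[, 2]])[, c(1, 2)]
  colnames(gp$edges_aa) <- c("from", "to")
  gp$frag_of_atom <- g$frag_of_atom[inv]
  gp$edges_junction <- rbind(
    cbind(atom = seq_len(g$n_atoms), fragment = gp$frag_of_atom, dir = 1L),
    cbind(atom = seq_len(g$n_atoms), fragment = gp$frag_of_atom, dir = 2L)
  )
  cfg <- model_config(hidden_dim = 12L, n_layers = 2L, pooling = "avg", seed = 3L)
  params <- init_model_params(cfg, n_vocab(v))
  ea <- encode(g, params, cfg)$graph_embedding
  ep <- encode(gp, params, cfg)$graph_embedding
  expect_equal(ea, ep, tolerance = 1e-10)
  cfgm <- model_config(hidden_dim = 12L, n_layers = 2L, pooling = "max", seed = 3L)
  expect_equal(encode(g, params, cfgm)$graph_embedding,
               encode(gp, params, cfgm)$graph_embedding, tolerance = 1e-10)
  cfgg <- model_config(hidden_dim = 12L, n_layers = 2L, pooling = "gru", seed = 3L)
  expect_false(isTRUE(all.equal(encode(g, params, cfgg)$graph_embedding,
                                encode(gp, params, cfgg)$graph_embedding)))
})

test_that("analytic gradients match numerical differentiation", {
  lib <- fx_lib()
  mols <- list(sequence_to_molecule(c("G", "A"), lib))
  v <- learn_vocabulary(mols, min_freq = 1L)
  entries <- prepare_graphs(mols, v)
  mc <- model_config(hidden_dim = 6L, n_layers = 2L, seed = 3L)
  pc <- pretrain_config(strategy = "fragment", seed = 3L, lambda_frag = 0.7)
  params <- init_model_params(mc, n_vocab(v))
  grads <- peptigraph:::.pt_zero_grads(params)
  set.seed(42)
  peptigraph:::.pt_masked_loss(entries[[1]], params, mc, pc, grads)
  numgrad <- function(nm, i, j) {
    eps <- 1e-6
    p2 <- params; p2[[nm]][i, j] <- p2[[nm]][i, j] + eps
    set.seed(42); l1 <- peptigraph:::.pt_masked_loss(entries[[1]], p2, mc, pc)$loss
    p2[[nm]][i, j] <- p2[[nm]][i, j] - 2 * eps
    set.seed(42); l2 <- peptigraph:::.pt_masked_loss(entries[[1]], p2, mc, pc)$loss
    (l1 - l2) / (2 * eps)
  }
  for (spec in list(c("W_in", 1, 2), c("W_sa1", 3, 4), c("W_aa2", 1, 1),
                    c("W_ja1", 2, 2), c("W_jf2", 2, 1), c("W_elem", 4, 5),
                    c("W_fragcls", 2, 2), c("E_frag", 13, 3))) {
    nm <- spec[1]; i <- as.integer(spec[2]); j <- as.integer(spec[3])
    expect_equal(get(nm, envir = grads)[i, j], numgrad(nm, i, j),
                 tolerance = 1e-5, label = nm)
  }
})

test_that("spearman matches the hand-computed worked examples", {
  expect_identical(spearman(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(spearman(c(1, 2, 3), c(3, 2, 1)), -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with d = (0-2, 1-(-1), ...) => sum(d^2) = 6, n = 3
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2)), -0.5, tolerance = 1e-12)
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman(1, 2), "length")
})

test_that("auc matches pair enumeration and the pROC reference", {
  expect_identical(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # 4 positive-negative pairs, 3 concordant: AUC = 0.75
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75, tolerance = 1e-12)
  expect_error(auc(c(0.2, 0.3), c(1, 1)), "both classes")
  set.seed(8)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<")))
  expect_equal(auc(sc, lb), ref, tolerance = 1e-12)
})

test_that("a frozen probe recovers labels that are linear in the embedding", {
  lib <- fx_lib()
  v <- fx_small_vocab()
  set.seed(4002)
  pool <- c("A", "G", "F", "S", "K", "P", "W", "dA", "Aib", "Sar", "Nle")
  mols <- lapply(1:150, function(i) {
    sequence_to_molecule(sample(pool, sample(2:8, 1), replace = TRUE), lib)
  })
  entries <- prepare_graphs(mols, v)
  # identifiability needs more training points than embedding dimensions,
  # and enough held-out points that single rank swaps cannot dominate
  cfg <- model_config(hidden_dim = 8L, n_layers = 2L, pooling = "avg", seed = 5L)
  params <- init_model_params(cfg, n_vocab(v))
  emb <- embed_corpus(entries, params, cfg)
  set.seed(6)
  w <- rnorm(ncol(emb))
  y <- drop(scale(emb) %*% w)
  ft <- finetune(entries, y, "regression", params, cfg, mode = "frozen_probe",
                 seed = 1L, embeddings = emb, maxit = 1000L, decay = 1e-4,
                 head_hidden = 16L, heldout_fraction = 1 / 3)
  expect_gte(unname(ft$metric), 0.95)
})

test_that("binary fine-tuning rejects single-class training labels", {
  mols <- fx_small_corpus()[1:10]
  v <- fx_small_vocab()
  entries <- prepare_graphs(mols, v)
  cfg <- model_config(hidden_dim = 8L, n_layers = 1L, seed = 2L)
  params <- init_model_params(cfg, n_vocab(v))
  expect_error(
    finetune(entries, rep(1L, 10), "binary", params, cfg, seed = 1L),
    "single class"
  )
})

test_that("full fine-tuning improves the training objective", {
  mols <- fx_small_corpus()[1:30]
  v <- fx_small_vocab()
  entries <- prepare_graphs(mols, v)
  cfg <- model_config(hidden_dim = 8L, n_layers = 1L, pooling = "avg", seed = 4L)
  params <- init_model_params(cfg, n_vocab(v))
  # nitrogen fraction: a composition signal visible to the averaged readout
  y <- drop(scale(vapply(mols, function(m) mean(m$atoms$element == "N"), numeric(1))))
  ft <- finetune(entries, y, "regression", params, cfg, mode = "full",
                 epochs = 30L, lr = 0.01, seed = 2L, heldout_fraction = 0.3)
  # backbone parameters were updated
  expect_false(isTRUE(all.equal(ft$params$W_in, params$W_in)))
  expect_true(all(is.finite(ft$predictions)))
  expect_gte(unname(ft$metric), 0.5)
})
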