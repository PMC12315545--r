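# Masked-attribute self-supervised pre-training. Masked atoms are predicted
# (their element class) from the atom-side view variant; masked fragments
# (their vocabulary id) from the fragment-side variant. The two-stage
# schedule first trains on canonical-only peptides and then continues, with
# the same parameters and the same vocabulary, on non-canonical peptides.

#' Pre-training configuration
#'
#' @param mask_ratio fraction of atoms to mask (default 0.15).
#' @param strategy masking strategy (default `"fragment"`).
#' @param epochs_stage1,epochs_stage2 epochs for the two training stages.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed root seed; fixes parameter initialization and all sampling.
#' @param lambda_frag weight of the masked-fragment cross-entropy term.
#' @param heldout_fraction fraction of the corpus held out for the
#'   masked-attribute accuracy metric.
#' @return a `pretrain_config` list.
#' @export
pretrain_config <- function(mask_ratio = 0.15,
                            strategy = c("fragment", "random", "bulk", "sidechain"),
                            epochs_stage1 = 5L, epochs_stage2 = 3L,
                            batch_size = 16L, lr = 0.003, seed = 1L,
                            lambda_frag = 1.0, heldout_fraction = 0.1) {
  strategy <- match.arg(strategy)
  stopifnot(mask_ratio > 0, mask_ratio < 1, heldout_fraction >= 0,
            heldout_fraction < 1)
  structure(list(
    mask_ratio = mask_ratio, strategy = strategy,
    epochs_stage1 = as.integer(epochs_stage1),
    epochs_stage2 = as.integer(epochs_stage2),
    batch_size = as.integer(batch_size), lr = lr, seed = as.integer(seed),
    lambda_frag = lambda_frag, heldout_fraction = heldout_fraction
  ), class = "pretrain_config")
}

#' Build heterogeneous graphs for a corpus
#'
#' Fragments every molecule with AdaFrag (vocabulary coverage guaranteed) and
#' builds the heterogeneous graph.
#'
#' @param corpus list of `pep_mol`.
#' @param vocab a `fragment_vocabulary`.
#' @return list of lists with elements `graph` and `mol`.
#' @export
prepare_graphs <- function(corpus, vocab) {
  lapply(seq_along(corpus), function(i) {
    mol <- corpus[[i]]
    frag <- adafrag_fragment(mol, vocab)
    list(graph = build_heterograph(mol, frag, vocab,
                                   mol_ref = names(corpus)[i] %||% as.character(i)),
         mol = mol)
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

.pt_zero_grads <- function(params) {
  g <- new.env(hash = TRUE, parent = emptyenv())
  for (nm in setdiff(names(params), "n_vocab")) {
    assign(nm, params[[nm]] * 0, envir = g)
  }
  g
}

.pt_adam_init <- function(params) {
  list(
    m = lapply(params[setdiff(names(params), "n_vocab")], function(x) x * 0),
    v = lapply(params[setdiff(names(params), "n_vocab")], function(x) x * 0),
    t = 0L
  )
}

.pt_adam_step <- function(params, grads, state, lr,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(state$m)) {
    g <- get(nm, envir = grads)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# loss + gradients of one masked graph; accumulates into `grads` when
# provided (predict-only mode otherwise)
.pt_masked_loss <- function(entry, params, mconfig, pconfig, grads = NULL) {
  graph <- entry$graph; mol <- entry$mol
  plan <- plan_mask(graph, mol, pconfig$strategy, pconfig$mask_ratio)
  masked <- apply_mask(graph, plan)
  tn <- .pt_graph_tensors(masked$graph)
  sides <- .pt_fusion_sides(mconfig$fusion)
  fa <- sides$atom; ff <- sides$frag
  fwdA <- .pt_forward_variant(tn, params, mconfig, fa["aa"], fa["ff"], fa["j"])
  ma <- plan$masked_atoms
  logits_a <- sweep(fwdA$Ha[ma, , drop = FALSE] %*% params$W_elem, 2, params$b_elem, "+")
  ce_a <- .pt_softmax_ce(logits_a, unname(masked$atom_labels))
  acc_a <- mean(max.col(ce_a$p) == unname(masked$atom_labels))

  frag_loss <- 0; acc_f <- NA_real_
  fwdF <- NULL; ce_f <- NULL; mf <- plan$masked_fragments
  if (pconfig$strategy == "fragment" && length(mf) > 0L) {
    fwdF <- .pt_forward_variant(tn, params, mconfig, ff["aa"], ff["ff"], ff["j"])
    logits_f <- sweep(fwdF$Hf[mf, , drop = FALSE] %*% params$W_fragcls, 2,
                      params$b_fragcls, "+")
    ce_f <- .pt_softmax_ce(logits_f, unname(masked$fragment_labels) + 1L)
    frag_loss <- ce_f$loss
    acc_f <- mean(max.col(ce_f$p) == unname(masked$fragment_labels) + 1L)
  }

  if (!is.null(grads)) {
    add <- function(nm, val) assign(nm, get(nm, envir = grads) + val, envir = grads)
    dHa <- matrix(0, tn$n_atoms, mconfig$hidden_dim)
    dHa[ma, ] <- ce_a$dlogits %*% t(params$W_elem)
    add("W_elem", crossprod(fwdA$Ha[ma, , drop = FALSE], ce_a$dlogits))
    add("b_elem", colSums(ce_a$dlogits))
    dHf0 <- matrix(0, tn$n_frag, mconfig$hidden_dim)
    .pt_backward_variant(fwdA, tn, params, mconfig, dHa, dHf0, grads)
    if (!is.null(fwdF)) {
      lam <- pconfig$lambda_frag
      if (lam != 0) {
        dHf <- matrix(0, tn$n_frag, mconfig$hidden_dim)
        dHf[mf, ] <- lam * (ce_f$dlogits %*% t(params$W_fragcls))
        add("W_fragcls", lam * crossprod(fwdF$Hf[mf, , drop = FALSE], ce_f$dlogits))
        add("b_fragcls", lam * colSums(ce_f$dlogits))
        dHa0 <- matrix(0, tn$n_atoms, mconfig$hidden_dim)
        .pt_backward_variant(fwdF, tn, params, mconfig, dHa0, dHf, grads)
      }
    }
  }
  list(loss = ce_a$loss + pconfig$lambda_frag * frag_loss,
       atom_loss = ce_a$loss, frag_loss = frag_loss,
       atom_acc = acc_a, frag_acc = acc_f)
}

# one training stage over prepared graphs; RNG state flows through
.pt_train_loop <- function(entries, params, mconfig, pconfig, epochs, adam,
                           stage = 1L) {
  n <- length(entries)
  n_hold <- floor(pconfig$heldout_fraction * n)
  hold_idx <- if (n_hold > 0L) sample.int(n, n_hold) else integer(0)
  train_idx <- setdiff(seq_len(n), hold_idx)
  metrics <- NULL
  eval_heldout <- function() {
    if (length(hold_idx) == 0L) return(c(NA_real_, NA_real_))
    res <- lapply(entries[hold_idx], .pt_masked_loss, params = params,
                  mconfig = mconfig, pconfig = pconfig)
    c(mean(vapply(res, `[[`, numeric(1), "atom_acc")),
      mean(vapply(res, `[[`, numeric(1), "frag_acc"), na.rm = TRUE))
  }
  # epoch 0: initial loss at current parameters, no update
  init <- lapply(entries[train_idx], .pt_masked_loss, params = params,
                 mconfig = mconfig, pconfig = pconfig)
  hv <- eval_heldout()
  metrics <- rbind(metrics, data.frame(
    stage = stage, epoch = 0L,
    loss = mean(vapply(init, `[[`, numeric(1), "loss")),
    atom_loss = mean(vapply(init, `[[`, numeric(1), "atom_loss")),
    frag_loss = mean(vapply(init, `[[`, numeric(1), "frag_loss")),
    heldout_atom_acc = hv[1], heldout_frag_acc = hv[2]
  ))
  for (ep in seq_len(epochs)) {
    perm <- sample(train_idx)
    losses <- atom_losses <- frag_losses <- numeric(0)
    i <- 1L
    while (i <= length(perm)) {
      batch <- perm[i:min(i + pconfig$batch_size - 1L, length(perm))]
      grads <- .pt_zero_grads(params)
      for (bi in batch) {
        r <- .pt_masked_loss(entries[[bi]], params, mconfig, pconfig, grads)
        losses <- c(losses, r$loss)
        atom_losses <- c(atom_losses, r$atom_loss)
        frag_losses <- c(frag_losses, r$frag_loss)
      }
      for (nm in ls(grads)) {
        assign(nm, get(nm, envir = grads) / length(batch), envir = grads)
      }
      st <- .pt_adam_step(params, grads, adam, pconfig$lr)
      params <- st$params; adam <- st$state
      i <- i + pconfig$batch_size
    }
    if (any(!is.finite(losses))) {
      stop(sprintf("divergent (non-finite) loss in epoch %d; lower the learning rate", ep))
    }
    hv <- eval_heldout()
    metrics <- rbind(metrics, data.frame(
      stage = stage, epoch = ep, loss = mean(losses),
      atom_loss = mean(atom_losses), frag_loss = mean(frag_losses),
      heldout_atom_acc = hv[1], heldout_frag_acc = hv[2]
    ))
  }
  list(params = params, metrics = metrics, adam = adam)
}

#' Masked-attribute pre-training on a peptide corpus
#'
#' Minimizes masked-atom element cross-entropy plus `lambda_frag` times the
#' masked-fragment vocabulary cross-entropy with Adam. Fully seeded; per-epoch
#' training loss and held-out masked-attribute accuracy are recorded,
#' including an epoch-0 row at the initial parameters.
#'
#' @param corpus list of `pep_mol` (or pre-built entries from
#'   [prepare_graphs()]).
#' @param vocab a `fragment_vocabulary`.
#' @param mconfig a `model_config`.
#' @param pconfig a `pretrain_config`.
#' @param params optional starting parameters (continued training).
#' @param epochs number of epochs (default `pconfig$epochs_stage1`).
#' @return a `pretrain_model`: parameters, configs, per-epoch metrics.
#' @export
pretrain <- function(corpus, vocab, mconfig = model_config(),
                     pconfig = pretrain_config(), params = NULL,
                     epochs = pconfig$epochs_stage1) {
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  entries <- if (!is.null(corpus[[1]]$graph)) corpus else prepare_graphs(corpus, vocab)
  set.seed(pconfig$seed)
  if (is.null(params)) params <- init_model_params(mconfig, n_vocab(vocab))
  adam <- .pt_adam_init(params)
  res <- .pt_train_loop(entries, params, mconfig, pconfig, epochs, adam)
  structure(list(
    params = res$params, mconfig = mconfig, pconfig = pconfig,
    metrics = res$metrics, n_vocab = n_vocab(vocab)
  ), class = "pretrain_model")
}

#' Two-stage pre-training (canonical, then non-canonical)
#'
#' Stage 1 trains on the canonical corpus; stage 2 continues from the stage-1
#' parameters (no re-initialization) on the non-canonical corpus. Both stages
#' share one vocabulary (learned on the union of corpora) so that stage-2
#' fragments are representable from the start. `epochs_stage2 = 0` gives the
#' one-stage ablation: parameters identical to the stage-1 checkpoint.
#'
#' @param stage1_corpus,stage2_corpus lists of `pep_mol` (or prepared
#'   entries).
#' @param vocab shared `fragment_vocabulary`.
#' @param mconfig,pconfig model and pre-training configuration.
#' @return a `pretrain_model` with `stage1_params` checkpoint and combined
#'   metrics.
#' @export
two_stage_pretrain <- function(stage1_corpus, stage2_corpus, vocab,
                               mconfig = model_config(),
                               pconfig = pretrain_config()) {
  if (length(stage1_corpus) == 0L || length(stage2_corpus) == 0L) {
    stop("both corpora must be non-empty")
  }
  e1 <- if (!is.null(stage1_corpus[[1]]$graph)) stage1_corpus else prepare_graphs(stage1_corpus, vocab)
  e2 <- if (!is.null(stage2_corpus[[1]]$graph)) stage2_corpus else prepare_graphs(stage2_corpus, vocab)
  set.seed(pconfig$seed)
  params <- init_model_params(mconfig, n_vocab(vocab))
  adam <- .pt_adam_init(params)
  r1 <- .pt_train_loop(e1, params, mconfig, pconfig, pconfig$epochs_stage1, adam,
                       stage = 1L)
  stage1_params <- r1$params
  r2 <- if (pconfig$epochs_stage2 > 0L) {
    .pt_train_loop(e2, r1$params, mconfig, pconfig, pconfig$epochs_stage2,
                   r1$adam, stage = 2L)
  } else {
    list(params = r1$params, metrics = NULL, adam = r1$adam)
  }
  structure(list(
    params = r2$params, stage1_params = stage1_params,
    mconfig = mconfig, pconfig = pconfig,
    metrics = rbind(r1$metrics, r2$metrics), n_vocab = n_vocab(vocab)
  ), class = "pretrain_model")
}

#' @export
print.pretrain_model <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(
    "<pretrain_model> hidden_dim=%d, layers=%d, fusion=%s, vocab=%d; final loss %.4f, held-out masked-atom acc %.3f\n",
    x$mconfig$hidden_dim, x$mconfig$n_layers, x$mconfig$fusion, x$n_vocab,
    last$loss, last$heldout_atom_acc
  ))
  invisible(x)
}
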