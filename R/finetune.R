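# Embedding extraction and supervised fine-tuning. The graph-level embedding
# is the concatenation of the pooled atom-side and fragment-side
# representations selected by the fusion strategy (length 2 x hidden_dim).

#' Encode a heterogeneous graph into embeddings
#'
#' A pure, deterministic function of (graph, params, config). The fusion
#' strategy selects the atom-side variant (A or AJ) and fragment-side variant
#' (F or FJ); each side is pooled independently and the two pooled vectors
#' concatenated.
#'
#' @param graph a `hetero_graph`.
#' @param params model parameters ([init_model_params()] or a trained
#'   `pretrain_model$params`).
#' @param config a `model_config`.
#' @return an `embedding_result`: `atom_embeddings` (n_atoms x d),
#'   `fragment_embeddings` (n_fragments x d), `graph_embedding` (length 2d).
#' @export
encode <- function(graph, params, config) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (ncol(params$W_in) != config$hidden_dim) {
    stop("parameter dimensions do not match the configuration")
  }
  tn <- .pt_graph_tensors(graph)
  sides <- .pt_fusion_sides(config$fusion)
  fa <- sides$atom; ff <- sides$frag
  fwdA <- .pt_forward_variant(tn, params, config, fa["aa"], fa["ff"], fa["j"])
  fwdF <- .pt_forward_variant(tn, params, config, ff["aa"], ff["ff"], ff["j"])
  pa <- pool(fwdA$Ha, config$pooling, params)
  pf <- pool(fwdF$Hf, config$pooling, params)
  structure(list(
    atom_embeddings = fwdA$Ha,
    fragment_embeddings = fwdF$Hf,
    graph_embedding = c(pa, pf)
  ), class = "embedding_result")
}

#' Graph-level embeddings for a corpus
#'
#' @param entries prepared entries ([prepare_graphs()]) or a list of
#'   `hetero_graph`.
#' @param params,config as in [encode()].
#' @return numeric matrix, one row per graph (2 x hidden_dim columns).
#' @export
embed_corpus <- function(entries, params, config) {
  t(vapply(entries, function(e) {
    g <- if (inherits(e, "hetero_graph")) e else e$graph
    encode(g, params, config)$graph_embedding
  }, numeric(2L * config$hidden_dim)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("spearman needs two equal-length vectors of length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman undefined for constant input")
  }
  stats::cor(x, y, method = "spearman")
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney statistic with midrank tie correction.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("auc needs both classes present")
  r <- rank(scores) # average ranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# 2-layer perceptron head (tanh hidden layer) forward/backward used by the
# full fine-tuning mode
.pt_head_init <- function(in_dim, hidden) {
  list(
    W_h1 = matrix(stats::rnorm(in_dim * hidden, sd = sqrt(1 / in_dim)), in_dim, hidden),
    b_h1 = numeric(hidden),
    W_h2 = matrix(stats::rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1),
    b_h2 = 0
  )
}

.pt_head_forward <- function(head, x) {
  a1 <- drop(x %*% head$W_h1) + head$b_h1
  h1 <- tanh(a1)
  yhat <- drop(h1 %*% head$W_h2) + head$b_h2
  list(a1 = a1, h1 = h1, yhat = yhat)
}

#' Fine-tune on labelled peptides
#'
#' A 2-layer perceptron head on the graph embedding; squared-error loss for
#' regression, logistic loss for binary classification. `frozen_probe` keeps
#' the backbone untouched and fits only the head (via `nnet`); `full`
#' backpropagates through pooling and the encoder as well. Performance is
#' reported as Spearman correlation (regression) or AUC (binary) on a
#' held-out split.
#'
#' @param entries prepared entries ([prepare_graphs()]).
#' @param labels numeric (regression) or 0/1 (binary) labels.
#' @param task `"regression"` or `"binary"`.
#' @param params backbone parameters.
#' @param config a `model_config`.
#' @param mode `"frozen_probe"` or `"full"`.
#' @param heldout_fraction held-out fraction for evaluation.
#' @param head_hidden hidden units of the perceptron head.
#' @param epochs,lr training schedule for `full` mode.
#' @param seed seed for the split, head initialization and training order.
#' @param embeddings optional precomputed [embed_corpus()] matrix
#'   (frozen_probe only); avoids re-encoding when probing repeatedly.
#' @param maxit optimizer iteration cap for the frozen-probe head fit. The
#'   head is kept small (BFGS cost grows quadratically in the weight count).
#' @param decay weight decay of the frozen-probe head fit.
#' @return list with `metric` (named value), `predictions`, `heldout_idx`,
#'   `head` (head parameters or the nnet fit), and for `full` mode the
#'   updated backbone `params`.
#' @export
finetune <- function(entries, labels, task = c("regression", "binary"),
                     params, config, mode = c("frozen_probe", "full"),
                     heldout_fraction = 0.2, head_hidden = 16L,
                     epochs = 30L, lr = 0.003, seed = 1L, embeddings = NULL,
                     maxit = 150L, decay = 1e-2) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  n <- length(entries)
  stopifnot(length(labels) == n, n >= 5L)
  if (any(!is.finite(labels))) stop("labels must be finite")
  set.seed(seed)
  hold <- sample.int(n, max(1L, floor(heldout_fraction * n)))
  train <- setdiff(seq_len(n), hold)
  if (task == "binary" && length(unique(labels[train])) < 2L) {
    stop("degenerate binary task: training labels contain a single class")
  }

  if (mode == "frozen_probe") {
    emb <- if (is.null(embeddings)) embed_corpus(entries, params, config) else embeddings
    sc <- apply(emb, 2, stats::sd); sc[sc == 0] <- 1
    ctr <- colMeans(emb)
    Z <- sweep(sweep(emb, 2, ctr), 2, sc, "/")
    fit <- if (task == "regression") {
      nnet::nnet(Z[train, , drop = FALSE], matrix(labels[train]),
                 size = head_hidden, linout = TRUE, decay = decay,
                 maxit = maxit, trace = FALSE, MaxNWts = 100000L)
    } else {
      nnet::nnet(Z[train, , drop = FALSE], matrix(labels[train]),
                 size = head_hidden, entropy = TRUE, decay = decay,
                 maxit = maxit, trace = FALSE, MaxNWts = 100000L)
    }
    pred <- drop(stats::predict(fit, Z))
    metric <- if (task == "regression") {
      c(spearman = spearman(pred[hold], labels[hold]))
    } else {
      c(auc = auc(pred[hold], labels[hold]))
    }
    return(list(metric = metric, predictions = pred, heldout_idx = hold,
                head = fit, mode = mode))
  }

  # full fine-tuning: backprop through head, pooling and encoder
  d2 <- 2L * config$hidden_dim
  head <- .pt_head_init(d2, head_hidden)
  params$W_h1 <- head$W_h1; params$b_h1 <- head$b_h1
  params$W_h2 <- head$W_h2; params$b_h2 <- head$b_h2
  adam <- .pt_adam_init(params)
  sides <- .pt_fusion_sides(config$fusion)
  fa <- sides$atom; ffl <- sides$frag
  d <- config$hidden_dim

  one_pass <- function(entry, y, params, grads = NULL) {
    g <- entry$graph
    tn <- .pt_graph_tensors(g)
    fwdA <- .pt_forward_variant(tn, params, config, fa["aa"], fa["ff"], fa["j"])
    fwdF <- .pt_forward_variant(tn, params, config, ffl["aa"], ffl["ff"], ffl["j"])
    gruA <- if (config$pooling == "gru") .pt_gru_forward(fwdA$Ha, params) else NULL
    gruF <- if (config$pooling == "gru") .pt_gru_forward(fwdF$Hf, params) else NULL
    pa <- if (is.null(gruA)) pool(fwdA$Ha, config$pooling, params) else gruA$h
    pf <- if (is.null(gruF)) pool(fwdF$Hf, config$pooling, params) else gruF$h
    x <- c(pa, pf)
    hf <- .pt_head_forward(params, x)
    if (task == "regression") {
      err <- hf$yhat - y
      loss <- err^2
      dy <- 2 * err
    } else {
      p <- .pt_sigmoid(hf$yhat)
      loss <- -(y * log(max(p, 1e-12)) + (1 - y) * log(max(1 - p, 1e-12)))
      dy <- p - y
    }
    if (!is.null(grads)) {
      add <- function(nm, val) assign(nm, get(nm, envir = grads) + val, envir = grads)
      dW_h2 <- matrix(hf$h1 * dy, ncol = 1)
      dh1 <- drop(params$W_h2) * dy
      da1 <- dh1 * (1 - hf$h1^2)
      add("W_h2", dW_h2); add("b_h2", dy)
      add("W_h1", outer(x, da1)); add("b_h1", da1)
      dx <- drop(params$W_h1 %*% da1)
      dpa <- dx[seq_len(d)]; dpf <- dx[d + seq_len(d)]
      dHa <- .pt_pool_backward(fwdA$Ha, config$pooling, params, pa, dpa, grads, gruA)
      dHf_zero <- matrix(0, tn$n_frag, d)
      .pt_backward_variant(fwdA, tn, params, config, dHa, dHf_zero, grads)
      dHf <- .pt_pool_backward(fwdF$Hf, config$pooling, params, pf, dpf, grads, gruF)
      dHa_zero <- matrix(0, tn$n_atoms, d)
      .pt_backward_variant(fwdF, tn, params, config, dHa_zero, dHf, grads)
    }
    list(loss = loss, yhat = if (task == "binary") .pt_sigmoid(hf$yhat) else hf$yhat)
  }

  batch_size <- 16L
  for (ep in seq_len(epochs)) {
    perm <- sample(train)
    i <- 1L
    while (i <= length(perm)) {
      batch <- perm[i:min(i + batch_size - 1L, length(perm))]
      grads <- .pt_zero_grads(params)
      for (bi in batch) one_pass(entries[[bi]], labels[bi], params, grads)
      for (nm in ls(grads)) {
        assign(nm, get(nm, envir = grads) / length(batch), envir = grads)
      }
      st <- .pt_adam_step(params, grads, adam, lr)
      params <- st$params; adam <- st$state
      i <- i + batch_size
    }
  }
  pred <- vapply(seq_len(n), function(i) one_pass(entries[[i]], labels[i], params)$yhat,
                 numeric(1))
  metric <- if (task == "regression") {
    c(spearman = spearman(pred[hold], labels[hold]))
  } else {
    c(auc = auc(pred[hold], labels[hold]))
  }
  list(metric = metric, predictions = pred, heldout_idx = hold,
       head = params[c("W_h1", "b_h1", "W_h2", "b_h2")], params = params,
       mode = mode)
}
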