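# Heterogeneous message-passing encoder with hand-derived gradients.
#
# Layer update (per layer l, parameters shared across view variants):
#   za = Ha W_sa + Agg_aa(Ha, bond emb) W_aa + Lift_fa(Hf) W_ja + b_a
#   zf = Hf W_sf + Agg_ff(Hf) W_ff + Agg_af(Ha) W_jf + b_f
#   Ha' = Ha + tanh(za),  Hf' = Hf + tanh(zf)
# with edge-type terms switched on per view variant:
#   A  : aa only (atoms)        F  : ff only (fragments)
#   AJ : aa + junction (atoms)  FJ : ff + junction (fragments)
# Training is plain Adam on the masked-attribute cross-entropy.

#' Model configuration
#'
#' @param hidden_dim embedding width (default 128).
#' @param n_layers number of message-passing layers (>= 1).
#' @param fusion `"A_F"`, `"AJ_F"` or `"AJ_FJ"` — which atom-side and
#'   fragment-side variants are pooled and concatenated.
#' @param pooling `"max"`, `"avg"` or `"gru"`.
#' @param dropout kept for interface completeness; not used by the
#'   deterministic encoder.
#' @param seed root seed fanned out to parameter initialization and sampling.
#' @return a `model_config` list.
#' @export
model_config <- function(hidden_dim = 128L, n_layers = 3L,
                         fusion = c("AJ_FJ", "A_F", "AJ_F"),
                         pooling = c("gru", "max", "avg"),
                         dropout = 0, seed = 1L) {
  fusion <- match.arg(fusion)
  pooling <- match.arg(pooling)
  stopifnot(hidden_dim > 0L, n_layers >= 1L)
  structure(list(
    hidden_dim = as.integer(hidden_dim), n_layers = as.integer(n_layers),
    fusion = fusion, pooling = pooling, dropout = dropout,
    seed = as.integer(seed)
  ), class = "model_config")
}

.pt_atom_feature_dims <- c(element = 13L, degree = 6L, charge = 5L,
                           aromatic = 2L, n_h = 5L, chirality = 3L)
.pt_bond_feature_dims <- c(order = 4L, conjugated = 2L, in_ring = 2L)

# one-hot encode categorical feature matrix given per-column cardinalities
.pt_onehot <- function(feat, dims) {
  n <- nrow(feat)
  out <- matrix(0, n, sum(dims))
  off <- 0L
  for (j in seq_along(dims)) {
    out[cbind(seq_len(n), off + feat[, j])] <- 1
    off <- off + dims[j]
  }
  out
}

# numeric tensors for one graph, reused across forward/backward passes
.pt_graph_tensors <- function(graph) {
  list(
    X = .pt_onehot(graph$atom_features, .pt_atom_feature_dims),
    BF = if (nrow(graph$edges_aa) > 0L) {
      .pt_onehot(graph$bond_features, .pt_bond_feature_dims)
    } else matrix(0, 0, sum(.pt_bond_feature_dims)),
    src = graph$edges_aa[, 1], dst = graph$edges_aa[, 2],
    ff_src = graph$edges_ff[, 1], ff_dst = graph$edges_ff[, 2],
    frag_of_atom = graph$frag_of_atom,
    frag_ids = graph$fragment_ids, # 0-based
    n_atoms = graph$n_atoms, n_frag = graph$n_fragments
  )
}

# sum-aggregate rows of H over directed edges (dst collects from src)
.pt_agg <- function(H, src, dst, n_out) {
  Z <- matrix(0, n_out, ncol(H))
  if (length(src) > 0L) {
    S <- rowsum(H[src, , drop = FALSE], group = dst)
    Z[as.integer(rownames(S)), ] <- S
  }
  Z
}

#' Initialize model parameters
#'
#' @param config a `model_config`.
#' @param n_vocab vocabulary size (reserved + learned entries).
#' @return named list of parameter matrices (class `pt_params`).
#' @export
init_model_params <- function(config, n_vocab) {
  d <- config$hidden_dim
  set.seed(config$seed)
  rmat <- function(nr, nc, scale = sqrt(1 / nr)) {
    matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
  }
  p <- list(
    W_in = rmat(sum(.pt_atom_feature_dims), d),
    b_in = numeric(d),
    E_frag = rmat(n_vocab + 1L, d, scale = 0.1), # + MASK row
    W_bf = rmat(sum(.pt_bond_feature_dims), d, scale = 0.1),
    W_elem = rmat(d, .pt_n_element_classes(), scale = 0.01),
    b_elem = numeric(.pt_n_element_classes()),
    W_fragcls = rmat(d, n_vocab, scale = 0.01),
    b_fragcls = numeric(n_vocab)
  )
  for (l in seq_len(config$n_layers)) {
    for (nm in c("W_sa", "W_aa", "W_ja", "W_sf", "W_ff", "W_jf")) {
      p[[paste0(nm, l)]] <- rmat(d, d)
    }
    p[[paste0("b_a", l)]] <- numeric(d)
    p[[paste0("b_f", l)]] <- numeric(d)
  }
  # gated recurrent pooling parameters (used by the gru readout)
  for (nm in c("Wz", "Uz", "Wr", "Ur", "Wn", "Un")) p[[paste0("gru_", nm)]] <- rmat(d, d)
  for (nm in c("bz", "br", "bn")) p[[paste0("gru_", nm)]] <- numeric(d)
  p$n_vocab <- n_vocab
  class(p) <- "pt_params"
  p
}

# forward pass of one view variant; returns node states and a cache for
# backprop. flags: use_aa, use_ff, use_j.
.pt_forward_variant <- function(tn, params, config, use_aa, use_ff, use_j) {
  d <- config$hidden_dim
  Ha <- tn$X %*% params$W_in
  Ha <- sweep(Ha, 2, params$b_in, "+")
  Hf <- params$E_frag[tn$frag_ids + 1L, , drop = FALSE]
  Bemb <- if (use_aa && nrow(tn$BF) > 0L) tn$BF %*% params$W_bf else NULL
  cache <- list(layers = vector("list", config$n_layers))
  for (l in seq_len(config$n_layers)) {
    lay <- list(Ha = Ha, Hf = Hf)
    za <- Ha %*% params[[paste0("W_sa", l)]]
    za <- sweep(za, 2, params[[paste0("b_a", l)]], "+")
    if (use_aa && length(tn$src) > 0L) {
      Msg <- Ha[tn$src, , drop = FALSE] + Bemb
      Na <- .pt_agg(Msg, seq_along(tn$dst), tn$dst, tn$n_atoms)
      lay$Na <- Na
      za <- za + Na %*% params[[paste0("W_aa", l)]]
    }
    if (use_j) {
      Lf <- Hf[tn$frag_of_atom, , drop = FALSE]
      lay$Lf <- Lf
      za <- za + Lf %*% params[[paste0("W_ja", l)]]
    }
    zf <- Hf %*% params[[paste0("W_sf", l)]]
    zf <- sweep(zf, 2, params[[paste0("b_f", l)]], "+")
    if (use_ff && length(tn$ff_src) > 0L) {
      Nf <- .pt_agg(Hf, tn$ff_src, tn$ff_dst, tn$n_frag)
      lay$Nf <- Nf
      zf <- zf + Nf %*% params[[paste0("W_ff", l)]]
    }
    if (use_j) {
      Af <- .pt_agg(Ha, seq_len(tn$n_atoms), tn$frag_of_atom, tn$n_frag)
      lay$Af <- Af
      zf <- zf + Af %*% params[[paste0("W_jf", l)]]
    }
    ta <- tanh(za); tf <- tanh(zf)
    lay$ta <- ta; lay$tf <- tf
    Ha <- Ha + ta
    Hf <- Hf + tf
    cache$layers[[l]] <- lay
  }
  cache$Bemb <- Bemb
  list(Ha = Ha, Hf = Hf, cache = cache,
       use_aa = use_aa, use_ff = use_ff, use_j = use_j)
}

# backward pass matching .pt_forward_variant; accumulates into `grads`
# (environment holding parameter-shaped gradient matrices)
.pt_backward_variant <- function(fwd, tn, params, config, dHa, dHf, grads) {
  add <- function(nm, val) assign(nm, get(nm, envir = grads) + val, envir = grads)
  use_aa <- fwd$use_aa; use_ff <- fwd$use_ff; use_j <- fwd$use_j
  dBemb <- NULL
  for (l in rev(seq_len(config$n_layers))) {
    lay <- fwd$cache$layers[[l]]
    ta <- lay$ta; tf <- lay$tf
    ga <- dHa * (1 - ta * ta)  # d loss / d za
    gf <- dHf * (1 - tf * tf)
    W_sa <- params[[paste0("W_sa", l)]]
    W_sf <- params[[paste0("W_sf", l)]]
    add(paste0("W_sa", l), crossprod(lay$Ha, ga))
    add(paste0("b_a", l), colSums(ga))
    add(paste0("W_sf", l), crossprod(lay$Hf, gf))
    add(paste0("b_f", l), colSums(gf))
    dHa_new <- dHa + ga %*% t(W_sa)   # residual + self term
    dHf_new <- dHf + gf %*% t(W_sf)
    if (use_aa && length(tn$src) > 0L) {
      W_aa <- params[[paste0("W_aa", l)]]
      add(paste0("W_aa", l), crossprod(lay$Na, ga))
      dNa <- ga %*% t(W_aa)
      # Na[dst] collected Msg over edges; route back to src atoms and bonds
      dMsg <- dNa[tn$dst, , drop = FALSE]
      dHa_new <- dHa_new + .pt_agg(dMsg, seq_along(tn$src), tn$src, tn$n_atoms)
      dBemb <- if (is.null(dBemb)) dMsg else dBemb + dMsg
    }
    if (use_j) {
      W_ja <- params[[paste0("W_ja", l)]]
      add(paste0("W_ja", l), crossprod(lay$Lf, ga))
      dLf <- ga %*% t(W_ja)
      dHf_new <- dHf_new + .pt_agg(dLf, seq_len(tn$n_atoms), tn$frag_of_atom, tn$n_frag)
      W_jf <- params[[paste0("W_jf", l)]]
      add(paste0("W_jf", l), crossprod(lay$Af, gf))
      dAf <- gf %*% t(W_jf)
      dHa_new <- dHa_new + dAf[tn$frag_of_atom, , drop = FALSE]
    }
    if (use_ff && length(tn$ff_src) > 0L) {
      W_ff <- params[[paste0("W_ff", l)]]
      add(paste0("W_ff", l), crossprod(lay$Nf, gf))
      dNf <- gf %*% t(W_ff)
      dHf_new <- dHf_new + .pt_agg(dNf[tn$ff_dst, , drop = FALSE],
                                   seq_along(tn$ff_src), tn$ff_src, tn$n_frag)
    }
    dHa <- dHa_new; dHf <- dHf_new
  }
  add("W_in", crossprod(tn$X, dHa))
  add("b_in", colSums(dHa))
  if (!is.null(dBemb) && nrow(tn$BF) > 0L) {
    add("W_bf", crossprod(tn$BF, dBemb))
  }
  # embedding-table rows
  dE <- .pt_agg(dHf, seq_len(tn$n_frag), tn$frag_ids + 1L, params$n_vocab + 1L)
  add("E_frag", dE)
  invisible(NULL)
}

# variant flags for the two sides of a fusion strategy
.pt_fusion_sides <- function(fusion) {
  switch(fusion,
    A_F = list(atom = c(aa = TRUE, ff = FALSE, j = FALSE),
               frag = c(aa = FALSE, ff = TRUE, j = FALSE)),
    AJ_F = list(atom = c(aa = TRUE, ff = FALSE, j = TRUE),
                frag = c(aa = FALSE, ff = TRUE, j = FALSE)),
    AJ_FJ = list(atom = c(aa = TRUE, ff = FALSE, j = TRUE),
                 frag = c(aa = FALSE, ff = TRUE, j = TRUE)),
    stop(sprintf("unknown fusion strategy '%s'", fusion))
  )
}

# softmax cross-entropy over selected rows; returns loss, probabilities and
# gradient w.r.t. the selected rows' logits
.pt_softmax_ce <- function(logits, labels) {
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  p <- ex / rowSums(ex)
  n <- nrow(logits)
  ll <- -log(pmax(p[cbind(seq_len(n), labels)], 1e-12))
  dlogits <- p
  dlogits[cbind(seq_len(n), labels)] <- dlogits[cbind(seq_len(n), labels)] - 1
  list(loss = mean(ll), p = p, dlogits = dlogits / n)
}
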