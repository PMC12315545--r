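# Graph readout. Max and average pooling are permutation invariant; the
# gated recurrent readout consumes nodes in the canonical order (atom index
# order of the parsed canonical SMILES; fragments by minimum atom index), so
# it is order-dependent but reproducible for identical inputs.

#' Pool node vectors into a single graph-level vector
#'
#' @param node_vectors numeric matrix, one node per row (at least one row).
#' @param method `"max"` (elementwise maximum), `"avg"` (elementwise mean) or
#'   `"gru"` (final hidden state of a single-layer gated recurrent pass from
#'   a zero initial state, consuming rows in order).
#' @param params model parameters (required for `"gru"`: the `gru_*`
#'   matrices).
#' @return numeric vector of length `ncol(node_vectors)`.
#' @export
pool <- function(node_vectors, method = c("max", "avg", "gru"), params = NULL) {
  method <- match.arg(method)
  if (!is.matrix(node_vectors) || nrow(node_vectors) < 1L) {
    stop("pooling needs at least one node vector")
  }
  switch(method,
    max = apply(node_vectors, 2, max),
    avg = colMeans(node_vectors),
    gru = {
      if (is.null(params)) stop("gru pooling requires recurrent parameters")
      .pt_gru_forward(node_vectors, params)$h
    }
  )
}

.pt_sigmoid <- function(x) 1 / (1 + exp(-x))

# GRU recurrence over rows of X from zero state; returns final state and the
# per-step cache needed for backpropagation through time
.pt_gru_forward <- function(X, params) {
  d <- ncol(X)
  Tn <- nrow(X)
  h <- numeric(d)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- X[t, ]
    z <- .pt_sigmoid(drop(x %*% params$gru_Wz) + drop(h %*% params$gru_Uz) + params$gru_bz)
    r <- .pt_sigmoid(drop(x %*% params$gru_Wr) + drop(h %*% params$gru_Ur) + params$gru_br)
    nn <- tanh(drop(x %*% params$gru_Wn) + drop((r * h) %*% params$gru_Un) + params$gru_bn)
    h_new <- (1 - z) * nn + z * h
    cache[[t]] <- list(x = x, h_prev = h, z = z, r = r, n = nn)
    h <- h_new
  }
  list(h = h, cache = cache)
}

# backward through the GRU recurrence; dh is the gradient at the final state.
# Accumulates parameter gradients into `grads` and returns dX.
.pt_gru_backward <- function(fwd, params, dh, grads) {
  add <- function(nm, val) assign(nm, get(nm, envir = grads) + val, envir = grads)
  cache <- fwd$cache
  Tn <- length(cache)
  d <- length(dh)
  dX <- matrix(0, Tn, d)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    z <- cc$z; r <- cc$r; nn <- cc$n; h_prev <- cc$h_prev; x <- cc$x
    dz <- dh * (h_prev - nn)
    dn <- dh * (1 - z)
    dh_prev <- dh * z
    da_n <- dn * (1 - nn * nn)               # pre-tanh of candidate
    add("gru_Wn", outer(x, da_n))
    add("gru_Un", outer(r * h_prev, da_n))
    add("gru_bn", da_n)
    dX[t, ] <- dX[t, ] + drop(da_n %*% t(params$gru_Wn))
    drh <- drop(da_n %*% t(params$gru_Un))
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    da_z <- dz * z * (1 - z)
    add("gru_Wz", outer(x, da_z))
    add("gru_Uz", outer(h_prev, da_z))
    add("gru_bz", da_z)
    dX[t, ] <- dX[t, ] + drop(da_z %*% t(params$gru_Wz))
    dh_prev <- dh_prev + drop(da_z %*% t(params$gru_Uz))
    da_r <- dr * r * (1 - r)
    add("gru_Wr", outer(x, da_r))
    add("gru_Ur", outer(h_prev, da_r))
    add("gru_br", da_r)
    dX[t, ] <- dX[t, ] + drop(da_r %*% t(params$gru_Wr))
    dh_prev <- dh_prev + drop(da_r %*% t(params$gru_Ur))
    dh <- dh_prev
  }
  dX
}

# pooling backward: gradient of pooled vector w.r.t. node matrix
.pt_pool_backward <- function(node_vectors, method, params, pooled, dpool, grads,
                              gru_fwd = NULL) {
  n <- nrow(node_vectors)
  switch(method,
    avg = matrix(rep(dpool / n, each = n), n),
    max = {
      dX <- matrix(0, n, ncol(node_vectors))
      arg <- max.col(t(node_vectors), ties.method = "first")
      dX[cbind(arg, seq_along(dpool))] <- dpool
      dX
    },
    gru = .pt_gru_backward(gru_fwd, params, dpool, grads)
  )
}
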