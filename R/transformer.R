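#' Parameters of one transformer block
#'
#' Bundles the multi-head attention projections, the position-wise
#' feed-forward network and three layer-norm parameter pairs (one for the
#' query/key source, one for the value source, one before the MLP). The same
#' structure serves both the self-attention encoder block and the cross-view
#' fusion block, which differ only in where their inputs come from.
#'
#' @param d model width (token embedding size).
#' @param h number of attention heads; must divide `d`.
#' @param d_ff hidden width of the feed-forward network (default `2 * d`).
#' @return object of class `transformer_params`: fields `Wq`, `Wk`, `Wv`,
#'   `Wo` (`d x d`), `ffn` (`W1`, `b1`, `W2`, `b2`) and `ln_q`, `ln_kv`,
#'   `ln_mlp` (each `gamma`, `beta`). Head count is recorded in the
#'   attribute `heads` so the parameter tree stays purely numeric. Weights
#'   come from the active RNG stream.
#' @export
transformer_params <- function(d, h = 4, d_ff = 2L * d) {
  if (!is_count(h) || h < 1) stopf("h must be a positive integer")
  if (d %% h != 0) stopf("head count h = %d must divide d = %d", h, d)
  ln <- function() list(gamma = rep(1, d), beta = rep(0, d))
  structure(
    list(
      Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d), Wo = glorot(d, d),
      ffn = list(W1 = glorot(d, d_ff), b1 = rep(0, d_ff),
                 W2 = glorot(d_ff, d), b2 = rep(0, d)),
      ln_q = ln(), ln_kv = ln(), ln_mlp = ln()
    ),
    heads = as.integer(h),
    class = "transformer_params"
  )
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, rowwise: every output row is a convex
#' combination of the rows of `V`.
#'
#' @param Q query matrix `S_q x d_k`.
#' @param K key matrix `S_k x d_k`.
#' @param V value matrix `S_k x d_v`.
#' @return `S_q x d_v` matrix.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  check_matrix(Q, "Q"); check_matrix(K, "K"); check_matrix(V, "V")
  if (ncol(Q) != ncol(K)) {
    stopf("d_k mismatch: Q has %d columns, K has %d", ncol(Q), ncol(K))
  }
  if (nrow(K) != nrow(V)) {
    stopf("K and V must share row count (%d vs %d)", nrow(K), nrow(V))
  }
  sda_fwd(Q, K, V)$out
}

sda_fwd <- function(Q, K, V) {
  dk <- ncol(K)
  S <- tcrossprod(Q, K) / sqrt(dk)
  E <- exp(S - row_max(S))
  A <- E / rowSums(E)
  list(out = A %*% V, A = A, cache = list(Q = Q, K = K, V = V, A = A, dk = dk))
}

sda_bwd <- function(dout, cache) {
  A <- cache$A
  dA <- tcrossprod(dout, cache$V)
  dV <- crossprod(A, dout)
  dS <- softmax_rows_bwd(dA, A) / sqrt(cache$dk)
  list(dQ = dS %*% cache$K, dK = crossprod(dS, cache$Q), dV = dV)
}

#' Multi-head attention
#'
#' Projects the query source and the key/value source through per-head
#' linear maps, applies [scaled_dot_attention()] per head, concatenates the
#' heads and applies the output projection. Self-attention is the special
#' case `query_src == kv_src`; the cross-view fusion block instead draws
#' queries and keys from one token matrix and values from another (see
#' [mvutb_block()]).
#'
#' @param query_src `S_q x d` token matrix supplying queries.
#' @param kv_src `S_k x d` token matrix supplying keys and values.
#' @param params a [transformer_params()] (only the attention fields are
#'   used).
#' @param heads head count; defaults to the `heads` attribute of `params`.
#' @return `S_q x d` token matrix.
#' @export
multi_head_attention <- function(query_src, kv_src, params,
                                 heads = attr(params, "heads") %||% 1L) {
  mha_fwd(query_src, kv_src, kv_src, params, heads)$out
}

# q/k/v sources may differ; prm needs Wq, Wk, Wv, Wo
mha_fwd <- function(q_src, k_src, v_src, prm, h) {
  d <- ncol(prm$Wq)
  if (ncol(q_src) != d || ncol(k_src) != d || ncol(v_src) != d) {
    stopf("token width mismatch: inputs have %d/%d/%d columns, projections expect %d",
          ncol(q_src), ncol(k_src), ncol(v_src), d)
  }
  if (d %% h != 0) stopf("head count h = %d must divide d = %d", h, d)
  dk <- d %/% h
  Q <- q_src %*% prm$Wq
  K <- k_src %*% prm$Wk
  V <- v_src %*% prm$Wv
  O <- matrix(0, nrow(q_src), d)
  head_caches <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    sda <- sda_fwd(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                   V[, cols, drop = FALSE])
    O[, cols] <- sda$out
    head_caches[[i]] <- sda$cache
  }
  out <- O %*% prm$Wo
  list(out = out,
       cache = list(q_src = q_src, k_src = k_src, v_src = v_src, O = O,
                    prm = prm, h = h, dk = dk, head_caches = head_caches))
}

mha_bwd <- function(dout, cache) {
  prm <- cache$prm
  d <- ncol(prm$Wq)
  dO <- tcrossprod(dout, prm$Wo)
  dWo <- crossprod(cache$O, dout)
  dQ <- matrix(0, nrow(cache$q_src), d)
  dK <- matrix(0, nrow(cache$k_src), d)
  dV <- matrix(0, nrow(cache$v_src), d)
  for (i in seq_len(cache$h)) {
    cols <- ((i - 1L) * cache$dk + 1L):(i * cache$dk)
    g <- sda_bwd(dO[, cols, drop = FALSE], cache$head_caches[[i]])
    dQ[, cols] <- g$dQ
    dK[, cols] <- g$dK
    dV[, cols] <- g$dV
  }
  list(
    d_q_src = tcrossprod(dQ, prm$Wq),
    d_k_src = tcrossprod(dK, prm$Wk),
    d_v_src = tcrossprod(dV, prm$Wv),
    dprm = list(Wq = crossprod(cache$q_src, dQ),
                Wk = crossprod(cache$k_src, dK),
                Wv = crossprod(cache$v_src, dV),
                Wo = dWo)
  )
}

#' Position-wise feed-forward network
#'
#' `ReLU(x W1 + b1) W2 + b2`, applied to every token row. The fusion block's
#' MLP has this same two-layer form, so one implementation serves both.
#'
#' @param x `S x d` token matrix.
#' @param params list with `W1`, `b1`, `W2`, `b2` (or a
#'   [transformer_params()], whose `ffn` field is used).
#' @return `S x d` token matrix.
#' @export
ffn <- function(x, params) {
  if (!is.null(params$ffn)) params <- params$ffn
  ffn_fwd(x, params)$out
}

ffn_fwd <- function(x, prm) {
  if (ncol(x) != nrow(prm$W1)) {
    stopf("token width %d does not match W1 input dimension %d",
          ncol(x), nrow(prm$W1))
  }
  Hpre <- add_rows(x %*% prm$W1, prm$b1)
  Hr <- relu(Hpre)
  out <- add_rows(Hr %*% prm$W2, prm$b2)
  list(out = out, cache = list(x = x, Hpre = Hpre, Hr = Hr, prm = prm))
}

ffn_bwd <- function(dout, cache) {
  prm <- cache$prm
  dHr <- tcrossprod(dout, prm$W2)
  dHpre <- dHr * (cache$Hpre > 0)
  list(
    dx = tcrossprod(dHpre, prm$W1),
    dprm = list(W1 = crossprod(cache$x, dHpre), b1 = colSums(dHpre),
                W2 = crossprod(cache$Hr, dout), b2 = colSums(dout))
  )
}

#' Layer normalization
#'
#' Normalizes each token row to zero mean and unit (population) variance,
#' then rescales: `(x - mu) / sqrt(sigma^2 + eps) * gamma + beta`.
#'
#' @param x `S x d` token matrix.
#' @param ln_params list with numeric vectors `gamma`, `beta` (length `d`)
#'   and optionally `eps` (default `1e-5`).
#' @return `S x d` matrix.
#' @export
layer_norm <- function(x, ln_params) {
  check_matrix(x, "x")
  ln_fwd(x, ln_params, ln_params$eps %||% 1e-5)$out
}

ln_fwd <- function(x, prm, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- add_rows(mul_rows(xhat, prm$gamma), prm$beta)
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = prm$gamma))
}

ln_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- mul_rows(dout, cache$gamma)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx,
       dprm = list(gamma = colSums(dout * xhat), beta = colSums(dout)))
}

# inverted dropout; identity when rate <= 0 or not training
drop_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  keep <- 1 - rate
  mask <- matrix(stats::rbinom(length(x), 1L, keep) / keep, nrow(x), ncol(x))
  list(out = x * mask, mask = mask)
}

drop_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}
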