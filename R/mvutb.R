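#' Cross-view united transformer block
#'
#' The fusion block that merges two token matrices: both inputs are layer
#' normalized, multi-head attention draws its queries and keys from the
#' first input and its values from the second, the attention output is added
#' back onto the first input (residual), and a layer-normalized two-layer
#' MLP with a second residual produces the result. Because queries and keys
#' both come from the first input, the two inputs must share their token
#' count; the output has the token count of `x1`.
#'
#' With `x2 == x1` this is exactly a pre-norm transformer encoder block, see
#' [transformer_encoder_block()].
#'
#' @param x1 `S x d` token matrix supplying queries, keys and both residual
#'   paths.
#' @param x2 `S x d` token matrix supplying values.
#' @param params a [transformer_params()].
#' @param heads head count; defaults to the `heads` attribute of `params`.
#' @return `S x d` token matrix.
#' @export
mvutb_block <- function(x1, x2, params,
                        heads = attr(params, "heads") %||% 1L) {
  mvutb_fwd(x1, x2, params, heads)$out
}

#' Transformer encoder block
#'
#' Pre-norm residual self-attention block:
#' `R1 = x + MHA(LN(x), LN(x)); out = R1 + FFN(LN(R1))`. Implemented as the
#' cross-view block [mvutb_block()] applied to `(x, x)`, which makes the two
#' constructions coincide exactly under shared parameters. Tokens carry no
#' positional encoding (brain regions are unordered), so the block is
#' permutation-equivariant over tokens.
#'
#' @param x `S x d` token matrix.
#' @inheritParams mvutb_block
#' @return `S x d` token matrix.
#' @export
transformer_encoder_block <- function(x, params,
                                      heads = attr(params, "heads") %||% 1L) {
  mvutb_fwd(x, x, params, heads)$out
}

mvutb_fwd <- function(x1, x2, prm, h, dropout = 0, train = FALSE) {
  check_matrix(x1, "x1"); check_matrix(x2, "x2")
  if (ncol(x1) != ncol(x2)) {
    stopf("token width mismatch: x1 has %d columns, x2 has %d",
          ncol(x1), ncol(x2))
  }
  if (nrow(x1) != nrow(x2)) {
    stopf("token count mismatch: queries/keys come from x1 (%d tokens) so x2 must match (%d tokens)",
          nrow(x1), nrow(x2))
  }
  n1 <- ln_fwd(x1, prm$ln_q)
  n2 <- ln_fwd(x2, prm$ln_kv)
  att <- mha_fwd(n1$out, n1$out, n2$out, prm, h)
  d1 <- drop_fwd(att$out, dropout, train)
  R1 <- x1 + d1$out
  n3 <- ln_fwd(R1, prm$ln_mlp)
  f <- ffn_fwd(n3$out, prm$ffn)
  d2 <- drop_fwd(f$out, dropout, train)
  out <- R1 + d2$out
  list(out = out,
       cache = list(n1 = n1$cache, n2 = n2$cache, att = att$cache,
                    n3 = n3$cache, f = f$cache,
                    m1 = d1$mask, m2 = d2$mask))
}

mvutb_bwd <- function(dout, cache) {
  fb <- ffn_bwd(drop_bwd(dout, cache$m2), cache$f)
  n3b <- ln_bwd(fb$dx, cache$n3)
  dR1 <- dout + n3b$dx
  mb <- mha_bwd(drop_bwd(dR1, cache$m1), cache$att)
  n1b <- ln_bwd(mb$d_q_src + mb$d_k_src, cache$n1)
  n2b <- ln_bwd(mb$d_v_src, cache$n2)
  list(
    dx1 = dR1 + n1b$dx,
    dx2 = n2b$dx,
    dprm = list(Wq = mb$dprm$Wq, Wk = mb$dprm$Wk, Wv = mb$dprm$Wv,
                Wo = mb$dprm$Wo, ffn = fb$dprm,
                ln_q = n1b$dprm, ln_kv = n2b$dprm, ln_mlp = n3b$dprm)
  )
}

#' Fold transformer-encoder outputs of all views through fusion blocks
#'
#' Left fold of [mvutb_block()] over the per-view token matrices of one sign
#' branch: `out[1] = block(T1, T2)`, `out[k] = block(out[k-1], T[k+1])`.
#' With a single view the input is returned unchanged (no fusion possible).
#'
#' @param te_outputs ordered list of `V` token matrices (all `S x d`).
#' @param params_list list of `V - 1` [transformer_params()], one per fold
#'   step (unused when `V = 1`).
#' @param heads head count; defaults per block from each `params`.
#' @return list of `max(V - 1, 1)` token matrices (the fold intermediates;
#'   for `V = 3` exactly the two fusion outputs).
#' @export
stack_views <- function(te_outputs, params_list = NULL, heads = NULL) {
  if (!is.list(te_outputs) || length(te_outputs) == 0L) {
    stopf("te_outputs must be a non-empty list of token matrices")
  }
  V <- length(te_outputs)
  if (V == 1L) return(te_outputs)
  if (length(params_list) != V - 1L) {
    stopf("need %d fusion parameter sets for %d views, got %d",
          V - 1L, V, length(params_list))
  }
  out <- vector("list", V - 1L)
  cur <- te_outputs[[1L]]
  for (k in seq_len(V - 1L)) {
    prm <- params_list[[k]]
    h <- heads %||% attr(prm, "heads") %||% 1L
    cur <- mvutb_fwd(cur, te_outputs[[k + 1L]], prm, h)$out
    out[[k]] <- cur
  }
  out
}

# fold with caches for backprop
stack_fwd <- function(te_outputs, params_list, h, dropout = 0, train = FALSE) {
  V <- length(te_outputs)
  if (V == 1L) return(list(outs = te_outputs, caches = list()))
  outs <- vector("list", V - 1L)
  caches <- vector("list", V - 1L)
  cur <- te_outputs[[1L]]
  for (k in seq_len(V - 1L)) {
    st <- mvutb_fwd(cur, te_outputs[[k + 1L]], params_list[[k]], h,
                    dropout, train)
    cur <- st$out
    outs[[k]] <- cur
    caches[[k]] <- st$cache
  }
  list(outs = outs, caches = caches)
}

# douts: list of gradients w.r.t. each fold output (same length as outs);
# returns gradients w.r.t. the V te_outputs and each block's parameters
stack_bwd <- function(douts, caches, V) {
  if (V == 1L) return(list(d_te = douts, dprm = list()))
  d_te <- vector("list", V)
  dprm <- vector("list", V - 1L)
  dcur <- douts[[V - 1L]]
  for (k in rev(seq_len(V - 1L))) {
    b <- mvutb_bwd(dcur, caches[[k]])
    dprm[[k]] <- b$dprm
    d_te[[k + 1L]] <- b$dx2
    dcur <- b$dx1
    if (k > 1L) dcur <- dcur + douts[[k - 1L]]
  }
  d_te[[1L]] <- dcur
  list(d_te = d_te, dprm = dprm)
}

#' Pool fused token matrices and classify
#'
#' Readout and classifier head of the fusion stage: every retained token
#' matrix is mean-pooled over its tokens to a `d`-vector
#' (permutation-invariant readout), the pooled vectors of the positive
#' branch are concatenated into `FX`, those of the negative branch into
#' `FY`, `FConcat = [FX || FY]`, and three affine maps with ReLU in between
#' produce the 2-class logits. With the default configuration (`d = 96`,
#' two retained matrices per branch) `FX` and `FY` have length 192 and
#' `FConcat` length 384, matching the head `Linear(384,32) -> Linear(32,16)
#' -> Linear(16,2)`.
#'
#' @param pos_stack list of token matrices retained from the positive
#'   branch.
#' @param neg_stack list of token matrices retained from the negative
#'   branch.
#' @param head_params list with `W1`, `b1`, `W2`, `b2`, `W3`, `b3`.
#' @return numeric length-2 logit vector.
#' @export
fuse_and_classify <- function(pos_stack, neg_stack, head_params) {
  fuse_fwd(pos_stack, neg_stack, head_params)$out
}

fuse_fwd <- function(pos_stack, neg_stack, head) {
  pooled_p <- lapply(pos_stack, colMeans)
  pooled_n <- lapply(neg_stack, colMeans)
  FC <- c(unlist(pooled_p, use.names = FALSE), unlist(pooled_n, use.names = FALSE))
  if (length(FC) != nrow(head$W1)) {
    stopf("fusion head misconfigured: concatenated feature length %d but the first linear expects %d inputs",
          length(FC), nrow(head$W1))
  }
  x <- matrix(FC, 1L)
  a1 <- x %*% head$W1 + matrix(head$b1, 1L)
  r1 <- relu(a1)
  a2 <- r1 %*% head$W2 + matrix(head$b2, 1L)
  r2 <- relu(a2)
  z <- drop(r2 %*% head$W3) + head$b3
  list(out = z,
       cache = list(pos_stack = pos_stack, neg_stack = neg_stack, x = x,
                    a1 = a1, r1 = r1, a2 = a2, r2 = r2, head = head))
}

fuse_bwd <- function(dz, cache) {
  head <- cache$head
  dz <- matrix(dz, 1L)
  dW3 <- t(cache$r2) %*% dz
  db3 <- drop(dz)
  dr2 <- dz %*% t(head$W3)
  da2 <- dr2 * (cache$a2 > 0)
  dW2 <- t(cache$r1) %*% da2
  db2 <- drop(da2)
  dr1 <- da2 %*% t(head$W2)
  da1 <- dr1 * (cache$a1 > 0)
  dW1 <- t(cache$x) %*% da1
  db1 <- drop(da1)
  dFC <- drop(da1 %*% t(head$W1))
  # split dFC back into per-token-matrix gradients via the pooling adjoint
  offset <- 0L
  d_pos <- lapply(cache$pos_stack, function(tm) {
    d <- ncol(tm)
    g <- dFC[(offset + 1L):(offset + d)]
    offset <<- offset + d
    matrix(rep(g / nrow(tm), each = nrow(tm)), nrow(tm), d)
  })
  d_neg <- lapply(cache$neg_stack, function(tm) {
    d <- ncol(tm)
    g <- dFC[(offset + 1L):(offset + d)]
    offset <<- offset + d
    matrix(rep(g / nrow(tm), each = nrow(tm)), nrow(tm), d)
  })
  list(d_pos_stack = d_pos, d_neg_stack = d_neg,
       dhead = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3))
}
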