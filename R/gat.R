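#' Parameters of one graph attention layer
#'
#' Holds the shared linear map `W` (features `F -> F'`) and the attention
#' scorer weights `a` (length `2 F'`). Scores are the canonical single-layer
#' feed-forward form `LeakyReLU(a^T [W h_i || W h_j])`; the adjacency defines
#' the attention mask only, retained edge weights do not enter the score.
#'
#' @param f_in input feature width.
#' @param f_out output feature width.
#' @param leaky_slope negative slope of the LeakyReLU scorer (default 0.2).
#' @return object of class `gat_params` with fields `W` (`f_in x f_out`),
#'   `a` (length `2 f_out`) and `leaky_slope`. Weights are drawn from the
#'   active RNG stream (Glorot-uniform), so seed before calling for
#'   reproducibility.
#' @export
gat_params <- function(f_in, f_out, leaky_slope = 0.2) {
  if (f_out < 1) stopf("f_out must be >= 1")
  structure(
    list(W = glorot(f_in, f_out),
         a = stats::runif(2L * f_out, -sqrt(6 / (2 * f_out + 1)),
                          sqrt(6 / (2 * f_out + 1))),
         leaky_slope = leaky_slope),
    class = "gat_params"
  )
}

# neighborhoods may be a logical N x N mask (row i = N_i) or a list of index
# vectors; each node must appear in its own neighborhood.
as_nbr_mask <- function(neighborhoods, n) {
  if (is.matrix(neighborhoods)) {
    mask <- neighborhoods
    if (!is.logical(mask)) mask <- mask != 0
  } else {
    mask <- matrix(FALSE, n, n)
    for (i in seq_len(n)) mask[i, neighborhoods[[i]]] <- TRUE
  }
  if (any(!diag(mask))) diag(mask) <- TRUE  # self always attends (D-style GAT)
  mask
}

gat_check <- function(features, params) {
  check_matrix(features, "features")
  if (anyNA(features) || !all(is.finite(features))) {
    stopf("features contain NaN or non-finite values")
  }
  if (ncol(features) != nrow(params$W)) {
    stopf("feature width %d does not match W input dimension %d",
          ncol(features), nrow(params$W))
  }
}

#' Masked graph-attention coefficients
#'
#' Computes the attention matrix of one GAT layer: transformed features
#' `h'_i = W^T h_i`, raw scores
#' `e_ij = LeakyReLU(a_src . h'_i + a_dst . h'_j)` for `j` in the
#' neighborhood `N_i`, then a softmax over each neighborhood. Entries outside
#' `N_i` are exactly zero and every row restricted to `N_i` sums to 1.
#'
#' @param features `N x F` node-feature matrix.
#' @param params a [gat_params()].
#' @param neighborhoods logical `N x N` mask or list of neighbor index
#'   vectors (self-inclusive).
#' @return `N x N` attention matrix.
#' @export
gat_attention <- function(features, params, neighborhoods) {
  gat_check(features, params)
  mask <- as_nbr_mask(neighborhoods, nrow(features))
  gat_fwd(features, params, mask, params$leaky_slope %||% 0.2)$alpha
}

#' Graph-attention layer forward pass
#'
#' Aggregates transformed neighbor features with the attention weights of
#' [gat_attention()]: `out_i = sum_{j in N_i} alpha_ij W^T h_j`. No output
#' nonlinearity is applied here; callers add one where the architecture
#' requires it.
#'
#' @inheritParams gat_attention
#' @return `N x F'` matrix of aggregated features.
#' @export
gat_forward <- function(features, params, neighborhoods) {
  gat_check(features, params)
  mask <- as_nbr_mask(neighborhoods, nrow(features))
  gat_fwd(features, params, mask, params$leaky_slope %||% 0.2)$out
}

# forward with cache for backprop; prm needs only numeric fields W and a,
# the LeakyReLU slope travels separately so parameter trees stay numeric
gat_fwd <- function(X, prm, mask, slope = 0.2) {
  f_out <- ncol(prm$W)
  H <- X %*% prm$W                       # h'_i rows
  a_src <- prm$a[seq_len(f_out)]
  a_dst <- prm$a[f_out + seq_len(f_out)]
  s1 <- drop(H %*% a_src)                # contribution of the center node
  s2 <- drop(H %*% a_dst)                # contribution of the neighbor
  E <- outer(s1, s2, `+`)
  L <- leaky_relu(E, slope)
  alpha <- masked_softmax(L, mask)
  out <- alpha %*% H
  list(out = out, alpha = alpha,
       cache = list(X = X, H = H, E = E, mask = mask, W = prm$W,
                    slope = slope, a_src = a_src, a_dst = a_dst,
                    alpha = alpha))
}

gat_bwd <- function(dout, cache) {
  H <- cache$H
  alpha <- cache$alpha
  dalpha <- tcrossprod(dout, H)
  dH <- crossprod(alpha, dout)
  dL <- softmax_rows_bwd(dalpha, alpha)
  dE <- dL * leaky_relu_grad(cache$E, cache$slope)
  dE[!cache$mask] <- 0
  ds1 <- rowSums(dE)
  ds2 <- colSums(dE)
  dH <- dH + outer(ds1, cache$a_src) + outer(ds2, cache$a_dst)
  da <- c(drop(crossprod(H, ds1)), drop(crossprod(H, ds2)))
  dX <- tcrossprod(dH, cache$W)
  dW <- crossprod(cache$X, dH)
  list(dX = dX, dprm = list(W = dW, a = da))
}
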