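# Shared fixtures, all generated in code.

# random symmetric unit-diagonal matrix with entries in [-1, 1]
rand_fc <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n, -1, 1), n, n)
  fc <- (a + t(a)) / 2
  diag(fc) <- 1
  fc
}

# small architecture used throughout the unit tests
tiny_cfg <- function(V = 2, N = 6, seed = 7, ...) {
  model_config(V = V, N = N, gat_dim1 = 4, gat_dim2 = 4, te_dim = 6,
               heads = 2, view_head_hidden = 3, fusion_hidden = c(5, 4),
               seed = seed, ...)
}

tiny_view_cfg <- function(V = 2) {
  view_config(V = V, densities = seq(0.3, 0.7, length.out = V))
}

tiny_sample <- function(N = 6, seed = 11, label = 1) {
  connectivity_sample(sprintf("toy-%d", seed), rand_fc(N, seed), label)
}

# small synthetic cohort for training tests
tiny_cohort <- function(n_per_class = 8, N = 12, T = 150, effect = 0.5,
                        seed = 5) {
  simulate_cohort(sim_config(
    N = N, T = T, n_per_class = n_per_class, modules = c(4, 4, 4),
    effect = effect, seed = seed
  ))$samples
}

# independent scalar re-implementation of masked GAT attention (Eqs.-style
# enumeration, no shared code with the package internals)
oracle_gat_alpha <- function(X, W, a, nbrs, slope = 0.2) {
  n <- nrow(X)
  fo <- ncol(W)
  H <- matrix(0, n, fo)
  for (i in seq_len(n)) for (c in seq_len(fo)) H[i, c] <- sum(X[i, ] * W[, c])
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- vapply(nbrs[[i]], function(j) {
      s <- sum(a * c(H[i, ], H[j, ]))
      if (s > 0) s else slope * s
    }, 0)
    w <- exp(e - max(e))
    alpha[i, nbrs[[i]]] <- w / sum(w)
  }
  alpha
}

# independent scalar softmax-attention oracle
oracle_sda <- function(Q, K, V) {
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- vapply(seq_len(nrow(K)), function(j) {
      sum(Q[i, ] * K[j, ]) / sqrt(ncol(K))
    }, 0)
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (c in seq_len(ncol(V))) out[i, c] <- sum(w * V[, c])
  }
  out
}

# independent multi-head attention with separate q/k/v sources
oracle_mha <- function(q_src, k_src, v_src, prm, h) {
  d <- ncol(prm$Wq)
  dk <- d / h
  O <- matrix(0, nrow(q_src), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    O[, cols] <- oracle_sda(q_src %*% prm$Wq[, cols, drop = FALSE],
                            k_src %*% prm$Wk[, cols, drop = FALSE],
                            v_src %*% prm$Wv[, cols, drop = FALSE])
  }
  O %*% prm$Wo
}

# zero every numeric leaf of a parameter tree
zero_tree <- function(p) {
  if (is.list(p)) return(lapply(p, zero_tree))
  p * 0
}

rand_tokens <- function(S, d, seed) {
  set.seed(seed)
  matrix(stats::rnorm(S * d), S, d)
}
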