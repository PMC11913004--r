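#' Model configuration
#'
#' Collects the architectural constants of the signed multi-view GAT /
#' transformer-fusion classifier. Defaults follow the reference
#' configuration: two stacked GAT layers of width 64 per sign channel (so
#' the pooled per-view concatenation has width `2 * 64 = 128`, feeding the
#' per-view head `Linear(128,16) -> Linear(16,2)`), a token projection
#' lifting 64 to the transformer width 96, and a fusion head
#' `Linear(384,32) -> Linear(32,16) -> Linear(16,2)` fed by four pooled
#' 96-vectors (two retained fusion outputs per sign branch).
#'
#' @param V number of views (default 3).
#' @param N number of regions (nodes) per graph.
#' @param feature_mode node-feature mode, must match the [view_config()]
#'   used to build graphs; determines the input feature width `F`.
#' @param gat_dim1,gat_dim2 output widths of GAT-1 and GAT-2.
#' @param te_dim transformer token width.
#' @param heads attention heads (must divide `te_dim`).
#' @param d_ff feed-forward hidden width (default `2 * te_dim`).
#' @param leaky_slope LeakyReLU slope of the GAT attention scorer.
#' @param aux_loss_weight weight `lambda >= 0` of the auxiliary per-view
#'   classification losses (default 0.5); prediction always uses the fusion
#'   head only.
#' @param dropout dropout rate in `[0, 1)` applied inside transformer blocks
#'   during training (default 0).
#' @param view_head_hidden hidden width of the per-view head (default 16).
#' @param fusion_hidden the two hidden widths of the fusion head
#'   (default `c(32, 16)`).
#' @param seed integer seed for weight initialization.
#' @return object of class `model_config` (a list), with derived fields
#'   `F` (input feature width), `view_head_in` (pooled per-view concat
#'   width) and `fusion_in` (FConcat length).
#' @export
model_config <- function(V = 3, N = 32,
                         feature_mode = c("fc_row", "degree", "identity"),
                         gat_dim1 = 64, gat_dim2 = 64, te_dim = 96,
                         heads = 4, d_ff = 2L * te_dim, leaky_slope = 0.2,
                         aux_loss_weight = 0.5, dropout = 0,
                         view_head_hidden = 16, fusion_hidden = c(32, 16),
                         seed = 1) {
  feature_mode <- match.arg(feature_mode)
  if (!is_count(V) || V < 1) stopf("V must be a positive integer")
  if (te_dim %% heads != 0) {
    stopf("heads = %d must divide te_dim = %d", heads, te_dim)
  }
  if (aux_loss_weight < 0) {
    stopf("aux_loss_weight must be >= 0, got %g", aux_loss_weight)
  }
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  F_in <- switch(feature_mode, fc_row = N, degree = 1L, identity = N)
  n_pool <- if (V == 1) 1L else 2L
  structure(
    list(V = as.integer(V), N = as.integer(N), feature_mode = feature_mode,
         F = as.integer(F_in), gat_dim1 = as.integer(gat_dim1),
         gat_dim2 = as.integer(gat_dim2), te_dim = as.integer(te_dim),
         heads = as.integer(heads), d_ff = as.integer(d_ff),
         leaky_slope = leaky_slope, aux_loss_weight = aux_loss_weight,
         dropout = dropout, view_head_hidden = as.integer(view_head_hidden),
         fusion_hidden = as.integer(fusion_hidden),
         view_head_in = 2L * as.integer(gat_dim2),
         fusion_in = 2L * n_pool * as.integer(te_dim),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

linear_params <- function(n_in, n_out) {
  list(W = glorot(n_in, n_out), b = rep(0, n_out))
}

# transformer_params() carries a class and a heads attribute for standalone
# use; inside the model tree parameters must stay plain nested lists so that
# flatten/relist round-trips exactly (relist dispatches on skeleton class)
plain_tf_params <- function(d, h, d_ff) {
  p <- transformer_params(d, h, d_ff)
  attributes(p) <- list(names = names(p))
  p
}

branch_params <- function(cfg) {
  p <- list(gat1 = list(W = glorot(cfg$F, cfg$gat_dim1),
                        a = stats::runif(2L * cfg$gat_dim1, -0.1, 0.1)))
  if (cfg$F != cfg$gat_dim1) {
    p$skip <- list(W = glorot(cfg$F, cfg$gat_dim1))
  }
  p$gat2 <- list(W = glorot(cfg$gat_dim1, cfg$gat_dim2),
                 a = stats::runif(2L * cfg$gat_dim2, -0.1, 0.1))
  p$te_proj <- linear_params(cfg$gat_dim2, cfg$te_dim)
  p$te <- plain_tf_params(cfg$te_dim, cfg$heads, cfg$d_ff)
  p
}

#' Initialize all learnable parameters of the model
#'
#' Glorot-uniform, fully determined by `cfg$seed`. The returned tree groups
#' weights by module: per-view positive/negative branches (GAT-1, optional
#' skip projection, GAT-2, token projection, transformer encoder), per-view
#' classifier heads, the `V - 1` fusion blocks per sign branch, and the
#' final fusion head.
#'
#' @param cfg a [model_config()].
#' @return nested list of numeric matrices/vectors.
#' @export
init_model_params <- function(cfg) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  views <- lapply(seq_len(cfg$V), function(v) {
    list(pos = branch_params(cfg), neg = branch_params(cfg),
         head = list(W1 = glorot(cfg$view_head_in, cfg$view_head_hidden),
                     b1 = rep(0, cfg$view_head_hidden),
                     W2 = glorot(cfg$view_head_hidden, 2L), b2 = rep(0, 2L)))
  })
  n_fold <- max(cfg$V - 1L, 0L)
  fold <- function() lapply(seq_len(n_fold), function(k) {
    plain_tf_params(cfg$te_dim, cfg$heads, cfg$d_ff)
  })
  list(
    views = views,
    fold_pos = fold(),
    fold_neg = fold(),
    fusion = list(
      W1 = glorot(cfg$fusion_in, cfg$fusion_hidden[1]),
      b1 = rep(0, cfg$fusion_hidden[1]),
      W2 = glorot(cfg$fusion_hidden[1], cfg$fusion_hidden[2]),
      b2 = rep(0, cfg$fusion_hidden[2]),
      W3 = glorot(cfg$fusion_hidden[2], 2L), b3 = rep(0, 2L)
    )
  )
}

# ---- per-sign branch: GAT-1 -> ELU -> +skip -> GAT-2 -> proj -> TE ----

branch_fwd <- function(X, mask, prm, cfg, train = FALSE) {
  g1 <- gat_fwd(X, prm$gat1, mask, cfg$leaky_slope)
  A1 <- elu(g1$out)
  skip <- if (!is.null(prm$skip)) X %*% prm$skip$W else X
  R <- A1 + skip
  g2 <- gat_fwd(R, prm$gat2, mask, cfg$leaky_slope)
  tok_in <- add_rows(g2$out %*% prm$te_proj$W, prm$te_proj$b)
  te <- mvutb_fwd(tok_in, tok_in, prm$te, cfg$heads, cfg$dropout, train)
  list(G2 = g2$out, R = R, tokens = te$out,
       cache = list(X = X, g1 = g1$cache, pre1 = g1$out, has_skip = !is.null(prm$skip),
                    g2 = g2$cache, G2 = g2$out, te_proj = prm$te_proj,
                    te = te$cache))
}

branch_bwd <- function(dG2_extra, dtokens, cache) {
  te_b <- mvutb_bwd(dtokens, cache$te)
  dtok_in <- te_b$dx1 + te_b$dx2          # TE feeds the same matrix twice
  dG2 <- dG2_extra + tcrossprod(dtok_in, cache$te_proj$W)
  d_proj <- list(W = crossprod(cache$G2, dtok_in), b = colSums(dtok_in))
  g2b <- gat_bwd(dG2, cache$g2)
  dR <- g2b$dX
  dA1 <- dR
  dpre1 <- dA1 * elu_grad(cache$pre1)
  g1b <- gat_bwd(dpre1, cache$g1)
  g <- list(gat1 = g1b$dprm)
  if (cache$has_skip) g$skip <- list(W = crossprod(cache$X, dR))
  g$gat2 <- g2b$dprm
  g$te_proj <- d_proj
  g$te <- te_b$dprm
  g
}

view_head_fwd <- function(G2p, G2n, head) {
  pooled <- c(colMeans(G2p), colMeans(G2n))
  x <- matrix(pooled, 1L)
  a1 <- x %*% head$W1 + matrix(head$b1, 1L)
  r1 <- relu(a1)
  z <- drop(r1 %*% head$W2) + head$b2
  list(out = z, cache = list(x = x, a1 = a1, r1 = r1, head = head,
                             np = nrow(G2p), nn = nrow(G2n),
                             dp = ncol(G2p), dn = ncol(G2n)))
}

view_head_bwd <- function(dz, cache) {
  head <- cache$head
  dz <- matrix(dz, 1L)
  dW2 <- t(cache$r1) %*% dz
  db2 <- drop(dz)
  dr1 <- dz %*% t(head$W2)
  da1 <- dr1 * (cache$a1 > 0)
  dW1 <- t(cache$x) %*% da1
  db1 <- drop(da1)
  dpooled <- drop(da1 %*% t(head$W1))
  gp <- dpooled[seq_len(cache$dp)]
  gn <- dpooled[cache$dp + seq_len(cache$dn)]
  list(dG2p = matrix(rep(gp / cache$np, each = cache$np), cache$np),
       dG2n = matrix(rep(gn / cache$nn, each = cache$nn), cache$nn),
       dhead = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Forward pass of one view branch
#'
#' Runs the positive and negative graphs of one view through
#' GAT-1 -> ELU -> residual skip -> GAT-2, pools and concatenates both sign
#' channels into the per-view classifier head, and encodes each channel's
#' GAT-2 output as transformer tokens.
#'
#' @param pos,neg the positive- and negative-channel `view_graph` of one
#'   view (from [build_views()]).
#' @param params_v the per-view parameter group
#'   (`init_model_params(cfg)$views[[v]]`).
#' @param cfg a [model_config()].
#' @return list with `view_logits` (length 2), `pos_tokens` and
#'   `neg_tokens` (`N x te_dim` token matrices).
#' @export
view_branch_forward <- function(pos, neg, params_v, cfg) {
  if (!identical(dim(pos$adjacency), dim(neg$adjacency))) {
    stopf("positive and negative graphs differ in size (%d vs %d nodes)",
          nrow(pos$adjacency), nrow(neg$adjacency))
  }
  bp <- branch_fwd(pos$node_features, pos$mask, params_v$pos, cfg)
  bn <- branch_fwd(neg$node_features, neg$mask, params_v$neg, cfg)
  vh <- view_head_fwd(bp$G2, bn$G2, params_v$head)
  list(view_logits = vh$out, pos_tokens = bp$tokens, neg_tokens = bn$tokens)
}

arrange_views <- function(sample_views, V) {
  key <- vapply(sample_views, function(g) paste0(g$sign, g$view_index), "")
  out <- list(pos = vector("list", V), neg = vector("list", V))
  for (v in seq_len(V)) {
    for (s in c("+", "-")) {
      idx <- match(paste0(s, v), key)
      if (is.na(idx)) stopf("missing view graph (view %d, sign '%s')", v, s)
      if (s == "+") out$pos[[v]] <- sample_views[[idx]]
      else out$neg[[v]] <- sample_views[[idx]]
    }
  }
  out
}

select_retained <- function(outs, V) {
  if (V == 1L) outs
  else if (V == 2L) list(outs[[1L]], outs[[1L]])
  else outs[(length(outs) - 1L):length(outs)]
}

model_fwd <- function(sample_views, params, cfg, train = FALSE) {
  vs <- arrange_views(sample_views, cfg$V)
  branches_p <- vector("list", cfg$V)
  branches_n <- vector("list", cfg$V)
  view_heads <- vector("list", cfg$V)
  per_view_logits <- vector("list", cfg$V)
  for (v in seq_len(cfg$V)) {
    pv <- params$views[[v]]
    branches_p[[v]] <- branch_fwd(vs$pos[[v]]$node_features, vs$pos[[v]]$mask,
                                  pv$pos, cfg, train)
    branches_n[[v]] <- branch_fwd(vs$neg[[v]]$node_features, vs$neg[[v]]$mask,
                                  pv$neg, cfg, train)
    view_heads[[v]] <- view_head_fwd(branches_p[[v]]$G2, branches_n[[v]]$G2,
                                     pv$head)
    per_view_logits[[v]] <- view_heads[[v]]$out
  }
  tok_p <- lapply(branches_p, `[[`, "tokens")
  tok_n <- lapply(branches_n, `[[`, "tokens")
  st_p <- stack_fwd(tok_p, params$fold_pos, cfg$heads, cfg$dropout, train)
  st_n <- stack_fwd(tok_n, params$fold_neg, cfg$heads, cfg$dropout, train)
  fu <- fuse_fwd(select_retained(st_p$outs, cfg$V),
                 select_retained(st_n$outs, cfg$V), params$fusion)
  output <- structure(
    list(fusion_logits = fu$out, per_view_logits = per_view_logits,
         predicted_label = unname(which.max(fu$out)) - 1L),
    class = "model_output"
  )
  list(output = output,
       cache = list(branches_p = branches_p, branches_n = branches_n,
                    view_heads = view_heads, st_p = st_p, st_n = st_n,
                    fu = fu$cache))
}

#' Full model forward pass for one subject
#'
#' Runs every view branch, folds the per-view transformer tokens of each
#' sign channel through the cross-view fusion blocks, and classifies the
#' pooled fusion features. Deterministic given fixed parameters and inputs.
#'
#' @param sample_views list of `2 * V` `view_graph` objects from
#'   [build_views()] (any order; matched by view index and sign).
#' @param params parameter tree from [init_model_params()].
#' @param cfg a [model_config()].
#' @return object of class `model_output`: `fusion_logits` (length 2),
#'   `per_view_logits` (list of `V` length-2 vectors) and `predicted_label`
#'   (0/1, the argmax of the fusion logits).
#' @export
model_forward <- function(sample_views, params, cfg) {
  model_fwd(sample_views, params, cfg, train = FALSE)$output
}

#' Joint classification loss
#'
#' Cross-entropy of the fusion logits against the label plus
#' `lambda` times the summed cross-entropies of the per-view auxiliary
#' heads. Prediction uses the fusion head only; the auxiliary terms
#' regularize each view branch toward class-discriminative features.
#'
#' @param output a `model_output` from [model_forward()].
#' @param label 0/1 diagnostic label.
#' @param lambda auxiliary loss weight, `>= 0`.
#' @return nonnegative scalar.
#' @export
total_loss <- function(output, label, lambda = 0.5) {
  if (lambda < 0) stopf("lambda must be >= 0, got %g", lambda)
  check_finite(output$fusion_logits, "fusion logits")
  loss <- cross_entropy(output$fusion_logits, label)$loss
  for (z in output$per_view_logits) {
    loss <- loss + lambda * cross_entropy(z, label)$loss
  }
  loss
}

# loss + full analytic gradient for one subject
loss_and_grads <- function(sample_views, label, params, cfg, train = FALSE) {
  fw <- model_fwd(sample_views, params, cfg, train)
  out <- fw$output
  cache <- fw$cache
  lambda <- cfg$aux_loss_weight
  ce_f <- cross_entropy(out$fusion_logits, label)
  loss <- ce_f$loss
  fb <- fuse_bwd(ce_f$grad, cache$fu)
  # scatter retained-output grads back onto the fold outputs
  expand_sel <- function(dsel, outs, V) {
    douts <- lapply(outs, function(o) o * 0)
    if (V == 1L) {
      douts[[1L]] <- dsel[[1L]]
    } else if (V == 2L) {
      douts[[1L]] <- dsel[[1L]] + dsel[[2L]]
    } else {
      n <- length(outs)
      douts[[n - 1L]] <- douts[[n - 1L]] + dsel[[1L]]
      douts[[n]] <- douts[[n]] + dsel[[2L]]
    }
    douts
  }
  if (cfg$V == 1L) {
    d_te_p <- list(fb$d_pos_stack[[1L]])
    d_te_n <- list(fb$d_neg_stack[[1L]])
    dfold_p <- list()
    dfold_n <- list()
  } else {
    sb_p <- stack_bwd(expand_sel(fb$d_pos_stack, cache$st_p$outs, cfg$V),
                      cache$st_p$caches, cfg$V)
    sb_n <- stack_bwd(expand_sel(fb$d_neg_stack, cache$st_n$outs, cfg$V),
                      cache$st_n$caches, cfg$V)
    d_te_p <- sb_p$d_te
    d_te_n <- sb_n$d_te
    dfold_p <- sb_p$dprm
    dfold_n <- sb_n$dprm
  }
  dviews <- vector("list", cfg$V)
  for (v in seq_len(cfg$V)) {
    ce_v <- cross_entropy(out$per_view_logits[[v]], label)
    loss <- loss + lambda * ce_v$loss
    vh <- view_head_bwd(lambda * ce_v$grad, cache$view_heads[[v]]$cache)
    dviews[[v]] <- list(
      pos = branch_bwd(vh$dG2p, d_te_p[[v]], cache$branches_p[[v]]$cache),
      neg = branch_bwd(vh$dG2n, d_te_n[[v]], cache$branches_n[[v]]$cache),
      head = vh$dhead
    )
  }
  grads <- list(views = dviews, fold_pos = dfold_p, fold_neg = dfold_n,
                fusion = fb$dhead)
  list(loss = loss, grads = grads, output = out)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the full parameter tree, the model
#' configuration and the view configuration; loading and re-evaluating
#' reproduces outputs bitwise.
#'
#' @param model list with fields `params`, `config`, `view_config` (as
#'   produced by [train_mvgat()]).
#' @param path file path.
#' @return `load_checkpoint` returns the model list; `save_checkpoint`
#'   returns `path` invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(is.list(model), !is.null(model$params), !is.null(model$config))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  readRDS(path)
}
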