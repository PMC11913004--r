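test_that("zero GAT-1 weights leave the residual skip path only", {
  cfg <- tiny_cfg()
  params <- init_model_params(cfg)
  prm <- params$views[[1]]$pos
  prm$gat1$W[] <- 0
  prm$gat1$a[] <- 0
  s <- tiny_sample()
  vg <- build_views(s, tiny_view_cfg())
  b <- mvgat:::branch_fwd(vg[[1]]$node_features, vg[[1]]$mask, prm, cfg)
  expect_equal(b$R, vg[[1]]$node_features %*% prm$skip$W)
})

test_that("default configuration carries the documented head widths", {
  cfg <- model_config()
  expect_equal(cfg$view_head_in, 128)
  expect_equal(cfg$fusion_in, 384)
  params <- init_model_params(cfg)
  expect_equal(dim(params$views[[1]]$head$W1), c(128L, 16L))
  expect_equal(dim(params$views[[1]]$head$W2), c(16L, 2L))
  expect_equal(dim(params$fusion$W1), c(384L, 32L))
  expect_equal(dim(params$fusion$W2), c(32L, 16L))
  expect_equal(dim(params$fusion$W3), c(16L, 2L))
})

test_that("view branch emits 2-logit outputs and token matrices of the encoder width", {
  cfg <- tiny_cfg()
  params <- init_model_params(cfg)
  s <- tiny_sample()
  vg <- build_views(s, tiny_view_cfg())
  vb <- view_branch_forward(vg[[1]], vg[[3]], params$views[[1]], cfg)
  expect_length(vb$view_logits, 2)
  expect_equal(dim(vb$pos_tokens), c(6L, cfg$te_dim))
  expect_equal(dim(vb$neg_tokens), c(6L, cfg$te_dim))
})

test_that("model_forward produces per-view and fusion outputs and is deterministic", {
  cfg <- tiny_cfg(V = 3)
  params <- init_model_params(cfg)
  s <- tiny_sample()
  vg <- build_views(s, tiny_view_cfg(3))
  out1 <- model_forward(vg, params, cfg)
  out2 <- model_forward(vg, params, cfg)
  expect_length(out1$per_view_logits, 3)
  expect_length(out1$fusion_logits, 2)
  expect_true(out1$predicted_label %in% c(0L, 1L))
  expect_equal(out1$predicted_label, which.max(out1$fusion_logits) - 1L)
  expect_identical(out1, out2)
})

test_that("a missing view/sign pair is reported by name", {
  cfg <- tiny_cfg(V = 2)
  params <- init_model_params(cfg)
  vg <- build_views(tiny_sample(), tiny_view_cfg())
  drop_neg2 <- vg[vapply(vg, function(g) !(g$view_index == 2 && g$sign == "-"), TRUE)]
  expect_error(model_forward(drop_neg2, params, cfg), "view 2, sign '-'")
})

test_that("fusion logits are invariant to node relabeling with covariant features", {
  # degree features transform covariantly under relabeling; fc-row features
  # are themselves indexed by node labels, so only the former admit exact
  # end-to-end invariance
  cfg <- tiny_cfg(V = 2, N = 8, feature_mode = "degree")
  params <- init_model_params(cfg)
  vc <- view_config(2, c(0.3, 0.7), feature_mode = "degree")
  fc <- rand_fc(8, 91)
  s <- connectivity_sample("s", fc, 1)
  set.seed(2)
  p <- sample(8)
  s_perm <- connectivity_sample("sp", fc[p, p], 1)
  out <- model_forward(build_views(s, vc), params, cfg)
  out_p <- model_forward(build_views(s_perm, vc), params, cfg)
  expect_equal(out_p$fusion_logits, out$fusion_logits, tolerance = 1e-5)
})

test_that("swapping the positive and negative channels changes the fusion logits", {
  cfg <- tiny_cfg(V = 2)
  params <- init_model_params(cfg)
  vg <- build_views(tiny_sample(), tiny_view_cfg())
  vg_swapped <- lapply(vg, function(g) {
    g$sign <- if (g$sign == "+") "-" else "+"
    g
  })
  out <- model_forward(vg, params, cfg)
  out_sw <- model_forward(vg_swapped, params, cfg)
  expect_gt(max(abs(out$fusion_logits - out_sw$fusion_logits)), 1e-8)
})

test_that("total_loss has its closed-form values", {
  out <- structure(list(fusion_logits = c(0, 0), per_view_logits = list(c(1, 2)),
                        predicted_label = 0L), class = "model_output")
  expect_equal(total_loss(out, 1, lambda = 0), log(2))

  out2 <- out
  out2$fusion_logits <- c(20, -20)
  expect_lt(total_loss(out2, 0, lambda = 0), 1e-8)

  # lambda = 0 drops the per-view terms; lambda adds them linearly
  ce_v <- -log(exp(2) / (exp(1) + exp(2)))
  expect_equal(total_loss(out, 1, lambda = 0.5), log(2) + 0.5 * ce_v)
  expect_error(total_loss(out, 1, lambda = -1), ">= 0")
})

test_that("analytic gradients match central finite differences on a 5-node toy", {
  cfg <- model_config(V = 2, N = 5, gat_dim1 = 3, gat_dim2 = 3, te_dim = 4,
                      heads = 2, d_ff = 6, view_head_hidden = 3,
                      fusion_hidden = c(4, 3), seed = 3)
  vc <- view_config(V = 2, densities = c(0.4, 0.8))
  fc <- rand_fc(5, 17)
  views <- build_views(connectivity_sample("toy", fc, 1), vc)
  params <- init_model_params(cfg)
  lg <- mvgat:::loss_and_grads(views, 1, params, cfg)
  theta <- mvgat:::flatten_params(params)
  g_an <- mvgat:::flatten_params(lg$grads)
  expect_length(g_an, length(theta))
  f <- function(th) {
    total_loss(model_forward(views, mvgat:::unflatten_params(th, params), cfg),
               1, cfg$aux_loss_weight)
  }
  expect_equal(f(theta), lg$loss, tolerance = 1e-12)
  h <- 1e-5
  g_num <- vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, 0)
  rel_err <- max(abs(g_an - g_num) / pmax(1e-4, abs(g_num)))
  expect_lt(rel_err, 1e-4)
})

test_that("outputs stay finite for degenerate inputs", {
  cfg <- tiny_cfg(V = 1, N = 5)
  params <- init_model_params(cfg)
  vc <- view_config(1, 0.5)
  # all-positive constant graph (negative channel empty) and near-zero graph
  fc1 <- matrix(0.5, 5, 5); diag(fc1) <- 1
  fc2 <- diag(5) + 1e-6; fc2[1, 2] <- fc2[2, 1] <- 1e-6; diag(fc2) <- 1
  for (fc in list(fc1, fc2)) {
    vg <- suppressWarnings(build_views(connectivity_sample("d", fc, 0), vc))
    out <- model_forward(vg, params, cfg)
    expect_true(all(is.finite(out$fusion_logits)))
  }
})

test_that("checkpoints round-trip model outputs bitwise", {
  cfg <- tiny_cfg(V = 2)
  vc <- tiny_view_cfg()
  model <- list(params = init_model_params(cfg), config = cfg, view_config = vc)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  loaded <- load_checkpoint(path)
  vg <- build_views(tiny_sample(), vc)
  expect_identical(model_forward(vg, loaded$params, loaded$config),
                   model_forward(vg, model$params, model$config))
})
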