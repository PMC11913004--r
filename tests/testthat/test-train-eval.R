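test_that("metrics report reproduces the definition arithmetic", {
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.55, 0.3, 0.2, 0.1, 0.05)
  m <- metrics_report(scores, labels)
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$tn, 4); expect_equal(m$fp, 2)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 4 / 6)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$n, 10)
})

test_that("AUC follows the Mann-Whitney rank convention", {
  expect_equal(metrics_report(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # 4 case-control pairs, 3 concordant
  expect_equal(metrics_report(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  # full ties -> 0.5 by the half-credit rule
  expect_equal(metrics_report(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # single-class evaluation: AUC undefined, counts still present
  m <- metrics_report(c(0.9, 0.2), c(1, 1))
  expect_true(is.na(m$auc))
  expect_equal(m$tp + m$fn, 2)
})

test_that("zero learning rate leaves the parameters untouched", {
  samples <- tiny_cohort(n_per_class = 3)
  cfg <- tiny_cfg(V = 2, N = 12, seed = 2)
  vc <- tiny_view_cfg()
  m <- train_mvgat(samples, config = cfg, views = vc, epochs = 1, lr = 0,
                   weight_decay = 0, batch_size = 4)
  expect_identical(mvgat:::flatten_params(m$params),
                   mvgat:::flatten_params(init_model_params(cfg)))
})

test_that("training on a separable cohort reduces the loss", {
  samples <- tiny_cohort(n_per_class = 6, effect = 0.5)
  cfg <- tiny_cfg(V = 2, N = 12, seed = 3)
  m <- train_mvgat(samples, config = cfg, views = tiny_view_cfg(),
                   epochs = 8, batch_size = 4)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
})

test_that("training is reproducible and checkpoints evaluate bitwise-identically", {
  samples <- tiny_cohort(n_per_class = 4)
  cfg <- tiny_cfg(V = 2, N = 12, seed = 5)
  vc <- tiny_view_cfg()
  m1 <- train_mvgat(samples, config = cfg, views = vc, epochs = 2, batch_size = 4)
  m2 <- train_mvgat(samples, config = cfg, views = vc, epochs = 2, batch_size = 4)
  expect_identical(m1$params, m2$params)

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m1, path)
  direct <- evaluate_mvgat(m1, samples)
  roundtrip <- evaluate_mvgat(path, samples)
  expect_identical(unclass(direct), unclass(roundtrip))
})

test_that("evaluation is invariant to subject order", {
  samples <- tiny_cohort(n_per_class = 4)
  cfg <- tiny_cfg(V = 2, N = 12, seed = 6)
  m <- train_mvgat(samples, config = cfg, views = tiny_view_cfg(),
                   epochs = 2, batch_size = 4)
  expect_identical(unclass(evaluate_mvgat(m, samples)),
                   unclass(evaluate_mvgat(m, rev(samples))))
})

test_that("stratified folds partition subjects with balanced classes", {
  labels <- c(rep(0, 60), rep(1, 40))
  fold <- mvgat:::stratified_folds(labels, 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.vector(table(fold)), rep(20, 5))
  for (f in 1:5) {
    expect_equal(sum(labels[fold == f] == 1), 8)  # global ratio preserved
  }
  expect_identical(fold, mvgat:::stratified_folds(labels, 5, seed = 3))
  expect_error(mvgat:::stratified_folds(c(0, 0, 0, 1), 3, 1),
               "stratification impossible.*3.*1")
})

test_that("cross-validation trains per fold and summarizes the metric suite", {
  samples <- tiny_cohort(n_per_class = 6, effect = 0.5)
  cfg <- tiny_cfg(V = 2, N = 12, seed = 8)
  cv <- cross_validate_mvgat(samples, config = cfg, views = tiny_view_cfg(),
                             k = 3, seed = 8, epochs = 2, batch_size = 4)
  expect_length(cv$folds, 3)
  expect_equal(sort(unique(cv$assignments)), 1:3)
  expect_equal(sum(vapply(cv$folds, `[[`, 0L, "n")), 12)
  expect_setequal(cv$summary$metric,
                  c("accuracy", "sensitivity", "specificity", "auc"))
  expect_true(all(cv$summary$mean >= 0 & cv$summary$mean <= 1, na.rm = TRUE))
})

test_that("the command-line surface wires simulate/train/evaluate/predict together", {
  dir <- withr::local_tempdir()
  cfg_yaml <- file.path(dir, "run.yaml")
  writeLines(c(
    "seed: 3",
    "model:",
    "  V: 2", "  N: 9", "  gat_dim1: 4", "  gat_dim2: 4", "  te_dim: 6",
    "  heads: 2", "  view_head_hidden: 3",
    "  fusion_hidden: [5, 4]",
    "views:",
    "  densities: [0.3, 0.7]",
    "sim:",
    "  N: 9", "  T: 60", "  n_per_class: 4", "  modules: [3, 3, 3]",
    "  effect: 0.5",
    "optimizer:",
    "  epochs: 2", "  batch_size: 4"
  ), cfg_yaml)
  coh_dir <- file.path(dir, "cohort")
  run_cli(c("simulate", "--config", cfg_yaml, "--out", coh_dir))
  expect_true(file.exists(file.path(coh_dir, "manifest.tsv")))
  expect_length(list.files(coh_dir, pattern = "\\.tsv$"), 9)  # 8 + manifest

  fit_dir <- file.path(dir, "fit")
  run_cli(c("train", "--manifest", file.path(coh_dir, "manifest.tsv"),
            "--config", cfg_yaml, "--out", fit_dir))
  ckpt <- file.path(fit_dir, "model.rds")
  expect_true(file.exists(ckpt))
  expect_true(file.exists(file.path(fit_dir, "history.jsonl")))

  json_out <- file.path(dir, "metrics.json")
  out <- capture.output(
    run_cli(c("evaluate", "--checkpoint", ckpt,
              "--manifest", file.path(coh_dir, "manifest.tsv"),
              "--json", json_out))
  )
  expect_true(any(grepl("accuracy", out)))
  metrics <- jsonlite::read_json(json_out)
  expect_true(all(c("tp", "fp", "tn", "fn", "accuracy", "auc") %in% names(metrics)))

  mat <- read_manifest(file.path(coh_dir, "manifest.tsv"))$path[1]
  pred_out <- capture.output(
    run_cli(c("predict", "--checkpoint", ckpt, "--matrix", mat))
  )
  expect_true(any(grepl("predicted label: [01]", pred_out)))
})
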