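#' @noRd
#' Normalize the accepted data forms (manifest path, manifest data.frame,
#' list of connectivity_sample) to a list of samples.
as_samples <- function(data) {
  if (is.character(data) && length(data) == 1L) {
    return(load_manifest_samples(read_manifest(data)))
  }
  if (is.data.frame(data)) return(load_manifest_samples(data))
  if (is.list(data) && all(vapply(data, inherits, TRUE, "connectivity_sample"))) {
    return(data)
  }
  stopf("data must be a manifest path, a manifest data.frame, or a list of connectivity_sample objects")
}

precompute_views <- function(samples, view_cfg, coarsen = NULL) {
  lapply(samples, build_views, cfg = view_cfg, coarsen = coarsen)
}

check_compat <- function(cfg, view_cfg, samples) {
  if (cfg$V != view_cfg$V) {
    stopf("model config V = %d but view config V = %d", cfg$V, view_cfg$V)
  }
  if (cfg$feature_mode != view_cfg$feature_mode) {
    stopf("model feature_mode '%s' but view feature_mode '%s'",
          cfg$feature_mode, view_cfg$feature_mode)
  }
  n <- nrow(samples[[1]]$fc)
  if (cfg$N != n) {
    stopf("model config N = %d but matrices have %d regions", cfg$N, n)
  }
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Train the multi-view classifier
#'
#' Minimizes the joint loss (fusion cross-entropy plus weighted per-view
#' auxiliary cross-entropies) by mini-batch Adam with L2 weight decay, using
#' the package's analytic gradients. Fully seeded: weight initialization,
#' batch shuffling and any dropout masks derive from `config$seed` and
#' `seed`.
#'
#' @param data training subjects: a manifest path, a manifest data.frame, or
#'   a list of [connectivity_sample()] objects.
#' @param config a [model_config()].
#' @param views a [view_config()]; must agree with `config` on `V` and
#'   `feature_mode`.
#' @param epochs training epochs (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay L2 penalty coefficient (default 5e-4).
#' @param batch_size mini-batch size (default 16).
#' @param seed shuffling seed (default `config$seed`).
#' @param val_data optional held-out subjects evaluated after each epoch.
#' @param verbose print per-epoch loss.
#' @param log_file optional path; per-epoch records are appended as
#'   line-delimited JSON.
#' @return object of class `mvgat_model`: `params`, `config`,
#'   `view_config`, and `history` (data.frame of per-epoch mean training
#'   loss and, if `val_data` was given, validation accuracy/AUC).
#' @export
train_mvgat <- function(data, config = model_config(), views = view_config(config$V),
                        epochs = 100, lr = 1e-3, weight_decay = 5e-4,
                        batch_size = 16, seed = config$seed, val_data = NULL,
                        verbose = FALSE, log_file = NULL) {
  samples <- as_samples(data)
  check_compat(config, views, samples)
  labels <- vapply(samples, `[[`, 0L, "label")
  sv <- precompute_views(samples, views)
  params <- init_model_params(config)
  theta <- flatten_params(params)
  st <- adam_state(length(theta))
  history <- vector("list", epochs)
  val_samples <- if (!is.null(val_data)) as_samples(val_data)
  set.seed(mix_seed(seed, 7919))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(samples))
    ep_loss <- 0
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      batch <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      gsum <- NULL
      bloss <- 0
      for (i in batch) {
        lg <- loss_and_grads(sv[[i]], labels[i], params, config,
                             train = config$dropout > 0)
        bloss <- bloss + lg$loss
        gsum <- add_params(gsum, lg$grads)
      }
      if (!is.finite(bloss)) {
        stopf("non-finite loss in epoch %d for subjects: %s", ep,
              paste(vapply(samples[batch], `[[`, "", "subject_id"),
                    collapse = ", "))
      }
      grad <- flatten_params(gsum) / length(batch) + weight_decay * theta
      up <- adam_step(theta, grad, st, lr)
      theta <- up$theta
      st <- up$state
      params <- unflatten_params(theta, params)
      ep_loss <- ep_loss + bloss
    }
    rec <- list(epoch = ep, loss = ep_loss / length(samples))
    if (!is.null(val_samples)) {
      vm <- evaluate_samples(params, config, views, val_samples)
      rec$val_accuracy <- vm$accuracy
      rec$val_auc <- vm$auc
    }
    history[[ep]] <- rec
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f%s", ep, rec$loss,
                      if (!is.null(rec$val_accuracy))
                        sprintf("  val acc %.3f", rec$val_accuracy) else ""))
    }
    if (!is.null(log_file)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = log_file, append = TRUE, sep = "")
    }
  }
  structure(
    list(params = params, config = config, view_config = views,
         history = do.call(rbind, lapply(history, as.data.frame))),
    class = "mvgat_model"
  )
}

# case-class (label 1) softmax probability for each subject
score_samples <- function(params, config, views, samples) {
  vapply(samples, function(s) {
    out <- model_forward(build_views(s, views), params, config)
    z <- out$fusion_logits
    p <- exp(z - logsumexp(z))
    p[2]
  }, 0)
}

evaluate_samples <- function(params, config, views, samples) {
  scores <- score_samples(params, config, views, samples)
  labels <- vapply(samples, `[[`, 0L, "label")
  metrics_report(scores, labels)
}

#' Evaluate a trained model
#'
#' Scores every subject with the fusion head's softmax probability of class
#' 1, thresholds at 0.5 for the confusion counts, and computes AUC as the
#' Mann-Whitney rank statistic (ties one half). The result is invariant to
#' subject order.
#'
#' @param model an `mvgat_model` from [train_mvgat()] or a checkpoint path.
#' @param data subjects to evaluate (manifest path, manifest data.frame, or
#'   list of samples).
#' @return a [metrics_report()].
#' @export
evaluate_mvgat <- function(model, data) {
  if (is.character(model)) model <- load_checkpoint(model)
  samples <- as_samples(data)
  check_compat(model$config, model$view_config, samples)
  evaluate_samples(model$params, model$config, model$view_config, samples)
}

#' Predict the diagnostic label of one subject
#'
#' @param model an `mvgat_model` or checkpoint path.
#' @param fc a connectivity matrix, matrix file path, or
#'   [connectivity_sample()].
#' @return list with `predicted_label` (0/1), `prob` (class-1 probability)
#'   and `fusion_logits`.
#' @export
predict_mvgat <- function(model, fc) {
  if (is.character(model)) model <- load_checkpoint(model)
  sample <- if (inherits(fc, "connectivity_sample")) {
    fc
  } else {
    if (is.character(fc)) fc <- read_connectivity_matrix(fc)
    connectivity_sample("query", fc, 0L)
  }
  out <- model_forward(build_views(sample, model$view_config),
                       model$params, model$config)
  z <- out$fusion_logits
  list(predicted_label = out$predicted_label,
       prob = exp(z[2] - logsumexp(z)), fusion_logits = z)
}

#' Stratified fold assignment
#' @noRd
stratified_folds <- function(labels, k, seed) {
  if (k < 2) stopf("k must be >= 2 for cross-validation")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (min(counts) < k) {
    stopf("stratification impossible: k = %d folds but class counts are %d (control) and %d (case)",
          k, counts[1], counts[2])
  }
  fold <- integer(length(labels))
  for (cls in c(0, 1)) {
    idx <- which(labels == cls)
    set.seed(mix_seed(seed, 131, cls))
    perm <- idx[sample.int(length(idx))]
    fold[perm] <- rep_len(seq_len(k), length(perm))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits subjects into `k` stratified, disjoint test folds covering every
#' subject exactly once, trains a fresh model on each training split (fold-
#' specific derived seeds) and evaluates on the held-out fold.
#'
#' @inheritParams train_mvgat
#' @param k number of folds (default 5); must not exceed the minority class
#'   count.
#' @param ... further arguments passed to [train_mvgat()] (`epochs`, `lr`,
#'   `batch_size`, ...).
#' @return list with `folds` (list of `k` [metrics_report()]),
#'   `assignments` (fold id per subject) and `summary` (data.frame of mean
#'   and sd per metric across folds).
#' @export
cross_validate_mvgat <- function(data, config = model_config(),
                                 views = view_config(config$V), k = 5,
                                 seed = config$seed, ...) {
  samples <- as_samples(data)
  labels <- vapply(samples, `[[`, 0L, "label")
  fold <- stratified_folds(labels, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    cfg_f <- config
    cfg_f$seed <- mix_seed(seed, 977, f)
    model <- train_mvgat(samples[fold != f], config = cfg_f, views = views,
                         seed = cfg_f$seed, ...)
    reports[[f]] <- evaluate_mvgat(model, samples[fold == f])
  }
  metric_names <- c("accuracy", "sensitivity", "specificity", "auc")
  vals <- sapply(metric_names, function(m) {
    vapply(reports, `[[`, 0, m)
  })
  summary <- data.frame(
    metric = metric_names,
    mean = colMeans(vals, na.rm = TRUE),
    sd = apply(vals, 2L, stats::sd, na.rm = TRUE),
    row.names = NULL
  )
  list(folds = reports, assignments = fold, summary = summary)
}
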