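#' Configuration of the synthetic two-class connectome cohort
#'
#' The simulator emulates resting-state functional connectivity: each
#' subject's matrix is the sample Pearson correlation of `T` multivariate
#' normal "timepoints" drawn from a modular block covariance. Regions fall
#' into modules with within-module correlation `base_corr`; one designated
#' inter-module block carries the class difference (class 1 reduces its
#' correlation by `effect`), and one block is anti-correlated so the
#' negative-edge channel is non-trivial. Per-subject block-level jitter
#' (sd `noise_sd`) adds biological-style heterogeneity.
#'
#' @param N regions (default 32).
#' @param T timepoints per subject (default 200).
#' @param n_per_class subjects per class (default 50).
#' @param modules region counts per module; must sum to `N`.
#' @param base_corr within-module correlation `r0` (default 0.6).
#' @param effect class-1 reduction `delta` of the target block's correlation
#'   (default 0.3).
#' @param noise_sd sd of the per-subject block-level jitter (default 0.02).
#' @param background_corr correlation of unlisted inter-module blocks
#'   (default 0.1).
#' @param target_block pair of module indices whose correlation carries the
#'   class effect (default modules 1-2, baseline `target_corr = 0.45`).
#' @param target_corr baseline correlation of the target block.
#' @param anti_block pair of module indices given correlation `anti_corr`
#'   (default modules 2-3 at -0.2).
#' @param anti_corr correlation of the anti-correlated block.
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @return object of class `sim_config`. Construction fails if either
#'   class's target covariance is not positive semi-definite.
#' @export
sim_config <- function(N = 32, T = 200, n_per_class = 50,
                       modules = c(11, 11, 10), base_corr = 0.6,
                       effect = 0.3, noise_sd = 0.02,
                       background_corr = 0.1,
                       target_block = c(1, 2), target_corr = 0.45,
                       anti_block = c(2, 3), anti_corr = -0.2,
                       seed = 1) {
  if (sum(modules) != N) {
    stopf("module sizes must sum to N = %d, got %d", N, sum(modules))
  }
  if (N < 3) stopf("N must be >= 3")
  if (T < 3) stopf("T must be >= 3")
  cfg <- structure(
    list(N = as.integer(N), T = as.integer(T),
         n_per_class = as.integer(n_per_class),
         modules = as.integer(modules), base_corr = base_corr,
         effect = effect, noise_sd = noise_sd,
         background_corr = background_corr,
         target_block = as.integer(target_block), target_corr = target_corr,
         anti_block = as.integer(anti_block), anti_corr = anti_corr,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  for (cls in 0:1) {
    S <- target_covariance(cls, cfg)
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 1e-10) {
      stopf("class-%d target covariance is not positive semi-definite (min eigenvalue %.3g); adjust block correlations",
            cls, ev)
    }
  }
  cfg
}

# block-value matrix: entry (a, b) = target correlation between modules a, b
block_values <- function(cls, cfg) {
  m <- length(cfg$modules)
  B <- matrix(cfg$background_corr, m, m)
  diag(B) <- cfg$base_corr
  tb <- cfg$target_block
  tc <- if (cls == 1) cfg$target_corr - cfg$effect else cfg$target_corr
  B[tb[1], tb[2]] <- B[tb[2], tb[1]] <- tc
  ab <- cfg$anti_block
  B[ab[1], ab[2]] <- B[ab[2], ab[1]] <- cfg$anti_corr
  B
}

expand_blocks <- function(B, cfg) {
  idx <- rep(seq_along(cfg$modules), cfg$modules)
  S <- B[idx, idx]
  diag(S) <- 1
  S
}

target_covariance <- function(cls, cfg, jitter = NULL) {
  B <- block_values(cls, cfg)
  if (!is.null(jitter)) B <- B + jitter
  expand_blocks(B, cfg)
}

#' Simulate one subject's connectivity matrix
#'
#' Draws `T` multivariate normal samples from the class-specific block
#' covariance (with seeded per-subject block jitter) and returns the sample
#' Pearson correlation matrix, symmetrized with unit diagonal.
#'
#' @param cls class label, 0 or 1.
#' @param cfg a [sim_config()].
#' @param subject_seed integer seed for this subject (see
#'   [simulate_cohort()] for the derivation from the cohort seed).
#' @param subject_id subject identifier (default derived from class/seed).
#' @return a [connectivity_sample()].
#' @export
simulate_subject <- function(cls, cfg, subject_seed,
                             subject_id = sprintf("sim-%d-%d", cls, subject_seed)) {
  if (!cls %in% c(0, 1)) stopf("cls must be 0 or 1")
  set.seed(subject_seed)
  m <- length(cfg$modules)
  S <- NULL
  for (attempt in seq_len(10L)) {
    J <- matrix(0, m, m)
    J[upper.tri(J, diag = TRUE)] <- stats::rnorm(m * (m + 1) / 2, 0, cfg$noise_sd)
    J <- (J + t(J)) - diag(diag(J))      # symmetric block jitter
    cand <- target_covariance(cls, cfg, J)
    ev <- min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 1e-8) { S <- cand; break }
  }
  if (is.null(S)) {
    stopf("subject covariance not positive definite after 10 jitter attempts (seed %d)",
          subject_seed)
  }
  Z <- matrix(stats::rnorm(cfg$T * cfg$N), cfg$T, cfg$N) %*% chol(S)
  fc <- stats::cor(Z)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  connectivity_sample(subject_id, fc, cls)
}

#' Simulate a full two-class cohort
#'
#' Generates `n_per_class` subjects per class with deterministic per-subject
#' seeds derived from the cohort seed, and optionally writes the cohort to
#' disk in the package's exchange formats: one tab-separated matrix file per
#' subject, a tab-separated manifest (`subject_id`, `path`, `label`,
#' `subject_seed`) and a JSON sidecar recording the configuration.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory; created if absent. If it
#'   already contains a manifest the call fails unless `overwrite = TRUE`.
#' @param overwrite allow writing into a directory holding a previous cohort.
#' @return list with `samples` (list of [connectivity_sample()]) and
#'   `manifest` (data.frame; `path` is filled when `out_dir` is given).
#' @export
simulate_cohort <- function(cfg = sim_config(), out_dir = NULL,
                            overwrite = FALSE) {
  rows <- expand.grid(idx = seq_len(cfg$n_per_class), cls = 0:1)
  samples <- vector("list", nrow(rows))
  manifest <- data.frame(
    subject_id = character(nrow(rows)), path = character(nrow(rows)),
    label = integer(nrow(rows)), subject_seed = integer(nrow(rows)),
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(rows))) {
    cls <- rows$cls[r]
    idx <- rows$idx[r]
    sseed <- mix_seed(cfg$seed, cls, idx)
    id <- sprintf("sub-%d-%03d", cls, idx)
    samples[[r]] <- simulate_subject(cls, cfg, sseed, subject_id = id)
    manifest[r, ] <- list(id, paste0(id, ".tsv"), as.integer(cls), sseed)
  }
  if (!is.null(out_dir)) {
    mpath <- file.path(out_dir, "manifest.tsv")
    if (file.exists(mpath) && !overwrite) {
      stopf("output directory %s already holds a cohort (use overwrite = TRUE)",
            out_dir)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(nrow(manifest))) {
      write_connectivity_matrix(samples[[r]]$fc,
                                file.path(out_dir, manifest$path[r]))
    }
    utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(samples = samples, manifest = manifest)
}
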