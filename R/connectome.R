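#' Construct and validate a subject's connectivity sample
#'
#' A connectivity sample bundles one subject's symmetric region-by-region
#' functional-connectivity (FC) matrix with its binary diagnostic label.
#' The matrix is expected in correlation units: entries in `[-1, 1]`, unit
#' diagonal, symmetric to within `1e-8`.
#'
#' @param subject_id character scalar identifying the subject.
#' @param fc numeric `N x N` symmetric correlation matrix, `N >= 3`.
#' @param label diagnostic label: `0` (control) or `1` (case).
#' @return An object of class `connectivity_sample`: a list with fields
#'   `subject_id`, `fc`, `label`.
#' @examples
#' fc <- diag(3); fc[1, 2] <- fc[2, 1] <- 0.4
#' s <- connectivity_sample("sub-01", fc, 0)
#' @export
connectivity_sample <- function(subject_id, fc, label) {
  validate_fc(fc)
  if (!label %in% c(0, 1)) stopf("label must be 0 or 1, got %s", label)
  structure(
    list(subject_id = as.character(subject_id), fc = fc, label = as.integer(label)),
    class = "connectivity_sample"
  )
}

#' @noRd
validate_fc <- function(fc, tol = 1e-8, n_min = 3L) {
  check_matrix(fc, "fc")
  n <- nrow(fc)
  if (ncol(fc) != n) stopf("fc must be square, got %d x %d", n, ncol(fc))
  if (n < n_min) stopf("fc must have at least %d regions, got %d", n_min, n)
  check_finite(fc, "fc")
  asym <- abs(fc - t(fc))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stopf(
      "fc is not symmetric: entry (%d, %d) differs from (%d, %d) by %.3g",
      ij[1], ij[2], ij[2], ij[1], max(asym)
    )
  }
  if (max(abs(diag(fc) - 1)) > tol) {
    stopf("fc diagonal must be 1 (max deviation %.3g)", max(abs(diag(fc) - 1)))
  }
  invisible(fc)
}

#' Split a signed connectivity matrix into positive and negative channels
#'
#' Off-diagonal positive correlations go to the positive channel, the
#' magnitudes of negative correlations to the negative channel; both channels
#' have zero diagonals. For a unit-diagonal symmetric input,
#' `pos - neg + diag(N)` reconstructs the input exactly.
#'
#' @param fc symmetric unit-diagonal correlation matrix.
#' @return list with nonnegative matrices `pos` and `neg`.
#' @examples
#' fc <- diag(3); fc[1, 2] <- fc[2, 1] <- -0.3
#' signed_split(fc)$neg[1, 2]  # 0.3
#' @export
signed_split <- function(fc) {
  validate_fc(fc, n_min = 2L)
  pos <- pmax(fc, 0)
  neg <- pmax(-fc, 0)
  diag(pos) <- 0
  diag(neg) <- 0
  list(pos = pos, neg = neg)
}

#' Configuration of the multi-view graph construction
#'
#' Views are graded sparsifications of the signed connectivity: view `v`
#' keeps the fraction `densities[v]` of the strongest edges of each sign
#' channel, so distinct views carry distinct sparsity and the retained edge
#' sets are nested across views.
#'
#' @param V number of views (default 3).
#' @param densities strictly increasing retention fractions in `(0, 1]`, one
#'   per view. Default: `(1:V) / (V + 1)`.
#' @param feature_mode node features attached to every view graph:
#'   `"fc_row"` (row of the signed channel matrix, width `N`), `"degree"`
#'   (weighted degree, width 1) or `"identity"` (one-hot, width `N`).
#' @return object of class `view_config`.
#' @export
view_config <- function(V = 3, densities = NULL,
                        feature_mode = c("fc_row", "degree", "identity")) {
  feature_mode <- match.arg(feature_mode)
  if (!is_count(V) || V < 1) stopf("V must be a positive integer")
  V <- as.integer(V)
  if (is.null(densities)) densities <- seq_len(V) / (V + 1)
  densities <- as.numeric(densities)
  if (length(densities) != V) {
    stopf("densities must have length V = %d, got %d", V, length(densities))
  }
  if (any(densities <= 0 | densities > 1)) stopf("densities must lie in (0, 1]")
  if (V > 1 && any(diff(densities) <= 0)) {
    stopf("densities must be strictly increasing across views")
  }
  structure(list(V = V, densities = densities, feature_mode = feature_mode),
            class = "view_config")
}

# Edge ranking shared by all views of one sign channel: order candidate
# upper-triangle entries by (weight desc, row asc, col asc) for
# platform-independent determinism. Returns a data.frame of (i, j, w).
rank_edges <- function(half) {
  n <- nrow(half)
  ut <- which(upper.tri(half) & half > 0, arr.ind = TRUE)
  if (nrow(ut) == 0L) {
    return(data.frame(i = integer(), j = integer(), w = numeric()))
  }
  w <- half[ut]
  o <- order(-w, ut[, 1], ut[, 2])
  data.frame(i = ut[o, 1], j = ut[o, 2], w = w[o])
}

#' Build the signed multi-view graphs for one subject
#'
#' For each view `v` and each sign channel, keeps the
#' `ceiling(densities[v] * P)` strongest edges (`P` = number of strictly
#' positive entries of that channel, counting each undirected edge once),
#' mirrored symmetrically. Node neighborhoods are the retained neighbors plus
#' the node itself, so attention is defined even for isolated nodes.
#'
#' @param sample a [connectivity_sample()].
#' @param cfg a [view_config()].
#' @param coarsen optional hook: a function `view_graph -> view_graph`
#'   applied to every constructed view (extension point for graph
#'   coarsening; default `NULL` = no-op).
#' @return list of `2 * V` objects of class `view_graph`, ordered
#'   positive views 1..V then negative views 1..V. Each has fields
#'   `view_index`, `sign` (`"+"` or `"-"`), `adjacency`, `node_features`,
#'   `neighborhoods` (list of index vectors) and `mask` (logical `N x N`,
#'   retained edges plus the diagonal).
#' @export
build_views <- function(sample, cfg = view_config(), coarsen = NULL) {
  if (!inherits(sample, "connectivity_sample")) {
    stopf("sample must be a connectivity_sample")
  }
  if (!inherits(cfg, "view_config")) stopf("cfg must be a view_config")
  halves <- signed_split(sample$fc)
  n <- nrow(sample$fc)
  out <- vector("list", 2L * cfg$V)
  k <- 0L
  for (sign in c("+", "-")) {
    half <- if (sign == "+") halves$pos else halves$neg
    edges <- rank_edges(half)
    P <- nrow(edges)
    if (P == 0L) {
      warnf("subject %s: sign channel '%s' has no surviving edges; keeping self-loops only",
            sample$subject_id, sign)
    }
    for (v in seq_len(cfg$V)) {
      adj <- matrix(0, n, n)
      if (P > 0L) {
        keep <- edges[seq_len(ceiling(cfg$densities[v] * P)), , drop = FALSE]
        adj[cbind(keep$i, keep$j)] <- keep$w
        adj[cbind(keep$j, keep$i)] <- keep$w
      }
      mask <- adj != 0
      diag(mask) <- TRUE
      vg <- structure(
        list(
          view_index = v, sign = sign, adjacency = adj,
          node_features = view_features(half, adj, cfg$feature_mode),
          neighborhoods = lapply(seq_len(n), function(i) which(mask[i, ])),
          mask = mask
        ),
        class = "view_graph"
      )
      if (!is.null(coarsen)) vg <- coarsen(vg)
      k <- k + 1L
      out[[k]] <- vg
    }
  }
  # positive views first, then negative, each ordered by view_index
  out
}

view_features <- function(half, adj, feature_mode) {
  switch(feature_mode,
    fc_row = half,
    degree = matrix(rowSums(adj), ncol = 1L),
    identity = diag(nrow(half))
  )
}

#' Read a delimited connectivity matrix
#'
#' Accepts comma- or tab/whitespace-separated square numeric matrices with no
#' header, the common export format for region-by-region FC matrices.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_connectivity_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a connectivity matrix as tab-separated text
#' @param fc numeric matrix.
#' @param path output file path.
#' @export
write_connectivity_matrix <- function(fc, path) {
  utils::write.table(fc, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a subject manifest
#'
#' Tab-separated with a header row and columns `subject_id`, `path`,
#' `label` (0/1). Relative matrix paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest file path.
#' @return data.frame with character `subject_id`, character `path`, integer
#'   `label`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = TRUE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m))) {
    stopf("manifest must have columns %s; found %s",
          paste(need, collapse = ", "), paste(names(m), collapse = ", "))
  }
  m$label <- as.integer(m$label)
  if (!all(m$label %in% c(0L, 1L))) stopf("manifest labels must be 0 or 1")
  rel <- !file.exists(m$path) & file.exists(file.path(dirname(path), m$path))
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load all subjects named by a manifest
#' @param manifest data.frame from [read_manifest()] or a path to one.
#' @return list of [connectivity_sample()] objects.
#' @export
load_manifest_samples <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    connectivity_sample(manifest$subject_id[i],
                        read_connectivity_matrix(manifest$path[i]),
                        manifest$label[i])
  })
}
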