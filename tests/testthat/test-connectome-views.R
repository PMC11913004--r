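test_that("signed_split separates positive and negative correlations", {
  fc <- matrix(c(1, 0.5, 0.5, 1), 2)
  sp <- signed_split(fc)
  expect_equal(sp$pos[1, 2], 0.5)
  expect_equal(sp$neg, matrix(0, 2, 2))

  fc3 <- diag(3)
  fc3[1, 2] <- fc3[2, 1] <- -0.3
  fc3[1, 3] <- fc3[3, 1] <- 0.8
  sp3 <- signed_split(fc3)
  expect_equal(sp3$neg[1, 2], 0.3)
  expect_equal(sp3$pos[1, 2], 0)
  expect_equal(sp3$pos[1, 3], 0.8)
})

test_that("signed_split reconstruction pos - neg + I holds for random symmetric inputs", {
  for (seed in 1:5) {
    fc <- rand_fc(7, seed)
    sp <- signed_split(fc)
    expect_true(all(sp$pos >= 0) && all(sp$neg >= 0))
    expect_equal(diag(sp$pos), rep(0, 7))
    expect_identical(sp$pos - sp$neg + diag(7), fc)
  }
})

test_that("non-symmetric input is rejected naming the worst entry", {
  fc <- rand_fc(5, 1)
  fc[2, 4] <- fc[2, 4] + 0.01
  expect_error(signed_split(fc), "not symmetric.*\\(2, 4\\)")
  expect_error(connectivity_sample("x", fc, 0), "not symmetric")
})

test_that("view_config validates densities", {
  expect_error(view_config(3, c(0.5, 0.4, 0.6)), "strictly increasing")
  expect_error(view_config(3, c(0.2, 0.4)), "length")
  expect_error(view_config(2, c(0, 0.5)), "\\(0, 1\\]")
  expect_equal(view_config(3)$densities, c(0.25, 0.5, 0.75))
})

test_that("build_views retains the ceiling-count strongest edges per sign", {
  # 4 nodes, all six upper-triangle entries positive, rho = 0.5 -> 3 edges
  fc <- matrix(0.1, 4, 4)
  fc[upper.tri(fc)] <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  fc[lower.tri(fc)] <- t(fc)[lower.tri(fc)]
  diag(fc) <- 1
  s <- connectivity_sample("a", fc, 0)
  vg <- suppressWarnings(build_views(s, view_config(1, 0.5)))
  pos <- vg[[1]]
  expect_equal(sum(pos$adjacency != 0) / 2, 3)
  expect_equal(sort(pos$adjacency[pos$adjacency != 0]),
               rep(c(0.7, 0.8, 0.9), each = 2))
})

test_that("three views produce six graphs with matched indices and signs", {
  s <- tiny_sample(8, 3)
  vg <- build_views(s, view_config(3))
  expect_length(vg, 6)
  expect_equal(vapply(vg, `[[`, 0L, "view_index"), c(1:3, 1:3))
  expect_equal(vapply(vg, `[[`, "", "sign"), rep(c("+", "-"), each = 3))
  for (g in vg) {
    expect_true(all(g$adjacency >= 0))
    expect_identical(g$adjacency, t(g$adjacency))
  }
})

test_that("retained edge sets are nested across views and match the ceiling formula", {
  s <- tiny_sample(5, 21)
  cfg <- view_config(3, c(0.2, 0.4, 0.6))
  vg <- build_views(s, cfg)
  sp <- signed_split(s$fc)
  for (sign_i in 1:2) {
    half <- if (sign_i == 1) sp$pos else sp$neg
    # independent oracle: sort all positive upper-triangle entries once
    ut <- which(upper.tri(half) & half > 0, arr.ind = TRUE)
    ord <- order(-half[ut])
    sorted_edges <- ut[ord, , drop = FALSE]
    P <- nrow(sorted_edges)
    prev <- NULL
    for (v in 1:3) {
      g <- vg[[(sign_i - 1) * 3 + v]]
      k <- ceiling(cfg$densities[v] * P)
      got <- which(upper.tri(g$adjacency) & g$adjacency != 0, arr.ind = TRUE)
      expect_equal(nrow(got), k)
      want <- sorted_edges[seq_len(k), , drop = FALSE]
      expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
      if (!is.null(prev)) {
        expect_true(all(prev %in% paste(got[, 1], got[, 2])))
      }
      prev <- paste(got[, 1], got[, 2])
    }
  }
})

test_that("view construction commutes with node relabeling", {
  s <- tiny_sample(9, 33)
  cfg <- view_config(2, c(0.3, 0.6))
  set.seed(1)
  p <- sample(9)
  s_perm <- connectivity_sample("perm", s$fc[p, p], s$label)
  vg <- build_views(s, cfg)
  vg_perm <- build_views(s_perm, cfg)
  for (i in seq_along(vg)) {
    expect_equal(vg_perm[[i]]$adjacency, vg[[i]]$adjacency[p, p])
    expect_equal(vg_perm[[i]]$node_features, vg[[i]]$node_features[p, p])
  }
})

test_that("an empty sign channel warns and keeps self-loops only", {
  fc <- matrix(0.5, 4, 4)
  diag(fc) <- 1
  s <- connectivity_sample("allpos", fc, 0)
  expect_warning(vg <- build_views(s, view_config(1, 0.5)), "no surviving edges")
  neg <- vg[[2]]
  expect_equal(neg$adjacency, matrix(0, 4, 4))
  expect_equal(neg$neighborhoods, as.list(1:4))
})

test_that("node feature modes have the documented shapes", {
  s <- tiny_sample(6, 2)
  f_row <- build_views(s, view_config(1, 0.5))[[1]]$node_features
  expect_equal(dim(f_row), c(6, 6))
  f_deg <- build_views(s, view_config(1, 0.5, feature_mode = "degree"))[[1]]$node_features
  expect_equal(dim(f_deg), c(6, 1))
  f_id <- build_views(s, view_config(1, 0.5, feature_mode = "identity"))[[1]]$node_features
  expect_equal(f_id, diag(6))
})

test_that("matrix and manifest IO round-trips for both delimiters", {
  dir <- withr::local_tempdir()
  fc <- rand_fc(5, 9)
  p_tab <- file.path(dir, "m.tsv")
  write_connectivity_matrix(fc, p_tab)
  expect_equal(read_connectivity_matrix(p_tab), fc)
  p_csv <- file.path(dir, "m.csv")
  write.table(fc, p_csv, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_connectivity_matrix(p_csv), fc)

  man <- data.frame(subject_id = "s1", path = "m.tsv", label = 1L)
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  rd <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(rd$subject_id, "s1")
  expect_equal(rd$label, 1L)
  expect_true(file.exists(rd$path))  # resolved relative to the manifest
  samples <- load_manifest_samples(rd)
  expect_equal(samples[[1]]$fc, fc)
})
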