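test_that("noiseless duplicated blocks give a 0/1 consensus at k = 2", {
  base <- matrix(stats::rnorm(40), 8, 5)
  mat <- cbind(base + 5, base)    # two exact blocks of 5 samples
  colnames(mat) <- paste0("s", 1:10)
  rownames(mat) <- paste0("f", 1:8)
  res <- consensus_cluster(mat, k_range = 2:4, reps = 60, p_item = 0.8,
                           seed = 3)
  cm <- res$consensus[["2"]]
  expect_true(all(cm %in% c(0, 1)))
  expect_equal(res$selected_k, 2L)
  truth <- rep(1:2, each = 5)
  expect_equal(adjusted_rand_index(truth, unname(res$labels)), 1)
  # symmetric, unit diagonal, bounded
  for (k in names(res$consensus)) {
    m <- res$consensus[[k]]
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 10))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("reps = 1 with p_item = 1 is a single hard partition", {
  set.seed(8)
  mat <- matrix(stats::rnorm(60), 6, 10,
                dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  res <- consensus_cluster(mat, k_range = 2:3, reps = 1, p_item = 1,
                           seed = 1)
  for (k in names(res$consensus)) {
    m <- res$consensus[[k]]
    expect_true(all(m %in% c(0, 1)))
    cl <- consensus_labels(m, as.integer(k))
    expect_equal(unname(m), unname(outer(cl, cl, "==") * 1))
  }
})

test_that("consensus guards its preconditions", {
  mat <- matrix(stats::rnorm(30), 5, 6,
                dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  expect_error(consensus_cluster(mat, k_range = 1:3), ">= 2")
  expect_warning(consensus_cluster(mat, k_range = 2:10, reps = 5,
                                   seed = 1), "dropping")
})

test_that("planted subtypes are recovered exactly across seeds", {
  # criterion-6 style recovery at effect = 3 * noise_sd, reps = 100
  ks <- aris <- numeric(5)
  for (i in seq_along(ks)) {
    sim <- tiny_sim(seed = 300 + i)
    tr <- sim$truth
    mat <- sim$bundle$lnc[unlist(tr$marker_lnc_ids),
                          names(tr$subtype_labels)]
    res <- consensus_cluster(mat, k_range = 2:5, reps = 100, seed = i)
    ks[i] <- res$selected_k
    aris[i] <- adjusted_rand_index(tr$subtype_labels, res$labels)
  }
  expect_true(all(ks == 2L))
  expect_true(all(aris == 1))
})

test_that("consensus stabilizes with the number of repetitions", {
  sim <- tiny_sim(seed = 310)
  tr <- sim$truth
  mat <- sim$bundle$lnc[unlist(tr$marker_lnc_ids),
                        names(tr$subtype_labels)]
  r1 <- consensus_cluster(mat, k_range = 2, reps = 200, seed = 4)
  r2 <- consensus_cluster(mat, k_range = 2, reps = 1000, seed = 5)
  expect_lt(max(abs(r1$consensus[["2"]] - r2$consensus[["2"]])), 0.05)
})

test_that("pca_embed is an exact SVD with sane variance ratios", {
  set.seed(12)
  mat <- matrix(stats::rnorm(80), 10, 8,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  emb <- pca_embed(mat)
  centred <- t(mat) - colMeans(t(mat))[col(t(mat))]
  centred <- scale(t(mat), center = TRUE, scale = FALSE)
  recon <- emb$scores %*% t(emb$rotation)
  expect_equal(recon, centred, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(emb$var_explained) <= 1e-12))
  expect_lte(sum(emb$var_explained), 1 + 1e-12)
  expect_error(pca_embed(matrix(1, 4, 5)), "constant")

  # two well-separated blobs: PC1 separates with silhouette > 0.5
  blob <- cbind(matrix(stats::rnorm(40, 0), 10, 4),
                matrix(stats::rnorm(40, 6), 10, 4))
  dimnames(blob) <- list(paste0("f", 1:10), paste0("s", 1:8))
  e2 <- pca_embed(blob)
  pc1 <- e2$scores[, 1]
  lab <- rep(1:2, each = 4)
  sil <- vapply(1:8, function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    a <- mean(abs(pc1[i] - pc1[own]))
    b <- mean(abs(pc1[i] - pc1[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("subtype_de surfaces planted markers and clamps top_n", {
  sim <- tiny_sim(seed = 320, n_pulpitis = 8)
  tr <- sim$truth
  sub <- subtype_de(sim$bundle, tr$subtype_labels, top_n = 50,
                    moderated = TRUE)
  marker_genes <- unlist(sim$immune_sets$sets[unlist(tr$marker_sets)])
  # planted subtype-program genes dominate the top-50 mRNA table, far
  # beyond their 20% share of the gene pool (80 of 400)
  expect_gt(mean(sub$mrna$top$gene %in% marker_genes), 0.6)
  # planted marker lncRNAs rank at the top
  expect_gt(mean(sub$lnc$top$gene[1:10] %in% unlist(tr$marker_lnc_ids)),
            0.8)
  # z-scored matrices are row-standardized over the labelled samples
  expect_equal(unname(rowMeans(sub$lnc$zmat)),
               rep(0, nrow(sub$lnc$zmat)), tolerance = 1e-12)
  big <- subtype_de(sim$bundle, tr$subtype_labels, top_n = 1e6)
  expect_equal(nrow(big$lnc$top), nrow(sim$bundle$lnc))
  expect_error(subtype_de(sim$bundle, tr$subtype_labels[1:4][c(1, 2, 3)]),
               "two subtype labels|>= 2")
})

test_that("identical subtypes give uniform subtype_de p-values", {
  set.seed(9)
  pv <- unlist(lapply(1:20, function(i) {
    sim <- tiny_sim(seed = 400 + i, subtype_effect = 0, n_pulpitis = 8)
    labs <- sim$truth$subtype_labels
    sub <- subtype_de(sim$bundle, labs, top_n = 5, moderated = FALSE)
    sample(sub$mrna$table$p, 30)
  }))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif")$p.value), 0.01)
})
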