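test_that("rank_score follows the -log10(p) * sign(cc) formula", {
  expect_equal(rank_score(0.5, 1), 0)
  expect_equal(rank_score(-0.8, 0.01), -2)
  expect_equal(rank_score(0, 0.3), 0)
  # floor keeps the score finite
  expect_equal(rank_score(1, 0), 300)
  expect_equal(rank_score(-1, 1e-310), -300)
})

test_that("correlate matches closed-form r and p", {
  set.seed(4)
  n <- 5
  lnc <- matrix(stats::rnorm(3 * n), 3, n,
                dimnames = list(paste0("l", 1:3), paste0("s", 1:n)))
  mrna <- matrix(stats::rnorm(4 * n), 4, n,
                 dimnames = list(paste0("m", 1:4), paste0("s", 1:n)))
  res <- correlate(lnc, mrna)
  for (i in 1:3) for (j in 1:4) {
    r <- sum(scale(lnc[i, ], scale = FALSE) * scale(mrna[j, ],
                                                    scale = FALSE)) /
      ((n - 1) * stats::sd(lnc[i, ]) * stats::sd(mrna[j, ]))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    expect_equal(res$cc[i, j], r, tolerance = 1e-12)
    expect_equal(res$p[i, j], p, tolerance = 1e-12)
    ct <- stats::cor.test(lnc[i, ], mrna[j, ])
    expect_equal(res$p[i, j], ct$p.value, tolerance = 1e-10)
  }

  # perfect correlation is clamped, zero-variance rows are neutral
  self <- correlate(lnc[1, , drop = FALSE],
                    rbind(m = lnc[1, ], flat = rep(1, n)))
  expect_equal(self$cc[1, "m"], 1)
  expect_equal(self$p[1, "m"], 1e-300)
  expect_equal(self$cc[1, "flat"], 0)
  expect_equal(self$p[1, "flat"], 1)

  expect_error(correlate(lnc[, 1:3], mrna[, 1:3]), ">= 4")
})

test_that("gsea_es equals the exhaustive running-sum oracle", {
  # hand-checkable 5-gene case: rs = (3,2,1,-1,-2), set = ranks {1,3}
  rs <- stats::setNames(c(3, 2, 1, -1, -2), paste0("g", 1:5))
  set <- c("g1", "g3")
  # walk: +3/4, -1/3, +1/4, -1/3, -1/3 -> maximum deviation is the 3/4
  # reached right after the first hit
  expect_equal(gsea_es(rs, set), 3 / 4, tolerance = 1e-12)
  expect_equal(gsea_es(rs, set), gsea_es_oracle(rs, set), tolerance = 1e-12)

  # whole list as the set: no misses, peak = 1
  expect_equal(gsea_es(rs, names(rs)), gsea_es_oracle(rs, names(rs)),
               tolerance = 1e-12)
  expect_equal(gsea_es(rs, names(rs)), 1, tolerance = 1e-12)

  # coherent front-loading gives a positive score
  expect_gt(gsea_es(rs, c("g1", "g2")), 0)
  # empty intersection
  expect_true(is.na(gsea_es(rs, "absent")))

  # property: random lists of length <= 10 against the oracle
  set.seed(21)
  for (i in 1:300) {
    n <- sample(3:10, 1)
    rs <- stats::setNames(round(stats::rnorm(n), 2), paste0("g", 1:n))
    genes <- sample(names(rs), sample(1:n, 1))
    ex <- sample(c(0, 0.5, 1, 2), 1)
    expect_equal(gsea_es(rs, genes, exponent = ex),
                 gsea_es_oracle(rs, genes, exponent = ex),
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values are seeded, bounded and null-calibrated", {
  set.seed(2)
  rs <- stats::setNames(stats::rnorm(60), paste0("g", 1:60))
  ranked <- build_ranked_list(rs)
  es <- gsea_es(ranked, names(rs)[1:10])
  null1 <- withr::with_seed(5, gsea_null_es(ranked, 10, 500))
  null2 <- withr::with_seed(5, gsea_null_es(ranked, 10, 500))
  expect_identical(null1, null2)
  p <- gsea_perm_p(es, null1)
  expect_gte(p, 1 / 501)
  expect_lte(p, 1)
  expect_equal(gsea_perm_p(0, null1), 1)

  # strong planted signal saturates the estimator bound
  rs2 <- stats::setNames(c(rep(5, 8), stats::rnorm(52, 0, 0.1)),
                         paste0("g", 1:60))
  ranked2 <- build_ranked_list(rs2)
  es2 <- gsea_es(ranked2, paste0("g", 1:8))
  null3 <- withr::with_seed(1, gsea_null_es(ranked2, 8, 500))
  expect_lte(gsea_perm_p(es2, null3), 2 / (1 + sum(null3 > 0)))

  # null calibration: p for random sets on exchangeable lists is uniform
  set.seed(77)
  pvals <- replicate(200, {
    rsr <- stats::setNames(stats::rnorm(40), paste0("g", 1:40))
    rk <- build_ranked_list(rsr)
    genes <- sample(names(rsr), 8)
    e <- gsea_es(rk, genes)
    gsea_perm_p(e, gsea_null_es(rk, 8, 200))
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("lncres_transform algebra: bounds, signs, boundary, monotonicity", {
  expect_equal(lncres_transform(0.4, 0), 1)
  expect_equal(lncres_transform(-0.3, 0.5), 0)
  expect_equal(lncres_transform(0.4, 0.0025), 0.995)
  expect_equal(lncres_transform(0, 0.2), 0)
  expect_error(lncres_transform(0.5, 1.5), "\\[0, 1\\]")

  p <- seq(0, 1, by = 0.01)
  up <- lncres_transform(rep(1, length(p)), p)
  dn <- lncres_transform(rep(-1, length(p)), p)
  expect_true(all(up >= -1 & up <= 1 & dn >= -1 & dn <= 1))
  expect_true(all(diff(up) < 0))   # strictly decreasing in p for es > 0
  expect_true(all(diff(dn) > 0))   # strictly increasing in p for es < 0
  expect_equal(sign(up[p < 0.5]), rep(1, sum(p < 0.5)))
})

test_that("lncres_score is invariant to row and sample order", {
  sim <- tiny_sim(seed = 8, subtype_effect = 0)
  lnc <- sim$bundle$lnc[1:15, ]
  mrna <- sim$bundle$mrna[1:120, ]
  sets <- random_collection(rownames(mrna), n_sets = 3, size = 10)
  t1 <- lncres_score(lnc, mrna, sets, nperm = 100, min_set_size = 3,
                     seed = 5)
  t2 <- lncres_score(lnc[sample(nrow(lnc)), ],
                     mrna[sample(nrow(mrna)), ], sets, nperm = 100,
                     min_set_size = 3, seed = 5)
  expect_equal(t1$es, t2$es, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  perm <- sample(ncol(lnc))
  t3 <- lncres_score(lnc[, perm], mrna[, perm], sets, nperm = 100,
                     min_set_size = 3, seed = 5)
  expect_equal(t1$es, t3$es, tolerance = 1e-9)

  # vacuous filter flags every scored pair
  t4 <- lncres_score(lnc, mrna, sets, nperm = 100, min_set_size = 3,
                     lncres_cut = -1.01, fdr_cut = 1.01, seed = 5)
  expect_true(all(t4$significant))
  expect_equal(nrow(t4), nrow(lnc) * 3L)
})

test_that("intersect_with_de and overlap_validation behave on edge cases", {
  expect_identical(intersect_with_de(c("a", "b"), c("c"))$overlap,
                   character(0))
  expect_identical(intersect_with_de(c("b", "a"), c("a", "b", "c"))$overlap,
                   c("a", "b"))
  v <- intersect_with_de(c("a", "b"), c("b", "c"))
  expect_equal(c(v$n_a, v$n_b, v$n_overlap), c(2, 2, 1))

  tab <- data.frame(lnc = c("l1", "l2"), set = "S", lncres = c(0.999, 0.1),
                    significant = c(TRUE, FALSE))
  same <- overlap_validation(tab, tab)
  expect_equal(same$jaccard, 1)
  tab2 <- tab
  tab2$significant <- c(FALSE, TRUE)
  expect_equal(overlap_validation(tab, tab2)$jaccard, 0)
})

test_that("planted drivers replicate across independent-noise cohorts", {
  cfg_a <- tiny_config(seed = 40, rho = 0.8, subtype_effect = 0,
                       de_frac = 0, n_normal = 6, n_pulpitis = 6)
  cfg_b <- replication_config(cfg_a)
  sim_a <- generate_bundle(cfg_a)
  sim_b <- generate_bundle(cfg_b)
  ta <- lncres_score(sim_a$bundle$lnc[sim_a$truth$planted_lnc_ids, ],
                     sim_a$bundle$mrna, sim_a$immune_sets,
                     nperm = 1000, seed = 1)
  tb <- lncres_score(sim_b$bundle$lnc[sim_b$truth$planted_lnc_ids, ],
                     sim_b$bundle$mrna, sim_b$immune_sets,
                     nperm = 1000, seed = 2)
  ov <- overlap_validation(ta, tb)
  expect_gte(ov$jaccard, 0.7)
  # the driven (lnc, own-set) pairs carry reproducible lncRES values
  key_a <- paste(ta$lnc, ta$set)
  key_b <- paste(tb$lnc, tb$set)
  own <- paste(names(sim_a$truth$lnc_to_set), sim_a$truth$lnc_to_set)
  expect_gt(min(ta$lncres[match(own, key_a)]), 0.9)
  expect_gt(min(tb$lncres[match(own, key_b)]), 0.9)
})
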