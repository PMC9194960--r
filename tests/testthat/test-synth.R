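test_that("generator is seed-deterministic and structurally valid", {
  cfg <- synth_config(n_mrna = 2000, n_lnc = 300, n_planted_lnc = 20,
                      rho = 0.8, seed = 7)
  sim1 <- generate_bundle(cfg)
  sim2 <- generate_bundle(cfg)
  expect_identical(sim1$bundle$lnc, sim2$bundle$lnc)
  expect_identical(sim1$bundle$mrna, sim2$bundle$mrna)
  expect_identical(sim1$truth, sim2$truth)

  tr <- sim1$truth
  expect_true(all(tr$planted_lnc_ids %in% rownames(sim1$bundle$lnc)))
  expect_setequal(names(tr$lnc_to_set), tr$planted_lnc_ids)
  expect_true(all(tr$lnc_to_set %in% names(sim1$immune_sets$sets)))
  pulp <- sim1$bundle$design$sample_id[sim1$bundle$design$condition ==
                                         "pulpitis"]
  expect_setequal(names(tr$subtype_labels), pulp)
  expect_setequal(unique(tr$subtype_labels), 1:2)
  expect_length(sim1$immune_sets$sets, 17L)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(rho = 1), "rho")
  expect_error(synth_config(n_planted_lnc = 400, n_lnc = 300), "n_planted")
  expect_error(synth_config(genes_per_set = 200, n_immune_sets = 17,
                            n_mrna = 2000), "exceeds n_mrna")
  expect_error(synth_config(rho = 0.95, noise_sd = 0.8), "loading")
})

test_that("planted pairs attain the target correlation (n = 200)", {
  cfg <- synth_config(n_normal = 100, n_pulpitis = 100, rho = 0.8,
                      de_frac = 0, subtype_effect = 0, seed = 31)
  sim <- generate_bundle(cfg)
  rs <- vapply(names(sim$truth$lnc_to_set), function(l) {
    mem <- sim$immune_sets$sets[[sim$truth$lnc_to_set[[l]]]]
    mean(stats::cor(sim$bundle$lnc[l, ], t(sim$bundle$mrna[mem, ])))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.05)
})

test_that("zero-noise planted pairs correlate exactly, sign-consistently", {
  cfg <- tiny_config(seed = 2, noise_sd = 0, rho = 0.9, n_planted_lnc = 1,
                     de_frac = 0, subtype_effect = 0)
  sim <- generate_bundle(cfg)
  l <- names(sim$truth$lnc_to_set)[1]
  mem <- sim$immune_sets$sets[[sim$truth$lnc_to_set[[1]]]]
  r <- stats::cor(sim$bundle$lnc[l, ], t(sim$bundle$mrna[mem, ]))
  expect_equal(unname(drop(r)), rep(1, length(mem)), tolerance = 1e-12)
})

test_that("no planted signal means near-null data", {
  cfg <- tiny_config(seed = 3, rho = 0, n_planted_lnc = 0, de_frac = 0,
                     subtype_effect = 0)
  sim <- generate_bundle(cfg)
  expect_length(sim$truth$planted_lnc_ids, 0L)
  # member mRNAs of any set are mutually independent noise
  mem <- sim$immune_sets$sets[[1]]
  cmat <- stats::cor(t(sim$bundle$mrna[mem[1:10], ]))
  expect_lt(max(abs(cmat[upper.tri(cmat)])), 0.95)
})

test_that("planted subtypes separate on marker genes at 3*noise_sd", {
  sim <- tiny_sim(seed = 4)
  tr <- sim$truth
  mk <- unlist(tr$marker_lnc_ids)
  mat <- sim$bundle$lnc[mk, names(tr$subtype_labels)]
  d <- as.matrix(stats::dist(t(mat)))
  same <- outer(tr$subtype_labels, tr$subtype_labels, "==")
  within <- mean(d[same & upper.tri(d)])
  between <- mean(d[!same & upper.tri(d)])
  expect_gt(between, within)
})

test_that("fixture write/read round-trips losslessly", {
  sim <- tiny_sim(seed = 5)
  dir <- withr::local_tempdir()
  files <- write_fixture(sim, dir)
  expect_length(files, 5L)
  expect_true(all(file.exists(files)))
  back <- read_fixture(dir)
  expect_equal(back$bundle$lnc, sim$bundle$lnc)
  expect_equal(back$bundle$mrna, sim$bundle$mrna)
  expect_identical(back$bundle$design, sim$bundle$design)
  expect_identical(back$immune_sets$sets, sim$immune_sets$sets)
  expect_length(back$immune_sets$sets, 17L)
  expect_setequal(back$truth$planted_lnc_ids, sim$truth$planted_lnc_ids)
  expect_identical(back$truth$lnc_to_set[names(sim$truth$lnc_to_set)],
                   sim$truth$lnc_to_set)
  expect_identical(back$truth$subtype_labels[names(sim$truth$subtype_labels)],
                   sim$truth$subtype_labels)
})

test_that("replication cohort shares structure but not noise", {
  cfg_a <- tiny_config(seed = 6)
  cfg_b <- replication_config(cfg_a)
  sim_a <- generate_bundle(cfg_a)
  sim_b <- generate_bundle(cfg_b)
  expect_identical(sim_a$truth$planted_lnc_ids,
                   sim_b$truth$planted_lnc_ids)
  expect_identical(sim_a$truth$lnc_to_set, sim_b$truth$lnc_to_set)
  expect_identical(ncol(sim_b$bundle$lnc), 12L)
  expect_false(identical(sim_a$bundle$lnc[, 1], sim_b$bundle$lnc[, 1]))
})
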