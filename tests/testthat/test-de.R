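test_that("fit_two_group matches the direct pooled-variance formulas", {
  set.seed(1)
  m <- matrix(stats::rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  grp <- rep(c("normal", "pulpitis"), each = 5)
  fit <- fit_two_group(m, grp)
  for (i in 1:6) {
    o <- pooled_oracle(m[i, 1:5], m[i, 6:10])
    expect_equal(fit$log2fc[i], o$log2fc, tolerance = 1e-12)
    expect_equal(fit$s2[i], o$s2, tolerance = 1e-12)
    expect_equal(fit$df[i], o$df)
  }

  # degenerate rows
  m2 <- rbind(flat = rep(1, 10), shift = rep(c(0, 1), each = 5))
  colnames(m2) <- paste0("s", 1:10)
  fit2 <- fit_two_group(m2, grp)
  expect_equal(fit2$log2fc, c(0, 1))
  expect_equal(fit2$s2, c(0, 0))

  expect_error(fit_two_group(m[, c(1, 2, 6)], grp[c(1, 2, 6)]),
               ">= 2 samples")
  expect_error(fit_two_group(m[, 1:3], grp[1:3]), "two groups")
})

test_that("variance moderation recovers a known scaled-inverse-chi2 prior", {
  set.seed(42)
  d0 <- 4; s0_sq <- 2; m <- 5000; df <- 10
  sigma2 <- d0 * s0_sq / stats::rchisq(m, d0)
  s2 <- sigma2 * stats::rchisq(m, df) / df
  sq <- squeeze_variance(s2, df)
  expect_lt(abs(sq$d0 - d0), 0.5)
  expect_lt(abs(sq$s0_sq - s0_sq) / s0_sq, 0.10)
})

test_that("moderated t agrees with the independent reference implementation", {
  set.seed(9)
  n1 <- 4; n2 <- 5
  m <- matrix(stats::rnorm(200 * (n1 + n2), sd = stats::rchisq(200, 5) / 5),
              200, n1 + n2,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:(n1 + n2))))
  grp <- rep(c("normal", "pulpitis"), c(n1, n2))
  mine <- moderate_t(fit_two_group(m, grp))
  design <- cbind(1, grp == "pulpitis")
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(mine, "d0"), lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s0_sq"), lfit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(mine$p, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("d0 limits behave as the closed forms say", {
  set.seed(3)
  m <- matrix(stats::rnorm(50 * 8), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  grp <- rep(c("normal", "pulpitis"), each = 4)
  fit <- fit_two_group(m, grp)

  # d0 = Inf: equal log2FC implies equal t whatever the gene variances
  inf <- moderate_t(fit, d0 = Inf)
  su <- attr(fit, "stdev_unscaled")
  expect_equal(inf$t,
               fit$log2fc / (sqrt(attr(inf, "s0_sq")) * su),
               tolerance = 1e-12)

  # d0 = 0: ordinary pooled t
  ord <- moderate_t(fit, d0 = 0)
  expect_equal(ord$t, fit$log2fc / (sqrt(fit$s2) * su), tolerance = 1e-12)
  expect_equal(ord$p, 2 * stats::pt(-abs(ord$t), df = fit$df),
               tolerance = 1e-12)

  expect_error(squeeze_variance(rep(0, 50), 6), "degenerate")
})

test_that("t_mod is monotone in |log2FC| and in s2", {
  fit <- data.frame(gene = paste0("g", 1:100),
                    log2fc = seq(0, 2, length.out = 100),
                    s2 = rep(1, 100), df = 8)
  attr(fit, "stdev_unscaled") <- 0.5
  t1 <- moderate_t(fit, d0 = 4)$t
  expect_true(all(diff(t1) > 0))
  fit2 <- fit
  fit2$log2fc <- 1
  fit2$s2 <- seq(0.2, 3, length.out = 100)
  t2 <- moderate_t(fit2, d0 = 4)$t
  expect_true(all(diff(t2) < 0))
})

test_that("bh_adjust equals the O(m^2) oracle, p.adjust, and is permutation-safe", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:25) {
    p <- stats::runif(sample(2:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("select_de applies the dual threshold and sorts deterministically", {
  set.seed(2)
  m <- matrix(stats::rnorm(40 * 8), 40, 8,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  grp <- rep(c("normal", "pulpitis"), each = 4)
  tab <- de_analysis(m, grp)
  all_in <- select_de(tab, alpha = 1, lfc = 0)
  expect_equal(nrow(all_in), 40L)
  expect_true(!is.unsorted(all_in$p))
  # a single null gene (log2FC exactly 0) yields no selection
  none <- de_analysis(matrix(c(0, 1, 0, 1, 1, 0, 1, 0) + 0.5,
                             nrow = 1,
                             dimnames = list("g1", paste0("s", 1:8))),
                      grp, moderated = FALSE)
  expect_equal(nrow(select_de(none, alpha = 0.05, lfc = 0)), 0L)
})

test_that("planted differential genes are recovered with controlled FDR", {
  sens <- fdr <- numeric(20)
  for (i in 1:20) {
    cfg <- tiny_config(seed = 200 + i, n_normal = 6, n_pulpitis = 6,
                       de_frac = 0.1, de_effect = 2, noise_sd = 0.5,
                       subtype_effect = 0)
    sim <- generate_bundle(cfg)
    tab <- de_analysis(sim$bundle$mrna, sim$bundle$design$condition,
                       alpha = 0.05, lfc = 1)
    hits <- select_de(tab)$gene
    truth <- intersect(sim$truth$de_gene_ids, rownames(sim$bundle$mrna))
    sens[i] <- mean(truth %in% hits)
    fdr[i] <- if (length(hits)) mean(!hits %in% truth) else 0
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.1)
})
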