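test_that("additive fit matches exact and brute-force solutions", {
  g <- rep(c(0, 1, 2), each = 10)
  fit <- fit_additive(g, 0.5 * g)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_lt(fit$p, 1e-200)

  # brute-force normal-equations oracle on random small designs, and lm()
  set.seed(13)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(g) == 0) next
    C <- matrix(rnorm(n * 2), n)
    y <- rnorm(n) + 0.3 * g
    fit <- fit_additive(g, y, C)
    X <- cbind(1, g, C)
    beta_ne <- solve(t(X) %*% X, t(X) %*% y)       # normal equations
    expect_equal(fit$beta, beta_ne[2], tolerance = 1e-8)
    lm_fit <- summary(lm(y ~ g + C))$coefficients["g", ]
    expect_equal(fit$se, unname(lm_fit["Std. Error"]), tolerance = 1e-8)
    expect_equal(fit$p, unname(lm_fit["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("additive fit errors on degenerate designs", {
  expect_error(fit_additive(rep(1, 30), rnorm(30)),
               class = "pg_monomorphic_error")
  g <- rbinom(30, 2, 0.4)
  expect_error(fit_additive(g, rnorm(30), cbind(g)),   # collinear
               class = "pg_fit_error")
  expect_error(fit_additive(c(0, 2), rnorm(2)), class = "pg_fit_error")
})

test_that("the vectorized scan equals the per-SNP fit and handles missingness", {
  sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 150, n_snps = 40, missing_rate = 0.03, seed = 23
  ))
  covars <- data.frame(sex = sim$phenotypes$sex)
  res <- run_gwas(sim$genotypes, sim$phenotypes, covars)
  for (id in sample(res$id, 8)) {
    j <- match(id, sim$genotypes$snp_meta$id)
    fit <- fit_additive(sim$genotypes$codes[, j],
                        sim$phenotypes$phenotype, covars)
    k <- match(id, res$id)
    expect_equal(res$beta[k], fit$beta, tolerance = 1e-10)
    expect_equal(res$se[k], fit$se, tolerance = 1e-10)
    expect_equal(res$p[k], fit$p, tolerance = 1e-10)
    expect_equal(res$n_used[k], fit$n_used)
  }
  expect_true(!is.unsorted(res$p, na.rm = TRUE))
})

test_that("flipping allele labels flips beta and leaves p unchanged", {
  sim <- simulate_cohort(sim_cohort_config(n_individuals = 200,
                                           n_snps = 10, seed = 29))
  res1 <- run_gwas(sim$genotypes, sim$phenotypes)
  gm2 <- sim$genotypes
  gm2$codes[, 1] <- 2 - gm2$codes[, 1]
  res2 <- run_gwas(gm2, sim$phenotypes)
  id <- sim$genotypes$snp_meta$id[1]
  k1 <- match(id, res1$id)
  k2 <- match(id, res2$id)
  expect_equal(res2$beta[k2], -res1$beta[k1], tolerance = 1e-10)
  expect_equal(res2$p[k2], res1$p[k1], tolerance = 1e-10)
})

test_that("rank-transformed scans are invariant to monotone phenotype maps", {
  sim <- simulate_cohort(sim_cohort_config(n_individuals = 150,
                                           n_snps = 30, seed = 31))
  ph1 <- sim$phenotypes
  ph2 <- ph1
  ph2$phenotype <- exp(ph2$phenotype)              # strictly monotone
  r1 <- run_gwas(sim$genotypes, ph1, rank_transform = TRUE)
  r2 <- run_gwas(sim$genotypes, ph2, rank_transform = TRUE)
  expect_equal(r1$p[match(r1$id, r1$id)],
               r2$p[match(r1$id, r2$id)], tolerance = 1e-12)
})

test_that("rank mode calms a heavy-tailed null phenotype", {
  sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 300, n_snps = 400, causal_snp = NULL,
    sex_effect_sd = 0, seed = 37
  ))
  ph <- sim$phenotypes
  ph$phenotype <- ph$phenotype^3                   # heavy tails
  ks_raw <- suppressWarnings(
    ks.test(run_gwas(sim$genotypes, ph)$p, "punif")$statistic
  )
  ks_rank <- suppressWarnings(
    ks.test(run_gwas(sim$genotypes, ph, rank_transform = TRUE)$p,
            "punif")$statistic
  )
  expect_lt(ks_rank, ks_raw)
})

test_that("genotype PCA separates clusters and respects symmetries", {
  sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 160, n_snps = 300, causal_snp = NULL,
    n_clusters = 2, cluster_divergence = 0.1, seed = 41
  ))
  pcs <- genotype_pca(sim$genotypes, 3)
  r <- abs(cor(pcs$pc1, sim$truth$cluster_id))
  expect_gt(r, 0.9)

  # homogeneous cohort: leading eigenvalue stays inside the bulk
  null_sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 160, n_snps = 1000, causal_snp = NULL, seed = 43
  ))
  ev <- attr(genotype_pca(null_sim$genotypes, 3), "eigenvalues")
  expect_lt(ev[1] / median(ev[ev > 1e-8]), 3)

  # duplicating every sample duplicates the scores
  gm <- sim$genotypes
  dup <- genotype_matrix(rbind(gm$codes, gm$codes), gm$snp_meta,
                         c(gm$sample_ids, paste0(gm$sample_ids, "_b")))
  pcs_dup <- genotype_pca(dup, 2)
  n <- nrow(gm$codes)
  expect_equal(pcs_dup$pc1[1:n], pcs_dup$pc1[n + 1:n], tolerance = 1e-9)
  expect_error(genotype_pca(gm, 1000), class = "pg_parameter_error")
})

test_that("genomic inflation is calibrated and scale-equivariant", {
  m <- 10000
  p_grid <- (seq_len(m) - 0.5) / m
  gi <- genomic_inflation(p_grid)
  expect_equal(gi$lambda, 1, tolerance = 1e-3)
  # multiplying the chi-squares by 1.3 scales lambda by 1.3
  chi <- qchisq(p_grid, 1, lower.tail = FALSE)
  p_infl <- pchisq(1.3 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_infl)$lambda, 1.3, tolerance = 0.02)
  expect_error(genomic_inflation(runif(50)), class = "pg_parameter_error")
  expect_error(genomic_inflation(c(rep(0.5, 200), 0)),
               class = "pg_parameter_error")
  # Q-Q band brackets the diagonal
  expect_true(all(gi$qq$lower <= gi$qq$expected + 1e-9))
  expect_true(all(gi$qq$upper >= gi$qq$expected - 1e-9))
})

test_that("stratification inflates lambda and PCs deflate it back", {
  sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 400, n_snps = 2500, causal_snp = NULL,
    n_clusters = 2, cluster_divergence = 0.1, sex_effect_sd = 0, seed = 47
  ))
  # phenotype shifted by cluster membership: confounded null
  ph <- sim$phenotypes
  ph$phenotype <- ph$phenotype + 0.4 * (sim$truth$cluster_id - 1)
  lam_raw <- genomic_inflation(run_gwas(sim$genotypes, ph)$p)$lambda
  pcs <- genotype_pca(sim$genotypes, 3)
  lam_adj <- genomic_inflation(run_gwas(sim$genotypes, ph, pcs)$p)$lambda
  expect_gt(lam_raw, 1.05)
  expect_gte(lam_adj, 0.9)
  expect_lte(lam_adj, 1.1)
})
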