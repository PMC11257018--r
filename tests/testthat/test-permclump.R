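test_that("IBS clustering recovers trivial and simulated structure", {
  # two groups of identical-genotype samples -> perfect partition
  codes <- rbind(matrix(0, 5, 20), matrix(2, 5, 20))
  codes[, 1] <- c(rep(0, 5), rep(1, 5))            # keep SNPs polymorphic
  meta <- data.frame(chrom = "1", pos = 1:20 * 10,
                     id = sprintf("v%02d", 1:20), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(codes, meta, sprintf("i%02d", 1:10))
  cl <- ibs_cluster(gm, 2)
  expect_equal(length(unique(cl$cluster_id[1:5])), 1)
  expect_equal(length(unique(cl$cluster_id[6:10])), 1)
  expect_false(cl$cluster_id[1] == cl$cluster_id[6])
  expect_equal(unique(ibs_cluster(gm, 1)$cluster_id), 1L)
  expect_error(ibs_cluster(gm, 50), class = "pg_parameter_error")

  # two diverged populations -> near-perfect recovery
  sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 120, n_snps = 300, causal_snp = NULL,
    n_clusters = 2, cluster_divergence = 0.1, seed = 51
  ))
  cl2 <- ibs_cluster(sim$genotypes, 2)
  tab <- table(cl2$cluster_id, sim$truth$cluster_id)
  agree <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / 120
  expect_gt(agree, 0.95)
})

test_that("max-T with one SNP reproduces the raw p-value", {
  sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 200, n_snps = 1,
    causal_snp = list(maf = 0.3, beta_sd_per_allele = 0.15), seed = 53
  ))
  pr <- maxT_permutation(sim$genotypes, sim$phenotypes, n_perm = 800,
                         seed = 2)
  p_raw <- pr$table$p
  mc_se <- sqrt(p_raw * (1 - p_raw) / 800)
  expect_lt(abs(pr$table$corrected_p - p_raw), 4 * mc_se + 2 / 801)
})

test_that("max-T corrected p-values keep their structural guarantees", {
  sim <- simulate_cohort(sim_cohort_config(n_individuals = 150,
                                           n_snps = 60, seed = 57))
  cl <- ibs_cluster(sim$genotypes, 3)
  pr <- maxT_permutation(sim$genotypes, sim$phenotypes,
                         covars = data.frame(sex = sim$phenotypes$sex),
                         clusters = cl, n_perm = 200, seed = 5)
  tab <- pr$table[order(pr$table$p), ]
  expect_true(!is.unsorted(tab$corrected_p))       # monotone in raw p
  expect_true(all(tab$corrected_p >= 1 / 201))
  expect_true(all(tab$corrected_p <= 1))
  expect_equal(pr$observed_min_id, tab$id[1])
  # permutation stream is reproducible
  pr2 <- maxT_permutation(sim$genotypes, sim$phenotypes,
                          covars = data.frame(sex = sim$phenotypes$sex),
                          clusters = cl, n_perm = 200, seed = 5)
  expect_identical(pr$min_p_perm, pr2$min_p_perm)
})

test_that("permutation really is restricted to clusters", {
  # phenotype constant within each cluster: within-cluster shuffles leave
  # it untouched, so every permutation minimum equals the observed one
  sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 100, n_snps = 30, causal_snp = NULL, seed = 59
  ))
  clusters <- rep(1:2, length.out = 100)
  ph <- sim$phenotypes
  ph$phenotype <- as.numeric(clusters == 1)
  pr <- maxT_permutation(sim$genotypes, ph, clusters = clusters,
                         n_perm = 50, seed = 3)
  obs_min <- min(pr$table$p)
  expect_true(all(abs(pr$min_p_perm - obs_min) < 1e-12))
})

test_that("composite LD r2 obeys its identities and null expectation", {
  set.seed(61)
  g <- rbinom(400, 2, 0.4)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)                 # allele-flip invariance
  h <- rbinom(400, 2, 0.3)
  expect_equal(ld_r2(g, h), ld_r2(h, g))
  expect_error(ld_r2(g, rep(1, 400)), class = "pg_ld_error")

  # independent SNPs: E[r2] ~ 1/n
  n <- 500
  r2s <- replicate(400, ld_r2(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3)))
  se <- sd(r2s) / sqrt(length(r2s))
  expect_lt(abs(mean(r2s) - 1 / n), 3 * se + 1e-4)
})

test_that("clumping follows the greedy index rules", {
  # one isolated hit
  set.seed(63)
  codes <- matrix(rbinom(50 * 10, 2, 0.3), 50)
  meta <- data.frame(chrom = "1", pos = 1:10 * 1e5,
                     id = sprintf("v%02d", 1:10), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(codes, meta, sprintf("i%02d", 1:50))
  res <- data.frame(id = meta$id, chrom = meta$chrom, pos = meta$pos,
                    p = c(1e-8, rep(0.5, 9)))
  cr <- clump(res, gm)
  expect_equal(nrow(cr$ranges), 1)
  expect_equal(cr$members$id, "v01")

  # two SNPs in perfect LD: single clump indexed by the smaller p
  codes2 <- codes
  codes2[, 2] <- codes2[, 1]
  gm2 <- genotype_matrix(codes2, meta, sprintf("i%02d", 1:50))
  res2 <- res
  res2$p[2] <- 1e-6
  cr2 <- clump(res2, gm2)
  expect_equal(nrow(cr2$ranges), 1)
  expect_equal(cr2$ranges$index_id, "v01")
  expect_true("v02" %in% cr2$members$id)

  # nothing below p1 -> empty report, not an error
  res3 <- res
  res3$p <- rep(0.5, 10)
  expect_equal(nrow(clump(res3, gm)$ranges), 0)
})

test_that("clumps partition their SNPs on simulated LD blocks", {
  for (sd in 1:5) {
    lb <- simulate_ld_block(seed = 70 + sd)
    res <- run_gwas(lb$genotypes, lb$phenotypes)
    cr <- clump(res, lb$genotypes)
    expect_gt(nrow(cr$ranges), 0)
    expect_equal(anyDuplicated(cr$members$id), 0)
    expect_true(cr$ranges$bp_min[1] <= lb$truth$causal_pos)
    expect_true(cr$ranges$bp_max[1] >= lb$truth$causal_pos)
  }
})

test_that("group effect-size permutation flags a true sex difference", {
  set.seed(67)
  n <- 500
  g <- rbinom(n, 2, 0.4)
  grp <- rep(c(TRUE, FALSE), length.out = n)
  y <- ifelse(grp, 0.6 * g, 0) + rnorm(n)
  meta <- data.frame(chrom = "1", pos = 100, id = "snp1", a1 = "A",
                     a2 = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(matrix(g, ncol = 1), meta, sprintf("i%03d", 1:n))
  out <- sex_effect_permutation(gm, y, NULL, grp, "snp1", n_perm = 400,
                                seed = 9)
  expect_lt(out$p, 0.05)
  expect_equal(out$group_sizes, c(250, 250))
  expect_equal(out$beta_group1 - out$beta_group2, out$observed_diff,
               tolerance = 0.3)
  expect_error(
    sex_effect_permutation(gm, y, NULL, grp, "snp1", n_perm = 0),
    class = "pg_parameter_error"
  )
  expect_error(
    sex_effect_permutation(gm, y, NULL, grp, "nope", n_perm = 10),
    class = "pg_parameter_error"
  )
})

test_that("group permutation p-values are well-behaved under the null", {
  set.seed(71)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  meta <- data.frame(chrom = "1", pos = 100, id = "snp1", a1 = "A",
                     a2 = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(matrix(g, ncol = 1), meta, sprintf("i%03d", 1:n))
  ps <- vapply(1:20, function(r) {
    y <- 0.3 * g + rnorm(n)                        # same effect both groups
    grp <- sample(rep(c(TRUE, FALSE), length.out = n))
    sex_effect_permutation(gm, y, NULL, grp, "snp1", n_perm = 99,
                           seed = 100 + r)$p
  }, numeric(1))
  expect_lte(mean(ps <= 0.1), 0.35)
  expect_gt(mean(ps), 0.25)
})

test_that("noncentral-F power matches closed cases and a Monte-Carlo oracle", {
  # zero effect: power equals the significance level exactly
  expect_equal(as.numeric(power_ncf(0, 1, 977, 5e-7)), 5e-7,
               tolerance = 1e-12)
  # strictly increasing in effect size and residual df
  grid_r2 <- as.numeric(power_ncf(seq(0.01, 0.1, by = 0.01), 1, 977, 5e-7))
  expect_true(all(diff(grid_r2) > 0))
  grid_nu2 <- vapply(c(200, 500, 1000, 2000), function(nu2) {
    as.numeric(power_ncf(0.02, 1, nu2, 5e-7))
  }, numeric(1))
  expect_true(all(diff(grid_nu2) > 0))
  expect_error(power_ncf(1, 1, 977, 5e-7), class = "pg_parameter_error")
  expect_error(power_ncf(0.1, 1, 977, 2), class = "pg_parameter_error")

  # Monte-Carlo oracle from the definition of the noncentral F
  set.seed(73)
  r2 <- 0.02
  lam <- r2 / (1 - r2) * 977
  draws <- 2e5
  fstat <- (rnorm(draws, sqrt(lam))^2) / (rchisq(draws, 977) / 977)
  fcrit <- qf(1 - 5e-7, 1, 977)
  mc <- mean(fstat > fcrit)
  se <- sqrt(mc * (1 - mc) / draws)
  expect_lt(abs(as.numeric(power_ncf(r2, 1, 977, 5e-7)) - mc), 3 * se)
})
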