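toy_gm <- function() {
  # 12 samples x 40 SNPs; sample 1 misses half its genotypes (call rate
  # 0.5); SNP "mono" is monomorphic; SNP "gap" is missing for 2 of the 11
  # retained samples (18% > 2%) without pushing any sample below 0.97
  set.seed(42)
  codes <- matrix(rbinom(12 * 40, 2, 0.3), nrow = 12)
  codes[1, 1:20] <- NA
  codes[, 3] <- 0                       # monomorphic
  codes[2:3, 4] <- NA                   # missing among retained samples
  meta <- data.frame(chrom = "1", pos = 100 * (1:40),
                     id = c("s1", "s2", "mono", "gap",
                            sprintf("s%02d", 5:40)),
                     a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  genotype_matrix(codes, meta, sprintf("i%02d", 1:12))
}

test_that("QC applies sample, missingness and MAF filters in order", {
  gm <- toy_gm()
  out <- run_qc(gm)
  rep <- out$report
  expect_equal(rep$excluded_samples$sample_id, "i01")
  expect_true("gap" %in% rep$excluded_snps$missingness)
  expect_true("mono" %in% rep$excluded_snps$maf)

  # brute-force enumeration of the expected survivors
  kept_codes <- gm$codes[-1, , drop = FALSE]
  miss <- colMeans(is.na(kept_codes))
  f <- colMeans(kept_codes, na.rm = TRUE) / 2
  expect_keep <- miss <= 0.02 & pmin(f, 1 - f) >= 0.01
  expect_equal(sort(out$genotypes$snp_meta$id),
               sort(gm$snp_meta$id[expect_keep]))
  expect_equal(nrow(out$genotypes$codes), 11)
  expect_true(all(rep$snp_table$maf >= 0.01))

  # QC is idempotent
  again <- run_qc(out$genotypes)
  expect_identical(out$genotypes$codes, again$genotypes$codes)
  expect_equal(nrow(again$report$excluded_samples), 0)
})

test_that("QC enforces minor-allele orientation", {
  set.seed(7)
  codes <- matrix(rbinom(200, 2, 0.8), nrow = 20)   # allele 1 is major
  meta <- data.frame(chrom = "1", pos = 1:10 * 100,
                     id = sprintf("v%d", 1:10), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  gm <- run_qc(genotype_matrix(codes, meta, sprintf("i%02d", 1:20)))$genotypes
  f <- colMeans(gm$codes) / 2
  expect_true(all(f <= 0.5))
  expect_true(all(gm$snp_meta$a1[f < 0.5] == "G"))
})

test_that("HWE exact test matches its closed cases and the enumeration oracle", {
  expect_equal(hwe_exact_test(0, 0, 50), 1)        # monomorphic
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)      # total het deficit
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  # oracle agreement across a grid of triples
  set.seed(3)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    aa <- sample(0:n, 1)
    ab <- sample(0:(n - aa), 1)
    bb <- n - aa - ab
    expect_equal(hwe_exact_test(aa, ab, bb), hwe_oracle(aa, ab, bb),
                 tolerance = 1e-10)
  }
  expect_error(hwe_exact_test(0, 0, 0), class = "pg_parameter_error")
  expect_error(hwe_exact_test(-1, 2, 3), class = "pg_parameter_error")
})

test_that("HWE filtering is off by default but available", {
  set.seed(11)
  codes <- matrix(rbinom(600, 2, 0.5), nrow = 60)
  codes[, 1] <- rep(c(0, 2), 30)                   # gross het deficit
  meta <- data.frame(chrom = "1", pos = 1:10 * 50,
                     id = sprintf("v%d", 1:10), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(codes, meta, sprintf("i%02d", 1:60))
  kept_default <- run_qc(gm)$genotypes
  expect_true("v1" %in% kept_default$snp_meta$id)
  kept_strict <- run_qc(gm, hwe_p = 1e-4)$genotypes
  expect_false("v1" %in% kept_strict$snp_meta$id)
})

test_that("ancestry outliers and duplicate samples are screened out", {
  sim <- simulate_cohort(sim_cohort_config(
    n_individuals = 80, n_snps = 400, causal_snp = NULL, seed = 91
  ))
  gm <- sim$genotypes
  # make sample 1 an exact duplicate of sample 2
  gm$codes[1, ] <- gm$codes[2, ]
  rel <- exclude_related(gm, threshold = 0.95)
  expect_true(any(c("ind0001", "ind0002") %in% rel$excluded))
  expect_equal(nrow(rel$genotypes$codes), 79)
  expect_true(all(rel$pairs$similarity > 0.95))

  # an extreme-ancestry sample: shift its genotypes far from the cohort
  gm2 <- sim$genotypes
  gm2$codes[1, ] <- ifelse(colMeans(gm2$codes[-1, ]) / 2 < 0.5, 2, 0)
  out <- exclude_pc_outliers(gm2, k = 3, sd_mult = 6)
  expect_true("ind0001" %in% out$excluded)
})
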