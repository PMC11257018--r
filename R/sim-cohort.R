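#' Configure the genotype/phenotype cohort simulator
#'
#' Describes a cohort of unrelated diploid individuals genotyped at
#' independent SNPs drawn under Hardy-Weinberg equilibrium, optionally with
#' population-cluster structure (a Balding-Nichols-style dispersal of
#' cluster allele frequencies) and one additive causal SNP.
#'
#' The simulated quantitative phenotype is built on a standardized scale:
#'
#' `y = beta * (g - 2p) + s * (sex - 1/2)/(1/2) + e`
#'
#' where `g` is the causal minor-allele count, `p` its allele frequency,
#' `beta` the per-allele effect in phenotype SD units, `s` the sex-effect SD
#' and `e` Gaussian residual noise whose variance is chosen so that the total
#' phenotype variance is 1.  The variance explained by the causal SNP is
#' therefore `beta^2 * 2p(1-p)`.
#'
#' @param n_individuals cohort size.
#' @param n_snps number of SNPs (the causal SNP, if any, is one of them).
#' @param maf_range length-2 range in (0, 0.5] from which per-SNP ancestral
#'   minor-allele frequencies are drawn uniformly.
#' @param causal_snp `NULL` for a fully null cohort, or a list with elements
#'   `maf` and `beta_sd_per_allele` (standardized per-allele effect).
#' @param sex_effect_sd SD of the sex component of the phenotype.
#' @param n_clusters number of population clusters (equal sizes).
#' @param cluster_divergence Fst-like dispersal of cluster allele
#'   frequencies around the ancestral frequency (0 = homogeneous cohort).
#' @param missing_rate genotype missingness, applied completely at random.
#' @param seed integer seed.
#'
#' @return An object of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_individuals = 980L, n_snps = 1000L,
                              maf_range = c(0.05, 0.5),
                              causal_snp = list(maf = 0.49,
                                                beta_sd_per_allele = 0.29),
                              sex_effect_sd = 0.2,
                              n_clusters = 1L, cluster_divergence = 0,
                              missing_rate = 0, seed = 1L) {
  assert_scalar_num(n_individuals, "n_individuals", 1)
  assert_scalar_num(n_snps, "n_snps", 1)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L]) {
    stop_pg("`maf_range` must lie in (0, 0.5]", "pg_parameter_error")
  }
  if (!is.null(causal_snp)) {
    if (!is.list(causal_snp) ||
        !all(c("maf", "beta_sd_per_allele") %in% names(causal_snp))) {
      stop_pg("`causal_snp` needs elements maf and beta_sd_per_allele",
              "pg_parameter_error")
    }
    if (causal_snp$maf <= 0 || causal_snp$maf > 0.5) {
      stop_pg("causal maf must lie in (0, 0.5]", "pg_parameter_error")
    }
  }
  assert_scalar_num(sex_effect_sd, "sex_effect_sd", 0)
  assert_scalar_num(n_clusters, "n_clusters", 1)
  assert_scalar_num(cluster_divergence, "cluster_divergence", 0)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop_pg("`missing_rate` must lie in [0, 1)", "pg_parameter_error")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_snps = as.integer(n_snps), maf_range = maf_range,
         causal_snp = causal_snp, sex_effect_sd = sex_effect_sd,
         n_clusters = as.integer(n_clusters),
         cluster_divergence = cluster_divergence,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_cohort_config"
  )
}

#' Simulate a genotype/phenotype cohort with known ground truth
#'
#' Draws genotypes under within-cluster Hardy-Weinberg equilibrium, builds a
#' unit-variance quantitative phenotype from the configured causal SNP, sex
#' effect and Gaussian residual, and applies completely-at-random genotype
#' missingness.  Identical seeds reproduce identical cohorts.
#'
#' @param config a [sim_cohort_config()].
#'
#' @return A list with `genotypes` (a [genotype_matrix()]), `phenotypes`
#'   (data frame `sample_id`, `phenotype`, `sex` with female = 1) and
#'   `truth` (causal SNP id/index, true per-allele beta, per-individual
#'   genotype at the causal SNP, phenotype components, cluster assignment
#'   and allele-frequency draws).
#' @export
simulate_cohort <- function(config = sim_cohort_config()) {
  if (!inherits(config, "sim_cohort_config")) {
    stop_pg("`config` must be a sim_cohort_config", "pg_parameter_error")
  }
  n <- config$n_individuals
  m <- config$n_snps
  with_seed(config$seed, {
    cluster_id <- rep_len(seq_len(config$n_clusters), n)
    p_anc <- stats::runif(m, config$maf_range[1L], config$maf_range[2L])
    causal_index <- NA_integer_
    beta <- 0
    if (!is.null(config$causal_snp)) {
      causal_index <- sample.int(m, 1L)
      p_anc[causal_index] <- config$causal_snp$maf
      beta <- config$causal_snp$beta_sd_per_allele
    }

    # Balding-Nichols dispersal of cluster allele frequencies; the causal
    # SNP keeps its ancestral frequency in every cluster so that its effect
    # size is exactly the configured one.
    f <- config$cluster_divergence
    if (f > 0 && config$n_clusters > 1L) {
      pc <- sapply(seq_len(m), function(j) {
        stats::rbeta(config$n_clusters,
                     p_anc[j] * (1 - f) / f,
                     (1 - p_anc[j]) * (1 - f) / f)
      })
      if (!is.na(causal_index)) {
        pc[, causal_index] <- p_anc[causal_index]
      }
    } else {
      pc <- matrix(rep(p_anc, each = config$n_clusters),
                   nrow = config$n_clusters)
    }

    prob <- pc[cluster_id, , drop = FALSE]          # n x m HWE frequencies
    codes <- matrix(stats::rbinom(n * m, 2L, prob), nrow = n)

    sex <- stats::rbinom(n, 1L, 0.5)                # female = 1
    p_c <- if (is.na(causal_index)) 0.5 else p_anc[causal_index]
    g_causal <- if (is.na(causal_index)) rep(0, n) else codes[, causal_index]
    genetic <- beta * (g_causal - 2 * p_c)
    sex_comp <- config$sex_effect_sd * (sex - 0.5) / 0.5
    var_resid <- 1 - beta^2 * 2 * p_c * (1 - p_c) - config$sex_effect_sd^2
    if (var_resid <= 0) {
      stop_pg("causal and sex effects exceed unit phenotype variance",
              "pg_parameter_error")
    }
    resid <- stats::rnorm(n, 0, sqrt(var_resid))
    phenotype <- genetic + sex_comp + resid

    if (config$missing_rate > 0) {
      miss <- stats::runif(n * m) < config$missing_rate
      codes[miss] <- NA
    }

    ids <- sprintf("ind%04d", seq_len(n))
    snp_ids <- sprintf("snp%05d", seq_len(m))
    meta <- data.frame(
      chrom = "1", pos = 10000L + 5000L * (seq_len(m) - 1L),
      id = snp_ids, a1 = "A", a2 = "G", stringsAsFactors = FALSE
    )
    gm <- genotype_matrix(codes, meta, ids)

    list(
      genotypes = gm,
      phenotypes = data.frame(sample_id = ids, phenotype = phenotype,
                              sex = sex, stringsAsFactors = FALSE),
      truth = list(
        causal_index = causal_index,
        causal_id = if (is.na(causal_index)) NA_character_ else
          snp_ids[causal_index],
        beta_sd_per_allele = beta,
        genotype_of_causal = g_causal,
        phenotype_components = data.frame(
          sample_id = ids, genetic = genetic, covariate = sex_comp,
          residual = resid, stringsAsFactors = FALSE
        ),
        cluster_id = cluster_id,
        p_ancestral = p_anc,
        seed = config$seed
      )
    )
  })
}

#' Simulate an LD block embedded in a null genome
#'
#' Generates a cohort in which a contiguous block of SNPs is in mutual
#' linkage disequilibrium (via a Gaussian-copula haplotype model with AR(1)
#' latent correlation) around a causal SNP at the block's center, flanked by
#' independent null SNPs.  Used to exercise LD-based clumping against a
#' known causal position.
#'
#' @param n number of individuals.
#' @param n_block number of SNPs in the LD block.
#' @param rho latent AR(1) correlation between adjacent block haplotypes.
#' @param block_maf allele frequency of the block SNPs.
#' @param n_null number of independent flanking SNPs.
#' @param beta per-allele effect of the causal (central block) SNP on the
#'   standardized phenotype.
#' @param seed integer seed.
#'
#' @return A list with `genotypes`, `phenotypes` and `truth` (causal id,
#'   index and position) in the same shape as [simulate_cohort()].
#' @export
simulate_ld_block <- function(n = 400L, n_block = 10L, rho = 0.9,
                              block_maf = 0.3, n_null = 500L,
                              beta = 0.55, seed = 1L) {
  stopifnot(n_block >= 1L, n_null >= 0L, rho >= 0, rho < 1)
  with_seed(seed, {
    m <- n_block + n_null
    # haplotypes for the block: latent AR(1) Gaussians thresholded at the
    # allele-frequency quantile; genotype = sum of two haplotypes
    thresh <- stats::qnorm(block_maf)
    hap <- function() {
      z <- matrix(0, n, n_block)
      z[, 1L] <- stats::rnorm(n)
      if (n_block > 1L) {
        for (j in 2L:n_block) {
          z[, j] <- rho * z[, j - 1L] +
            sqrt(1 - rho^2) * stats::rnorm(n)
        }
      }
      (z < thresh) + 0
    }
    g_block <- hap() + hap()
    g_null <- matrix(
      stats::rbinom(n * n_null, 2L,
                    rep(stats::runif(n_null, 0.1, 0.5), each = n)),
      nrow = n
    )

    # interleave: null SNPs flank the block, block in the middle
    half <- n_null %/% 2L
    right <- if (n_null > half) {
      g_null[, (half + 1L):n_null, drop = FALSE]
    } else {
      matrix(0, n, 0L)
    }
    codes <- cbind(g_null[, seq_len(half), drop = FALSE], g_block, right)
    causal_index <- half + (n_block + 1L) %/% 2L

    # null SNPs every 100 kb; block SNPs 10 kb apart
    pos_left <- 100000L * seq_len(half)
    block_start <- if (half > 0L) pos_left[half] + 100000L else 100000L
    pos_block <- block_start + 10000L * (seq_len(n_block) - 1L)
    pos_right <- pos_block[n_block] + 100000L * seq_len(n_null - half)
    pos <- c(pos_left, pos_block, pos_right)
    snp_ids <- sprintf("snp%05d", seq_len(m))
    meta <- data.frame(chrom = "1", pos = pos, id = snp_ids,
                       a1 = "A", a2 = "G", stringsAsFactors = FALSE)
    ids <- sprintf("ind%04d", seq_len(n))
    gm <- genotype_matrix(codes, meta, ids)

    g_c <- codes[, causal_index]
    p_c <- mean(g_c) / 2
    var_g <- beta^2 * 2 * p_c * (1 - p_c)
    resid_sd <- sqrt(max(1 - var_g, 0.1))
    y <- beta * (g_c - 2 * p_c) + stats::rnorm(n, 0, resid_sd)
    list(
      genotypes = gm,
      phenotypes = data.frame(sample_id = ids, phenotype = y,
                              sex = stats::rbinom(n, 1L, 0.5),
                              stringsAsFactors = FALSE),
      truth = list(causal_index = causal_index,
                   causal_id = snp_ids[causal_index],
                   causal_pos = pos[causal_index],
                   block_ids = snp_ids[(half + 1L):(half + n_block)])
    )
  })
}
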