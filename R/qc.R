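#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test by enumeration of all heterozygote counts
#' compatible with the observed allele counts: the p-value is the total
#' conditional probability of configurations no more probable than the
#' observed one (mid-p off by default).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (`A` minor).
#' @param midp use the mid-p variant (halves the probability of the
#'   observed configuration).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_pg("genotype counts must be nonnegative integers",
            "pg_parameter_error")
  }
  n <- sum(counts)
  if (n == 0L) {
    stop_pg("all genotype counts are zero", "pg_parameter_error")
  }
  n1 <- 2 * n_AA + n_Aa                  # copies of allele A
  n2 <- 2 * n_aa + n_Aa
  rare <- min(n1, n2)
  if (rare == 0) return(1)               # monomorphic: single configuration

  # heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2, rare, by = 2)
  # conditional probability of each heterozygote count given allele counts:
  # genotype counts implied by h hets are (rare-h)/2 rare homozygotes and
  # n - h - (rare-h)/2 common homozygotes
  hom_rare <- (rare - het) / 2
  hom_common <- n - het - hom_rare
  logp <- lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(het + 1) -
    lgamma(hom_common + 1) + het * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- min(n_Aa, rare)                 # observed het count
  p_obs <- p[match(obs, het)]
  if (is.na(p_obs)) {
    stop_pg("genotype counts inconsistent", "pg_parameter_error")
  }
  tail <- sum(p[p <= p_obs * (1 + 1e-12)])
  if (midp) tail <- tail - 0.5 * p_obs
  min(1, tail)
}

#' Genotype and sample quality control
#'
#' Applies the standard marker/sample filters in a fixed order: (1) drop
#' samples whose genotyping call rate is below `sample_call_rate`; (2) drop
#' SNPs whose missing fraction among the retained samples exceeds
#' `snp_missing`; (3) drop SNPs whose minor allele frequency (computed after
#' the sample exclusions) is below `maf`.  Codes are then re-oriented so
#' that allele 1 is the minor allele.  Hardy-Weinberg p-values are computed
#' and reported for every surviving SNP; HWE is an exclusion criterion only
#' if `hwe_p` is set (off by default, as HWE is conventionally inspected as
#' post-association QC).
#'
#' @param gm a [genotype_matrix()].
#' @param sample_call_rate minimum per-sample call rate (default 0.97).
#' @param snp_missing maximum per-SNP missing fraction (default 0.02).
#' @param maf minimum minor allele frequency (default 0.01).
#' @param hwe_p optional HWE exact-test exclusion threshold.
#'
#' @return List with `genotypes` (filtered, minor-oriented
#'   `genotype_matrix`) and `report` (a `qc_report`: excluded samples with
#'   reasons, per-filter SNP exclusion counts, and the per-SNP `maf`,
#'   `missing_rate` and `hwe_p` table for survivors).
#' @export
run_qc <- function(gm, sample_call_rate = 0.97, snp_missing = 0.02,
                   maf = 0.01, hwe_p = NULL) {
  if (!inherits(gm, "genotype_matrix")) {
    stop_pg("`gm` must be a genotype_matrix", "pg_parameter_error")
  }
  call_rate <- rowMeans(!is.na(gm$codes))
  bad_samples <- which(call_rate < sample_call_rate)
  excluded_samples <- data.frame(
    sample_id = gm$sample_ids[bad_samples],
    reason = rep("call_rate", length(bad_samples)),
    call_rate = call_rate[bad_samples],
    stringsAsFactors = FALSE
  )
  if (length(bad_samples) > 0L) {
    gm <- subset_gm(gm, samples = -bad_samples)
  }
  if (nrow(gm$codes) == 0L) {
    stop_pg("no samples left after QC", "pg_qc_error")
  }

  miss <- colMeans(is.na(gm$codes))
  drop_missing <- miss > snp_missing
  f <- colMeans(gm$codes, na.rm = TRUE) / 2
  snp_maf <- pmin(f, 1 - f)
  snp_maf[is.nan(snp_maf)] <- 0
  drop_maf <- !drop_missing & snp_maf < maf

  keep <- !(drop_missing | drop_maf)
  excluded_snps <- list(
    missingness = gm$snp_meta$id[drop_missing],
    maf = gm$snp_meta$id[drop_maf]
  )
  gm <- subset_gm(gm, snps = which(keep))
  if (ncol(gm$codes) == 0L) {
    stop_pg("no SNPs left after QC", "pg_qc_error")
  }
  gm <- orient_minor(gm)

  counts_AA <- colSums(gm$codes == 2, na.rm = TRUE)
  counts_Aa <- colSums(gm$codes == 1, na.rm = TRUE)
  counts_aa <- colSums(gm$codes == 0, na.rm = TRUE)
  hwe <- vapply(seq_len(ncol(gm$codes)), function(j) {
    hwe_exact_test(counts_AA[j], counts_Aa[j], counts_aa[j])
  }, numeric(1))

  if (!is.null(hwe_p)) {
    fail <- hwe < hwe_p
    excluded_snps$hwe <- gm$snp_meta$id[fail]
    gm <- subset_gm(gm, snps = which(!fail))
    hwe <- hwe[!fail]
    if (ncol(gm$codes) == 0L) {
      stop_pg("no SNPs left after QC", "pg_qc_error")
    }
  }

  fq <- snp_freq(gm)
  fq$hwe_p <- hwe
  report <- structure(
    list(
      excluded_samples = excluded_samples,
      excluded_snps = excluded_snps,
      n_excluded_snps = vapply(excluded_snps, length, integer(1)),
      snp_table = fq,
      thresholds = list(sample_call_rate = sample_call_rate,
                        snp_missing = snp_missing, maf = maf,
                        hwe_p = hwe_p)
    ),
    class = "qc_report"
  )
  list(genotypes = gm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d samples excluded; SNPs dropped: %s\n",
              nrow(x$excluded_samples),
              paste(sprintf("%s=%d", names(x$n_excluded_snps),
                            x$n_excluded_snps), collapse = ", ")))
  invisible(x)
}

#' Exclude population outliers by principal-component score
#'
#' Flags samples whose score on any of the top genotype principal
#' components lies more than `sd_mult` standard deviations from the
#' component mean (the screen used to drop ancestry outliers before
#' association).
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param k number of components to screen.
#' @param sd_mult outlier cut in SD units (default 6).
#' @return List with `genotypes` (outliers removed) and `excluded`
#'   (sample ids).
#' @export
exclude_pc_outliers <- function(gm, k = 3L, sd_mult = 6) {
  pcs <- genotype_pca(gm, k = k)
  scores <- as.matrix(pcs[, -1L, drop = FALSE])
  z <- scale(scores)
  out <- which(apply(abs(z) > sd_mult, 1L, any))
  list(
    genotypes = if (length(out) > 0L) subset_gm(gm, samples = -out) else gm,
    excluded = gm$sample_ids[out]
  )
}

#' Exclude duplicate or related samples by IBS similarity
#'
#' For every pair with identity-by-state similarity (`1 - IBS distance`)
#' above `threshold`, one member is dropped: the sample with the lower
#' genotyping call rate, ties broken by sample order.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param threshold IBS similarity above which a pair is treated as
#'   duplicate/related (default 0.95).
#' @return List with `genotypes`, `excluded` (sample ids) and `pairs`
#'   (the offending pairs with their similarity).
#' @export
exclude_related <- function(gm, threshold = 0.95) {
  sim <- 1 - as.matrix(ibs_distance(gm))
  diag(sim) <- 0
  call_rate <- rowMeans(!is.na(gm$codes))
  hits <- which(sim > threshold, arr.ind = TRUE)
  hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
  pairs <- data.frame(
    sample_1 = gm$sample_ids[hits[, 1L]],
    sample_2 = gm$sample_ids[hits[, 2L]],
    similarity = sim[hits],
    stringsAsFactors = FALSE
  )
  drop <- integer(0)
  for (i in seq_len(nrow(hits))) {
    a <- hits[i, 1L]
    b <- hits[i, 2L]
    if (a %in% drop || b %in% drop) next
    drop <- c(drop, if (call_rate[b] <= call_rate[a]) b else a)
  }
  list(
    genotypes = if (length(drop) > 0L) subset_gm(gm, samples = -drop) else gm,
    excluded = gm$sample_ids[drop],
    pairs = pairs
  )
}
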