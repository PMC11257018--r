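#' Pairwise identity-by-state distance
#'
#' Distance between two individuals is `1 - mean(IBS share)/2`, where the
#' IBS share at a SNP is `2 - |g_i - g_j|` (0, 1 or 2 shared alleles) and
#' the mean runs over SNPs where both genotypes are non-missing.
#'
#' @param gm a [genotype_matrix()].
#' @return A `dist` object over samples.
#' @export
ibs_distance <- function(gm) {
  Z <- gm$codes
  Zi <- Z
  Zi[is.na(Zi)] <- -1
  A0 <- (Zi == 0) + 0
  A1 <- (Zi == 1) + 0
  A2 <- (Zi == 2) + 0
  M <- A0 + A1 + A2                       # non-missing indicator
  shared <- tcrossprod(M)                 # SNPs with both non-missing
  P1 <- tcrossprod(A1, A0 + A2)           # |gi-gj| = 1 contributions
  P2 <- tcrossprod(A0, A2)                # |gi-gj| = 2 contributions
  sumabs <- P1 + t(P1) + 2 * (P2 + t(P2))
  d <- sumabs / (2 * shared)
  d[shared == 0] <- NA
  rownames(d) <- colnames(d) <- gm$sample_ids
  stats::as.dist(d)
}

#' Cluster samples by identity-by-state similarity
#'
#' Complete-linkage agglomerative clustering on the pairwise IBS distance,
#' cut to a fixed number of clusters.  This reproduces the population
#' grouping used to constrain phenotype permutations.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param n_clusters number of clusters to cut the tree at.
#' @return List of class `cluster_assignment` with `cluster_id` (named
#'   integer vector), `n_clusters` and the `hclust` tree.
#' @export
ibs_cluster <- function(gm, n_clusters) {
  n <- nrow(gm$codes)
  if (n_clusters < 1L || n_clusters > n) {
    stop_pg("`n_clusters` must lie in [1, n]", "pg_parameter_error")
  }
  d <- ibs_distance(gm)
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, k = n_clusters)
  structure(
    list(cluster_id = cl, n_clusters = as.integer(n_clusters), tree = hc),
    class = "cluster_assignment"
  )
}

#' Max-T permutation correction with within-cluster shuffling
#'
#' Familywise-corrected per-SNP p-values: phenotype (together with its
#' covariate row) is permuted within each population cluster; for each
#' permutation the genome-wide minimum association p-value is recorded, and
#' the corrected p-value of a SNP is the add-one estimate of the
#' probability that this permutation minimum is at least as small as the
#' SNP's observed p-value:
#' `corrected_p = (1 + #\{perm: min-p <= p_obs\}) / (n_perm + 1)`.
#'
#' The per-permutation regression is an exact OLS refit of the full model
#' (genotype + covariates + intercept) at every SNP, computed via a
#' projection identity so that only two small matrix products are needed
#' per permutation.  Missing genotypes are mean-imputed per SNP for both
#' the observed and the permuted scans so that observed and null statistics
#' are computed identically.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param phenotype phenotype vector or keyed data frame (see
#'   [run_gwas()]).
#' @param covars optional covariates, permuted as a unit with the
#'   phenotype.
#' @param clusters a [ibs_cluster()] result, a bare vector of cluster
#'   labels, or `NULL` for unrestricted permutation.
#' @param n_perm number of permutations (the protocol used 10,000).
#' @param seed integer seed for the permutation stream.
#'
#' @return List of class `permutation_result`: `table` (data frame `id`,
#'   `p` observed, `corrected_p`), `min_p_perm` (the permutation minima),
#'   `observed_min_id`, `n_perm`, `seed`.
#' @export
maxT_permutation <- function(gm, phenotype, covars = NULL, clusters = NULL,
                             n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) {
    stop_pg("`n_perm` must be >= 1", "pg_parameter_error")
  }
  y <- align_phenotype(gm, phenotype)
  C <- align_covars(gm, covars)
  cl <- if (is.null(clusters)) {
    rep(1L, length(y))
  } else if (inherits(clusters, "cluster_assignment")) {
    clusters$cluster_id
  } else {
    as.integer(factor(clusters))
  }
  ok <- !is.na(y)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  G <- gm$codes[ok, , drop = FALSE]
  y <- y[ok]
  cl <- cl[ok]
  if (!is.null(C)) C <- C[ok, , drop = FALSE]

  # mean-impute missing genotypes per SNP
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2L]]
  }

  n <- length(y)
  Q <- qr.Q(qr(cbind(rep(1, n), C)))
  k <- ncol(Q)
  yr <- as.numeric(y - Q %*% crossprod(Q, y))
  yy <- sum(yr^2)
  gg0 <- colSums(G^2)
  df <- n - k - 1L

  # exact per-permutation OLS: permuting (phenotype, covariates) jointly
  # against fixed genotypes; Q keeps orthonormal columns under row
  # permutation, and the residualized phenotype permutes with it.
  perm_stats <- function(ix) {
    yp <- yr[ix]
    B <- crossprod(Q[ix, , drop = FALSE], G)
    gg <- gg0 - colSums(B^2)
    num <- as.numeric(crossprod(G, yp))
    ok_g <- gg0 > 0 & gg > gg0 * 1e-10
    t2 <- rep(NA_real_, ncol(G))
    rss <- pmax(yy - num[ok_g]^2 / gg[ok_g], 1e-300)
    t2[ok_g] <- num[ok_g]^2 * df / (gg[ok_g] * rss)
    pmax(2 * stats::pt(-sqrt(t2), df), 1e-300)
  }

  cluster_perm <- function() {
    ix <- seq_len(n)
    for (g in unique(cl)) {
      w <- which(cl == g)
      if (length(w) > 1L) ix[w] <- w[sample.int(length(w))]
    }
    ix
  }

  p_obs <- perm_stats(seq_len(n))
  min_p <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      min(perm_stats(cluster_perm()), na.rm = TRUE)
    }, numeric(1))
  })

  sorted_min <- sort(min_p)
  counts <- findInterval(p_obs, sorted_min)   # #\{min_p <= p_obs\}
  corrected <- (1 + counts) / (n_perm + 1)
  tab <- data.frame(id = gm$snp_meta$id, p = p_obs,
                    corrected_p = corrected, stringsAsFactors = FALSE)
  structure(
    list(table = tab,
         min_p_perm = min_p,
         observed_min_id = gm$snp_meta$id[which.min(p_obs)],
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "permutation_result"
  )
}

#' Permutation test for a sex (group) difference in effect size
#'
#' Tests whether the per-allele effect of one SNP differs between two
#' groups (e.g. females and males): the observed statistic is the absolute
#' difference of the group-specific additive regression betas; its null
#' distribution is generated by randomly re-splitting the cohort into
#' groups of the same two sizes.
#'
#' @param gm a [genotype_matrix()].
#' @param phenotype phenotype vector or keyed data frame.
#' @param covars optional covariates used inside each group's regression
#'   (do not include the grouping variable itself).
#' @param group logical or 0/1 vector defining the observed split.
#' @param snp_id id of the SNP to test.
#' @param n_perm number of random splits (>= 1).
#' @param seed integer seed.
#'
#' @return List with `p` (add-one permutation p-value), `observed_diff`,
#'   the two group betas, `n_perm` and the number of redrawn splits
#'   (splits where the SNP was monomorphic within a group).
#' @export
sex_effect_permutation <- function(gm, phenotype, covars = NULL, group,
                                   snp_id, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) {
    stop_pg("`n_perm` must be >= 1", "pg_parameter_error")
  }
  j <- match(snp_id, gm$snp_meta$id)
  if (is.na(j)) {
    stop_pg("unknown `snp_id`", "pg_parameter_error")
  }
  y <- align_phenotype(gm, phenotype)
  C <- align_covars(gm, covars)
  g <- gm$codes[, j]
  grp <- as.logical(group)
  ok <- !is.na(y) & !is.na(g) & !is.na(grp)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  y <- y[ok]; g <- g[ok]; grp <- grp[ok]
  if (!is.null(C)) C <- C[ok, , drop = FALSE]
  n <- length(y)
  n1 <- sum(grp)
  if (n1 == 0L || n1 == n) {
    stop_pg("both groups must be non-empty", "pg_parameter_error")
  }

  beta_diff <- function(sel) {
    bA <- fit_additive(g[sel], y[sel],
                       if (!is.null(C)) C[sel, , drop = FALSE])$beta
    bB <- fit_additive(g[!sel], y[!sel],
                       if (!is.null(C)) C[!sel, , drop = FALSE])$beta
    abs(bA - bB)
  }
  observed <- beta_diff(grp)
  bA <- fit_additive(g[grp], y[grp],
                     if (!is.null(C)) C[grp, , drop = FALSE])$beta
  bB <- fit_additive(g[!grp], y[!grp],
                     if (!is.null(C)) C[!grp, , drop = FALSE])$beta

  redraws <- 0L
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      repeat {
        sel <- logical(n)
        sel[sample.int(n, n1)] <- TRUE
        st <- tryCatch(beta_diff(sel),
                       pursuitgwas_error = function(e) NULL)
        if (!is.null(st)) return(st)
        redraws <<- redraws + 1L
        if (redraws > 100L * n_perm) {
          stop_pg("too many degenerate splits", "pg_permutation_error")
        }
      }
    }, numeric(1))
  })
  list(
    p = (1 + sum(null_stats >= observed)) / (n_perm + 1),
    observed_diff = observed,
    beta_group1 = bA, beta_group2 = bB,
    group_sizes = c(n1, n - n1),
    n_perm = as.integer(n_perm), redraws = redraws, seed = as.integer(seed)
  )
}
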