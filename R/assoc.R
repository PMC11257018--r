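#' Principal components of genetic variation
#'
#' Computes sample scores on the top-k axes of genotype variation for use
#' as stratification covariates.  Missing codes are mean-imputed per SNP
#' for the decomposition only; each SNP is centered at `2*p_hat` and scaled
#' by `sqrt(2*p_hat*(1-p_hat))` (the HWE standard deviation of the allele
#' count).  The sign of each component is fixed by making its
#' largest-magnitude SNP loading positive.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param k number of components (default 3).
#'
#' @return Data frame with `sample_id` and columns `pc1..pck`; eigenvalues
#'   of the decomposition are attached as attribute `eigenvalues`.
#' @export
genotype_pca <- function(gm, k = 3L) {
  if (!inherits(gm, "genotype_matrix")) {
    stop_pg("`gm` must be a genotype_matrix", "pg_parameter_error")
  }
  X <- gm$codes
  n <- nrow(X)
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  keep <- which(p_hat > 0 & p_hat < 1)
  X <- X[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  if (k >= min(n, length(keep))) {
    stop_pg("k must be smaller than the matrix rank", "pg_parameter_error")
  }
  center <- 2 * p_hat
  scale <- sqrt(2 * p_hat * (1 - p_hat))
  X <- sweep(X, 2L, center)
  X <- sweep(X, 2L, scale, "/")
  X[is.na(X)] <- 0                        # mean imputation after centering

  # eigen-decompose the smaller Gram matrix
  if (ncol(X) >= n) {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    if (any(d <= sqrt(.Machine$double.eps) * max(d))) {
      stop_pg("k exceeds numerical rank", "pg_parameter_error")
    }
    U <- e$vectors[, seq_len(k), drop = FALSE]
    V <- crossprod(X, U) %*% diag(1 / d, k)
  } else {
    e <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    if (any(d <= sqrt(.Machine$double.eps) * max(d))) {
      stop_pg("k exceeds numerical rank", "pg_parameter_error")
    }
    V <- e$vectors[, seq_len(k), drop = FALSE]
    U <- X %*% V %*% diag(1 / d, k)
  }
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(d, k)
  out <- data.frame(sample_id = gm$sample_ids, scores,
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("pc", seq_len(k)))
  attr(out, "eigenvalues") <- e$values
  out
}

#' Additive single-SNP association fit
#'
#' Ordinary least squares of the phenotype on the minor-allele count plus
#' covariates plus an intercept; the additive genetic model.  Samples with
#' a missing genotype, phenotype or covariate are dropped for this SNP
#' only (complete-case analysis).
#'
#' @param genotype numeric 0/1/2/`NA` vector.
#' @param phenotype numeric vector.
#' @param covars optional data frame or matrix of covariates.
#'
#' @return List with `beta` (phenotype units per minor allele), `se`, `t`,
#'   `p` (two-sided, from the t distribution with `n_used - n_params` df),
#'   `n_used` and `df`.
#' @export
fit_additive <- function(genotype, phenotype, covars = NULL) {
  C <- if (is.null(covars)) NULL else as.matrix(covars)
  ok <- !is.na(genotype) & !is.na(phenotype)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  g <- genotype[ok]
  y <- phenotype[ok]
  X <- cbind(`(Intercept)` = 1, g = g,
             if (!is.null(C)) C[ok, , drop = FALSE])
  n_par <- ncol(X)
  if (length(y) < n_par + 1L) {
    stop_pg("too few complete cases", "pg_fit_error")
  }
  if (stats::var(g) == 0) {
    stop_pg("monomorphic genotype", "pg_monomorphic_error")
  }
  qr_x <- qr(X)
  if (qr_x$rank < n_par) {
    stop_pg("collinear design", "pg_fit_error")
  }
  coef <- qr.coef(qr_x, y)
  res <- y - X %*% coef
  df <- length(y) - n_par
  sigma2 <- sum(res^2) / df
  XtX_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtX_inv[2L, 2L])
  tval <- coef[["g"]] / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(beta = coef[["g"]], se = se, t = tval,
       p = max(p, 1e-300), n_used = length(y), df = df)
}

# Vectorized complete-data association statistics via the
# Frisch-Waugh-Lovell projection: exact OLS t statistics for every SNP
# column of G against y given covariates C, assuming no missing values.
# Returns a list of vectors (beta, se, t, p) plus the df.
gwas_stats_complete <- function(G, y, C = NULL) {
  n <- length(y)
  Q <- qr.Q(qr(cbind(rep(1, n), C)))
  k <- ncol(Q)
  yr <- y - Q %*% crossprod(Q, y)
  yy <- sum(yr^2)
  B <- crossprod(Q, G)                    # k x m
  gg0 <- colSums(G^2)
  gg <- gg0 - colSums(B^2)                # ||residualized g||^2
  num <- as.numeric(crossprod(G, yr))
  df <- n - k - 1L
  ok <- gg0 > 0 & gg > gg0 * 1e-10
  beta <- se <- tval <- p <- rep(NA_real_, ncol(G))
  beta[ok] <- num[ok] / gg[ok]
  rss <- pmax(yy - num[ok]^2 / gg[ok], 0)
  se[ok] <- sqrt((rss / df) / gg[ok])
  tval[ok] <- beta[ok] / se[ok]
  p[ok] <- pmax(2 * stats::pt(-abs(tval[ok]), df), 1e-300)
  list(beta = beta, se = se, t = tval, p = p, df = df, ok = ok)
}

#' Genome-wide additive association scan
#'
#' Runs [fit_additive()] for every SNP of a genotype matrix (a vectorized
#' exact-OLS path is used for SNPs without missing genotypes).  With
#' `rank_transform = TRUE` the phenotype is replaced by its average ranks
#' before regression, making the scan invariant to monotone phenotype
#' transforms.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param phenotype numeric vector aligned with `gm$sample_ids`, or a data
#'   frame with `sample_id` and `phenotype` columns.
#' @param covars optional covariate data frame aligned the same way
#'   (non-numeric columns and `sample_id` are dropped).
#' @param rank_transform regress on average ranks of the phenotype.
#'
#' @return A data frame of class `assoc_result`, sorted by p-value:
#'   `chrom, pos, id, a1, a2, maf, n_used, beta, se, t, p, hwe_p, status`.
#'   Per-SNP failures (monomorphic, collinear) are recorded in `status`
#'   and carry `NA` statistics.
#' @export
run_gwas <- function(gm, phenotype, covars = NULL, rank_transform = FALSE) {
  if (!inherits(gm, "genotype_matrix")) {
    stop_pg("`gm` must be a genotype_matrix", "pg_parameter_error")
  }
  y <- align_phenotype(gm, phenotype)
  C <- align_covars(gm, covars)
  ok_sample <- !is.na(y)
  if (!is.null(C)) ok_sample <- ok_sample & stats::complete.cases(C)
  G <- gm$codes[ok_sample, , drop = FALSE]
  y <- y[ok_sample]
  if (!is.null(C)) C <- C[ok_sample, , drop = FALSE]
  if (rank_transform) y <- rank(y, ties.method = "average")
  m <- ncol(G)

  beta <- se <- tval <- p <- rep(NA_real_, m)
  n_used <- integer(m)
  status <- rep("ok", m)

  has_na <- colSums(is.na(G)) > 0L
  if (any(!has_na)) {
    idx <- which(!has_na)
    st <- gwas_stats_complete(G[, idx, drop = FALSE], y, C)
    beta[idx] <- st$beta
    se[idx] <- st$se
    tval[idx] <- st$t
    p[idx] <- st$p
    n_used[idx] <- length(y)
    status[idx][!st$ok] <- "monomorphic"
  }
  for (j in which(has_na)) {
    fit <- tryCatch(fit_additive(G[, j], y, C),
                    pursuitgwas_error = function(e) e)
    if (inherits(fit, "error")) {
      status[j] <- if (inherits(fit, "pg_monomorphic_error")) {
        "monomorphic"
      } else "fit_error"
      n_used[j] <- sum(!is.na(G[, j]))
    } else {
      beta[j] <- fit$beta; se[j] <- fit$se
      tval[j] <- fit$t; p[j] <- fit$p
      n_used[j] <- fit$n_used
    }
  }

  counts_AA <- colSums(G == 2, na.rm = TRUE)
  counts_Aa <- colSums(G == 1, na.rm = TRUE)
  counts_aa <- colSums(G == 0, na.rm = TRUE)
  hwe <- vapply(seq_len(m), function(j) {
    if (counts_AA[j] + counts_Aa[j] + counts_aa[j] == 0L) return(NA_real_)
    hwe_exact_test(counts_AA[j], counts_Aa[j], counts_aa[j])
  }, numeric(1))
  f <- colMeans(G, na.rm = TRUE) / 2

  out <- data.frame(
    chrom = gm$snp_meta$chrom, pos = gm$snp_meta$pos, id = gm$snp_meta$id,
    a1 = gm$snp_meta$a1, a2 = gm$snp_meta$a2,
    maf = pmin(f, 1 - f), n_used = n_used,
    beta = beta, se = se, t = tval, p = p, hwe_p = hwe,
    status = status, stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$id, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}

# Align a phenotype vector or keyed data frame to a genotype matrix.
align_phenotype <- function(gm, phenotype) {
  if (is.data.frame(phenotype)) {
    if (!all(c("sample_id", "phenotype") %in% names(phenotype))) {
      stop_pg("phenotype table needs sample_id and phenotype columns",
              "pg_parameter_error")
    }
    idx <- match(gm$sample_ids, phenotype$sample_id)
    return(phenotype$phenotype[idx])
  }
  if (length(phenotype) != nrow(gm$codes)) {
    stop_pg("phenotype length must match sample count", "pg_parameter_error")
  }
  as.numeric(phenotype)
}

align_covars <- function(gm, covars) {
  if (is.null(covars)) return(NULL)
  covars <- as.data.frame(covars)
  if ("sample_id" %in% names(covars)) {
    covars <- covars[match(gm$sample_ids, covars$sample_id), , drop = FALSE]
    covars$sample_id <- NULL
  } else if (nrow(covars) != nrow(gm$codes)) {
    stop_pg("covariate rows must match sample count", "pg_parameter_error")
  }
  num <- vapply(covars, is.numeric, logical(1))
  as.matrix(covars[, num, drop = FALSE])
}

#' Genomic inflation factor and Q-Q coordinates
#'
#' Converts association p-values to 1-df chi-square quantiles and estimates
#' the genomic-control inflation factor as the ratio of the median observed
#' chi-square to the null median (0.4549364); lambda near 1 indicates no
#' systematic confounding.  Also returns quantile-quantile plot coordinates
#' with a 95% order-statistic (beta-distribution) band.
#'
#' @param p_values vector of at least 100 p-values in (0, 1].
#' @return List with `lambda` and `qq` (data frame `expected`, `observed`
#'   on the -log10 scale, with `lower`/`upper` band columns).
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100L) {
    stop_pg("need at least 100 p-values", "pg_parameter_error")
  }
  if (any(p_values <= 0 | p_values > 1)) {
    stop_pg("p-values must lie in (0, 1]", "pg_parameter_error")
  }
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1,
                                                 lower.tail = FALSE)
  m <- length(p_values)
  i <- seq_len(m)
  qq <- data.frame(
    expected = -log10((i - 0.5) / m),
    observed = -log10(sort(p_values)),
    lower = -log10(stats::qbeta(0.975, i, m - i + 1)),
    upper = -log10(stats::qbeta(0.025, i, m - i + 1))
  )
  list(lambda = lambda, qq = qq)
}
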