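#' Composite linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of 0/1/2 genotype codes at two SNPs over
#' their pairwise-complete samples (composite LD; no haplotype phasing).
#' Invariant under allele-label flips of either SNP.
#'
#' @param genotypes_i,genotypes_j numeric 0/1/2/`NA` vectors over the same
#'   samples.
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(genotypes_i, genotypes_j) {
  ok <- !is.na(genotypes_i) & !is.na(genotypes_j)
  gi <- genotypes_i[ok]
  gj <- genotypes_j[ok]
  if (length(gi) < 2L) {
    stop_pg("fewer than 2 pairwise-complete samples", "pg_parameter_error")
  }
  if (stats::var(gi) == 0 || stats::var(gj) == 0) {
    stop_pg("zero genotype variance", "pg_ld_error")
  }
  stats::cor(gi, gj)^2
}

#' Greedy LD-based clumping of association results
#'
#' Defines association regions around index SNPs the way PLINK's clumping
#' does: repeatedly take the remaining SNP with the smallest p-value not
#' exceeding `p1` as the next index, and assign to its clump every
#' unclumped SNP with p <= `p2` on the same chromosome, within `kb`
#' kilobases, and with genotype r-squared at least `r2` with the index.
#' Ties in p are broken by SNP id.
#'
#' @param results an `assoc_result` table (needs `id`, `chrom`, `pos`,
#'   `p`).
#' @param gm the [genotype_matrix()] the results came from.
#' @param p1 index-SNP significance threshold (default 1e-5).
#' @param p2 clumped-SNP significance threshold (default 0.01).
#' @param r2 LD threshold (default 0.1).
#' @param kb physical distance threshold in kilobases (default 1250).
#'
#' @return A `clump_report`: list with `members` (data frame `clump`,
#'   `index_id`, `id`, `p`, `r2_with_index`, `pos`; the index SNP appears
#'   as its own member with r2 = 1) and `ranges` (per-clump `chrom`,
#'   `bp_min`, `bp_max`, `n_snps`).  No SNP is assigned to more than one
#'   clump.  An empty report (zero rows) is returned when no SNP reaches
#'   `p1`.
#' @export
clump <- function(results, gm, p1 = 1e-5, p2 = 0.01, r2 = 0.1, kb = 1250) {
  need <- c("id", "chrom", "pos", "p")
  if (!all(need %in% names(results))) {
    stop_pg("`results` must contain id, chrom, pos, p", "pg_parameter_error")
  }
  res <- results[!is.na(results$p), need]
  res <- res[order(res$p, res$id), ]
  codes <- gm$codes
  col_of <- match(res$id, gm$snp_meta$id)
  if (anyNA(col_of)) {
    stop_pg("results contain SNPs absent from the genotype matrix",
            "pg_parameter_error")
  }

  unclumped <- rep(TRUE, nrow(res))
  members <- NULL
  ranges <- NULL
  clump_no <- 0L
  repeat {
    cand <- which(unclumped & res$p <= p1)
    if (length(cand) == 0L) break
    i <- cand[1L]                         # smallest p (rows sorted)
    clump_no <- clump_no + 1L
    g_index <- codes[, col_of[i]]
    in_window <- which(
      unclumped & res$p <= p2 & res$chrom == res$chrom[i] &
        abs(res$pos - res$pos[i]) <= kb * 1000
    )
    in_window <- setdiff(in_window, i)
    r2_vals <- vapply(in_window, function(j) {
      tryCatch(ld_r2(g_index, codes[, col_of[j]]),
               pursuitgwas_error = function(e) 0)
    }, numeric(1))
    hit <- in_window[r2_vals >= r2]
    rows <- c(i, hit)
    members <- rbind(members, data.frame(
      clump = clump_no, index_id = res$id[i], id = res$id[rows],
      p = res$p[rows], r2_with_index = c(1, r2_vals[r2_vals >= r2]),
      chrom = res$chrom[rows], pos = res$pos[rows],
      stringsAsFactors = FALSE
    ))
    ranges <- rbind(ranges, data.frame(
      clump = clump_no, index_id = res$id[i], chrom = res$chrom[i],
      index_p = res$p[i], bp_min = min(res$pos[rows]),
      bp_max = max(res$pos[rows]), n_snps = length(rows),
      stringsAsFactors = FALSE
    ))
    unclumped[rows] <- FALSE
  }
  structure(
    list(
      members = if (is.null(members)) data.frame(
        clump = integer(0), index_id = character(0), id = character(0),
        p = numeric(0), r2_with_index = numeric(0), chrom = character(0),
        pos = numeric(0)
      ) else members,
      ranges = if (is.null(ranges)) data.frame(
        clump = integer(0), index_id = character(0), chrom = character(0),
        index_p = numeric(0), bp_min = numeric(0), bp_max = numeric(0),
        n_snps = integer(0)
      ) else ranges,
      params = list(p1 = p1, p2 = p2, r2 = r2, kb = kb)
    ),
    class = "clump_report"
  )
}
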