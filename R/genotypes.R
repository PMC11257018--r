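#' Construct a genotype matrix
#'
#' The central genotype container: an `n x m` matrix of minor-allele counts
#' (0/1/2, `NA` for missing) together with per-SNP metadata and sample
#' identifiers.  Rows are samples, columns are SNPs.
#'
#' @param codes numeric matrix of 0/1/2/`NA` allele-count codes
#'   (samples x SNPs).
#' @param snp_meta data frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `a1` (allele counted by `codes`), `a2`; one row per SNP.  Positions must
#'   be strictly increasing within each chromosome.
#' @param sample_ids character vector of sample identifiers.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, snp_meta, sample_ids) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (!all(codes %in% c(0, 1, 2) | is.na(codes))) {
    stop_pg("genotype codes must be 0, 1, 2 or NA", "pg_parameter_error")
  }
  need <- c("chrom", "pos", "id", "a1", "a2")
  if (!is.data.frame(snp_meta) || !all(need %in% names(snp_meta))) {
    stop_pg("`snp_meta` must have columns chrom, pos, id, a1, a2",
            "pg_parameter_error")
  }
  if (nrow(snp_meta) != ncol(codes)) {
    stop_pg("snp_meta rows must match number of SNP columns",
            "pg_parameter_error")
  }
  if (length(sample_ids) != nrow(codes)) {
    stop_pg("sample_ids must match number of rows", "pg_parameter_error")
  }
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop_pg("positions must be strictly increasing within chromosome",
              "pg_parameter_error")
    }
  }
  snp_meta <- snp_meta[, need]
  snp_meta$id <- as.character(snp_meta$id)
  rownames(codes) <- sample_ids
  colnames(codes) <- snp_meta$id
  structure(
    list(codes = codes, snp_meta = snp_meta,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Per-SNP allele-1 frequency and minor allele frequency
#'
#' @param gm a [genotype_matrix()].
#' @return A data frame with `id`, `freq_a1` (frequency of the counted
#'   allele), `maf` (`min(freq_a1, 1 - freq_a1)`) and `missing_rate`.
#' @export
snp_freq <- function(gm) {
  f <- colMeans(gm$codes, na.rm = TRUE) / 2
  data.frame(
    id = gm$snp_meta$id,
    freq_a1 = f,
    maf = pmin(f, 1 - f),
    missing_rate = colMeans(is.na(gm$codes)),
    row.names = NULL
  )
}

# Flip codes so that allele 1 is the minor allele at every SNP.
orient_minor <- function(gm) {
  f <- colMeans(gm$codes, na.rm = TRUE) / 2
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip) > 0L) {
    gm$codes[, flip] <- 2 - gm$codes[, flip]
    a1 <- gm$snp_meta$a1[flip]
    gm$snp_meta$a1[flip] <- gm$snp_meta$a2[flip]
    gm$snp_meta$a2[flip] <- a1
  }
  attr(gm, "flipped") <- gm$snp_meta$id[flip]
  gm
}

# Subset helper (keeps metadata in sync).
subset_gm <- function(gm, samples = NULL, snps = NULL) {
  if (!is.null(samples)) {
    gm$codes <- gm$codes[samples, , drop = FALSE]
    gm$sample_ids <- gm$sample_ids[samples]
  }
  if (!is.null(snps)) {
    gm$codes <- gm$codes[, snps, drop = FALSE]
    gm$snp_meta <- gm$snp_meta[snps, , drop = FALSE]
    rownames(gm$snp_meta) <- NULL
  }
  gm
}
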