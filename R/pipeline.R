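#' Build a pipeline run configuration
#'
#' A flat, serializable set of stage toggles and parameters for
#' [run_pipeline()].  Stage dependencies are validated: `gwas` needs
#' `simulate` (or pre-existing genotype/phenotype files in `out_dir`), and
#' `permtest` / `clump` need `gwas`.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed master seed; each stage derives its own stream from it.
#' @param do_simulate,do_qc,do_gwas,do_permtest,do_clump,do_power stage
#'   toggles.
#' @param n_individuals,n_snps,maf_min,maf_max,causal_maf,causal_beta,
#'   sex_effect_sd,n_clusters,cluster_divergence,missing_rate cohort
#'   simulator parameters (see [sim_cohort_config()]); set `causal_beta`
#'   to 0 for a null cohort.
#' @param n_pcs number of genotype principal components used as
#'   covariates.
#' @param rank_transform run the association scan on phenotype ranks.
#' @param perm_clusters,n_perm within-cluster max-T permutation
#'   parameters.
#' @param clump_p1,clump_p2,clump_r2,clump_kb clumping thresholds.
#' @param power_r2,power_nu1,power_nu2,power_alpha power-stage
#'   parameters.
#' @param log_level `"info"` or `"error"`.
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            do_simulate = TRUE, do_qc = TRUE,
                            do_gwas = TRUE, do_permtest = FALSE,
                            do_clump = TRUE, do_power = TRUE,
                            n_individuals = 200L, n_snps = 500L,
                            maf_min = 0.05, maf_max = 0.5,
                            causal_maf = 0.49, causal_beta = 0.29,
                            sex_effect_sd = 0.2,
                            n_clusters = 1L, cluster_divergence = 0,
                            missing_rate = 0,
                            n_pcs = 3L, rank_transform = FALSE,
                            perm_clusters = 2L, n_perm = 200L,
                            clump_p1 = 1e-5, clump_p2 = 0.01,
                            clump_r2 = 0.1, clump_kb = 1250,
                            power_r2 = 0.043, power_nu1 = 1,
                            power_nu2 = 977, power_alpha = 5e-7,
                            log_level = c("info", "error")) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    do_simulate = isTRUE(do_simulate), do_qc = isTRUE(do_qc),
    do_gwas = isTRUE(do_gwas), do_permtest = isTRUE(do_permtest),
    do_clump = isTRUE(do_clump), do_power = isTRUE(do_power),
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_min = maf_min, maf_max = maf_max,
    causal_maf = causal_maf, causal_beta = causal_beta,
    sex_effect_sd = sex_effect_sd, n_clusters = as.integer(n_clusters),
    cluster_divergence = cluster_divergence, missing_rate = missing_rate,
    n_pcs = as.integer(n_pcs), rank_transform = isTRUE(rank_transform),
    perm_clusters = as.integer(perm_clusters), n_perm = as.integer(n_perm),
    clump_p1 = clump_p1, clump_p2 = clump_p2, clump_r2 = clump_r2,
    clump_kb = clump_kb, power_r2 = power_r2, power_nu1 = power_nu1,
    power_nu2 = power_nu2, power_alpha = power_alpha,
    log_level = match.arg(log_level)
  )
  if ((cfg$do_permtest || cfg$do_clump) && !cfg$do_gwas) {
    stop_pg("permtest/clump stages require the gwas stage",
            "pg_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Serialize / parse a run configuration as flat key=value lines
#'
#' @param config a [pipeline_config()] object.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  vals <- vapply(unclass(config), function(v) {
    if (is.logical(v)) tolower(as.character(v)) else as.character(v)
  }, character(1))
  writeLines(paste0(names(vals), "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  parse_val <- function(v) {
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  args <- lapply(vals, parse_val)
  names(args) <- keys
  do.call(pipeline_config, args)
}

pg_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) {
    message(sprintf("[pursuitgwas] %s", sprintf(...)))
  }
  invisible(NULL)
}

#' Run the synthetic-cohort association pipeline
#'
#' Executes the enabled stages in order (simulate -> QC -> PCA covariates
#' -> GWAS -> max-T permutation -> clumping -> power), writing each stage's
#' outputs to `config$out_dir` before the next stage starts, and finally a
#' JSON run manifest with the tool version, config hash, output checksums,
#' per-stage row counts and wall time.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop_pg("`config` must be a run_config", "pg_parameter_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.txt")
  write_config(config, cfg_path)
  manifest <- list(
    tool = "pursuitgwas",
    version = as.character(utils::packageVersion("pursuitgwas")),
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = list()
  )
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, seconds = proc.time()[["elapsed"]] - t0)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop(e)
  }

  geno_path <- file.path(config$out_dir, "genotypes.tsv")
  pheno_path <- file.path(config$out_dir, "phenotypes.tsv")

  gm <- NULL
  pheno <- NULL
  if (config$do_simulate) {
    st <- t_stage(tryCatch({
      sim <- simulate_cohort(sim_cohort_config(
        n_individuals = config$n_individuals, n_snps = config$n_snps,
        maf_range = c(config$maf_min, config$maf_max),
        causal_snp = if (config$causal_beta != 0) {
          list(maf = config$causal_maf,
               beta_sd_per_allele = config$causal_beta)
        },
        sex_effect_sd = config$sex_effect_sd,
        n_clusters = config$n_clusters,
        cluster_divergence = config$cluster_divergence,
        missing_rate = config$missing_rate,
        seed = derive_seed(config$seed, 1L)
      ))
      write_genotypes_tsv(sim$genotypes, geno_path)
      write_table_tsv(sim$phenotypes, pheno_path)
      jsonlite::write_json(
        sim$truth[c("causal_id", "causal_index", "beta_sd_per_allele")],
        file.path(config$out_dir, "truth.json"), auto_unbox = TRUE,
        digits = NA
      )
      sim
    }, error = function(e) fail("simulate", e)))
    gm <- st$value$genotypes
    pheno <- st$value$phenotypes
    manifest$stages$simulate <- list(
      status = "ok", n_samples = nrow(gm$codes), n_snps = ncol(gm$codes),
      seconds = st$seconds
    )
    pg_log(config, "simulate: %d x %d", nrow(gm$codes), ncol(gm$codes))
  } else {
    if (!file.exists(geno_path) || !file.exists(pheno_path)) {
      stop_pg("gwas inputs missing and simulate stage disabled",
              "pg_config_error")
    }
    gm <- read_genotypes(geno_path)
    pheno <- read_table_tsv(pheno_path)
  }

  if (config$do_qc) {
    st <- t_stage(tryCatch(run_qc(gm), error = function(e) fail("qc", e)))
    gm <- st$value$genotypes
    jsonlite::write_json(
      list(excluded_samples = st$value$report$excluded_samples,
           n_excluded_snps = as.list(st$value$report$n_excluded_snps)),
      file.path(config$out_dir, "qc_report.json"), auto_unbox = TRUE,
      digits = NA
    )
    manifest$stages$qc <- list(status = "ok",
                               n_snps_kept = ncol(gm$codes),
                               seconds = st$seconds)
    pg_log(config, "qc: %d SNPs kept", ncol(gm$codes))
  }

  covars <- NULL
  assoc <- NULL
  if (config$do_gwas) {
    st <- t_stage(tryCatch({
      pcs <- genotype_pca(gm, k = config$n_pcs)
      covars <- cbind(pcs,
                      sex = pheno$sex[match(pcs$sample_id,
                                            pheno$sample_id)])
      write_table_tsv(covars, file.path(config$out_dir, "covars.tsv"))
      res <- run_gwas(gm, pheno, covars,
                      rank_transform = config$rank_transform)
      write_table_tsv(as.data.frame(res),
                      file.path(config$out_dir, "assoc.tsv"))
      list(res = res, covars = covars)
    }, error = function(e) fail("gwas", e)))
    assoc <- st$value$res
    covars <- st$value$covars
    lam <- if (sum(!is.na(assoc$p)) >= 100) {
      genomic_inflation(assoc$p)$lambda
    } else {
      NA_real_
    }
    manifest$stages$gwas <- list(status = "ok", n_snps = nrow(assoc),
                                 lambda = lam, seconds = st$seconds)
    pg_log(config, "gwas: %d SNPs, lambda %.3f", nrow(assoc), lam)
  }

  if (config$do_permtest) {
    st <- t_stage(tryCatch({
      cl <- ibs_cluster(gm, n_clusters = config$perm_clusters)
      pr <- maxT_permutation(gm, pheno, covars, cl,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, 2L))
      write_table_tsv(pr$table, file.path(config$out_dir, "permtest.tsv"))
      pr
    }, error = function(e) fail("permtest", e)))
    manifest$stages$permtest <- list(
      status = "ok", n_perm = st$value$n_perm,
      observed_min_id = st$value$observed_min_id,
      min_corrected_p = min(st$value$table$corrected_p),
      seconds = st$seconds
    )
    pg_log(config, "permtest: min corrected p %.4g",
           min(st$value$table$corrected_p))
  }

  if (config$do_clump) {
    st <- t_stage(tryCatch({
      cr <- clump(assoc, gm, p1 = config$clump_p1, p2 = config$clump_p2,
                  r2 = config$clump_r2, kb = config$clump_kb)
      write_table_tsv(cr$members, file.path(config$out_dir, "clumps.tsv"))
      write_table_tsv(cr$ranges,
                      file.path(config$out_dir, "clump_ranges.tsv"))
      cr
    }, error = function(e) fail("clump", e)))
    manifest$stages$clump <- list(status = "ok",
                                  n_clumps = nrow(st$value$ranges),
                                  seconds = st$seconds)
    pg_log(config, "clump: %d clumps", nrow(st$value$ranges))
  }

  if (config$do_power) {
    st <- t_stage(tryCatch({
      pow <- power_ncf(config$power_r2, config$power_nu1,
                       config$power_nu2, config$power_alpha)
      jsonlite::write_json(
        list(r_squared = config$power_r2, nu1 = config$power_nu1,
             nu2 = config$power_nu2, alpha = config$power_alpha,
             Fcrit = attr(pow, "Fcrit"), lambda = attr(pow, "lambda"),
             power = as.numeric(pow)),
        file.path(config$out_dir, "power.json"), auto_unbox = TRUE,
        digits = NA
      )
      as.numeric(pow)
    }, error = function(e) fail("power", e)))
    manifest$stages$power <- list(status = "ok", power = st$value,
                                  seconds = st$seconds)
    pg_log(config, "power: %.4f", st$value)
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
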