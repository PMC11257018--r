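#' Read genotypes from VCF, matrix TSV or PED/MAP
#'
#' Maps diploid genotypes to minor-allele counts.  For VCF the ALT allele
#' count is taken first and the SNP is flipped (with a message) wherever
#' the ALT frequency exceeds 0.5, so that allele 1 is always the minor
#' allele.  Missing genotypes (`./.`, `NA`, `0 0` in PED) become `NA`.
#'
#' @param path file path (for `ped_map`, the `.ped` file; the `.map` file
#'   is found by extension).
#' @param format `"auto"` (by extension), `"vcf"`, `"matrix_tsv"` or
#'   `"ped_map"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix_tsv",
                                            "ped_map")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
                     vcf = "vcf", ped = "ped_map", "matrix_tsv")
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         matrix_tsv = read_genotypes_tsv(path),
         ped_map = read_genotypes_ped(path))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  ploidy_bad <- !is.na(alleles) & grepl("/.*/", alleles)
  if (any(ploidy_bad)) {
    stop_pg("non-diploid GT encountered", "pg_ploidy_error")
  }
  count_alt <- function(a) {
    if (is.na(a) || a == "." || a == "./.") return(NA_real_)
    parts <- strsplit(a, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || any(parts == ".")) return(NA_real_)
    sum(parts == "1")
  }
  codes <- t(apply(gt, c(1L, 2L), function(a) {
    count_alt(gsub("\\|", "/", a))
  }))
  meta <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"], a1 = fix[, "ALT"], a2 = fix[, "REF"],
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(codes, meta, colnames(gt))
  gm <- orient_minor(gm)
  if (length(attr(gm, "flipped")) > 0L) {
    message(sprintf("flipped %d SNP(s) to minor-allele orientation: %s",
                    length(attr(gm, "flipped")),
                    paste(attr(gm, "flipped"), collapse = ", ")))
  }
  gm
}

read_genotypes_ped <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(map_path)) {
    stop_pg(sprintf("MAP file not found: %s", map_path), "pg_parse_error")
  }
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m) {
    stop_pg("PED column count does not match MAP", "pg_parse_error")
  }
  sample_ids <- ped[[2L]]
  codes <- matrix(NA_real_, nrow(ped), m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- ped[[6L + 2L * j - 1L]]
    x2 <- ped[[6L + 2L * j]]
    x1[x1 == "0"] <- NA
    x2[x2 == "0"] <- NA
    alleles <- sort(table(c(x1, x2)), decreasing = TRUE)
    if (length(alleles) > 2L) {
      stop_pg(sprintf("more than two alleles at %s", map$id[j]),
              "pg_parse_error")
    }
    major <- names(alleles)[1L]
    minor <- if (length(alleles) == 2L) names(alleles)[2L] else major
    a1[j] <- minor
    a2[j] <- major
    codes[, j] <- (x1 == minor) + (x2 == minor)
    codes[is.na(x1) | is.na(x2), j] <- NA
  }
  meta <- data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
                     a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  genotype_matrix(codes, meta, sample_ids)
}

#' Write / read the internal genotype matrix TSV
#'
#' The canonical interchange format: one row per SNP with columns
#' `chrom pos id a1 a2` followed by one 0/1/2/`NA` code column per sample.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_tsv <- function(gm, path) {
  df <- cbind(gm$snp_meta, as.data.frame(t(gm$codes)))
  names(df) <- c(names(gm$snp_meta), gm$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = list(chrom = "character",
                                            id = "character",
                                            a1 = "character",
                                            a2 = "character"))
  need <- c("chrom", "pos", "id", "a1", "a2")
  if (!all(need %in% names(df))) {
    stop_pg("malformed genotype TSV header", "pg_parse_error")
  }
  sample_ids <- setdiff(names(df), need)
  codes <- t(as.matrix(df[, sample_ids, drop = FALSE]))
  genotype_matrix(codes, df[, need], sample_ids)
}

#' Write a simulated session to trace/calibration TSV files
#'
#' Emits one `trial_###.tsv` per trial (`time_ms  eye_deg  valid`), one
#' `cal_###.tsv` per calibration segment (`time_ms  signal  target_deg`),
#' index tables `trials.tsv` / `calibrations.tsv` carrying the target
#' parameters needed to reconstruct each trial's target trajectory, and a
#' `truth.json` sidecar with the simulator's ground-truth event log.
#'
#' @param session a `pursuit_session`.
#' @param dir output directory (created if needed).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trial_index <- NULL
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    f <- sprintf("trial_%03d.tsv", i)
    utils::write.table(
      data.frame(time_ms = tr$time_ms,
                 eye_deg = signif(tr$signal, 10),
                 valid = as.integer(tr$valid)),
      file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
    )
    spec <- tr$target$spec
    trial_index <- rbind(trial_index, data.frame(
      file = f, trial_no = i, speed_deg_s = spec$speed_deg_s,
      amplitude_deg = spec$amplitude_deg, n_cycles = spec$n_cycles,
      fixation_ms = tr$target$fixation_ms,
      sample_rate_hz = spec$sample_rate_hz,
      start_direction = spec$start_direction, stringsAsFactors = FALSE
    ))
  }
  utils::write.table(trial_index, file.path(dir, "trials.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cal_index <- NULL
  for (i in seq_along(session$calibrations)) {
    cc <- session$calibrations[[i]]
    f <- sprintf("cal_%03d.tsv", i)
    utils::write.table(
      data.frame(time_ms = cc$segment$time_ms,
                 signal = signif(cc$segment$signal, 10),
                 target_deg = cc$segment$target_deg),
      file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
    )
    cal_index <- rbind(cal_index, data.frame(
      file = f, after_trial = cc$after_trial, stringsAsFactors = FALSE
    ))
  }
  utils::write.table(cal_index, file.path(dir, "calibrations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

read_session_dir <- function(dir) {
  ti_path <- file.path(dir, "trials.tsv")
  if (!file.exists(ti_path)) {
    stop_pg(sprintf("no trials.tsv in %s", dir), "pg_parse_error")
  }
  ti <- utils::read.delim(ti_path, stringsAsFactors = FALSE)
  trials <- vector("list", nrow(ti))
  for (i in seq_len(nrow(ti))) {
    f <- file.path(dir, ti$file[i])
    df <- utils::read.delim(f)
    if (!identical(names(df), c("time_ms", "eye_deg", "valid"))) {
      stop_pg(sprintf("malformed trace header in %s", f), "pg_parse_error")
    }
    if (any(diff(df$time_ms) <= 0)) {
      stop_pg(sprintf("non-monotone time in %s", f), "pg_data_error")
    }
    spec <- target_spec(
      speed_deg_s = ti$speed_deg_s[i], amplitude_deg = ti$amplitude_deg[i],
      n_cycles = ti$n_cycles[i], initial_fixation_ms = ti$fixation_ms[i],
      sample_rate_hz = ti$sample_rate_hz[i],
      start_direction = ti$start_direction[i]
    )
    target <- generate_target_waveform(spec, seed = 0L)
    if (length(target$time_ms) != nrow(df)) {
      stop_pg(sprintf("trace length does not match target in %s", f),
              "pg_data_error")
    }
    trials[[i]] <- structure(
      list(time_ms = df$time_ms, signal = df$eye_deg,
           valid = as.logical(df$valid), target = target,
           trial_no = ti$trial_no[i]),
      class = "pursuit_trial"
    )
  }
  ci <- utils::read.delim(file.path(dir, "calibrations.tsv"),
                          stringsAsFactors = FALSE)
  calibrations <- lapply(seq_len(nrow(ci)), function(i) {
    df <- utils::read.delim(file.path(dir, ci$file[i]))
    if (!identical(names(df), c("time_ms", "signal", "target_deg"))) {
      stop_pg(sprintf("malformed calibration header in %s", ci$file[i]),
              "pg_parse_error")
    }
    list(segment = structure(
      list(time_ms = df$time_ms, signal = df$signal,
           target_deg = df$target_deg,
           valid = rep(TRUE, nrow(df))),
      class = "calibration_segment"
    ), after_trial = ci$after_trial[i])
  })
  structure(list(trials = trials, calibrations = calibrations),
            class = "pursuit_session")
}

#' Read eye-movement sessions from a directory tree
#'
#' Each participant is a subdirectory containing the trace dialect written
#' by [write_session()]; a directory that itself contains `trials.tsv` is
#' read as a single anonymous participant.
#'
#' @param dir root directory.
#' @return Named list of `pursuit_session` objects keyed by participant.
#' @export
read_traces <- function(dir) {
  if (file.exists(file.path(dir, "trials.tsv"))) {
    out <- list(read_session_dir(dir))
    names(out) <- basename(dir)
    return(out)
  }
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "trials.tsv"))]
  if (length(subs) == 0L) {
    warning("no sessions found in ", dir)
    return(structure(list(), names = character(0)))
  }
  out <- lapply(subs, read_session_dir)
  names(out) <- basename(subs)
  out
}

#' Write / read phenotype and covariate tables
#'
#' Plain TSVs keyed by `sample_id` (phenotypes) or `participant_id`
#' (session phenotypes); floats are serialized with 10 significant digits.
#'
#' @param df data frame to write.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
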