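# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded simulator calls do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 2147483629L + 104729L * as.integer(k)) %% 2147483629L
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
stop_pg <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pursuitgwas_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict_lower && x <= lower) || (!strict_lower && x < lower) ||
      x > upper) {
    stop_pg(sprintf("invalid parameter `%s`", name), "pg_parameter_error")
  }
  invisible(x)
}

# Merge intervals given as two-column matrix [start, end]; assumes start<=end.
merge_intervals <- function(ivl) {
  if (is.null(ivl) || nrow(ivl) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  ivl <- ivl[order(ivl[, 1L]), , drop = FALSE]
  out <- ivl[1L, , drop = FALSE]
  if (nrow(ivl) > 1L) {
    for (i in 2L:nrow(ivl)) {
      j <- nrow(out)
      if (ivl[i, 1L] <= out[j, 2L]) {
        out[j, 2L] <- max(out[j, 2L], ivl[i, 2L])
      } else {
        out <- rbind(out, ivl[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

# Runs of TRUE in a logical vector -> matrix of [first, last] indices.
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
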