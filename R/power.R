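#' Power of the additive association test via the noncentral F distribution
#'
#' For an effect explaining a fraction `r_squared` of phenotypic variance,
#' the association F statistic with `nu1` numerator and `nu2` denominator
#' degrees of freedom is noncentral F with noncentrality
#' `lambda = r2/(1 - r2) * nu2`.  Power at significance level `alpha` is
#'
#' `power = 1 - F(Fcrit | nu1, nu2, lambda)`
#'
#' where `Fcrit` is the `100(1 - alpha)` percentile of the central
#' F(nu1, nu2) distribution.  At `r_squared = 0` the power equals `alpha`
#' exactly.
#'
#' @param r_squared effect size (coefficient of determination) in [0, 1);
#'   vectorized.
#' @param nu1 numerator degrees of freedom (1 for a single SNP).
#' @param nu2 denominator (residual) degrees of freedom.
#' @param alpha significance level in (0, 1).
#'
#' @return Power in [0, 1], same length as `r_squared`.  The critical
#'   value and noncentrality are attached as attributes `Fcrit` and
#'   `lambda`.
#' @export
power_ncf <- function(r_squared, nu1 = 1, nu2, alpha) {
  if (any(!is.finite(r_squared)) || any(r_squared < 0) ||
      any(r_squared >= 1)) {
    stop_pg("`r_squared` must lie in [0, 1)", "pg_parameter_error")
  }
  assert_scalar_num(nu1, "nu1", 1)
  assert_scalar_num(nu2, "nu2", 1)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_pg("`alpha` must lie in (0, 1)", "pg_parameter_error")
  }
  lambda <- r_squared / (1 - r_squared) * nu2
  f_crit <- stats::qf(1 - alpha, nu1, nu2)
  pow <- stats::pf(f_crit, nu1, nu2, ncp = lambda, lower.tail = FALSE)
  pow[lambda == 0] <- alpha             # null case: power is alpha exactly
  attr(pow, "Fcrit") <- f_crit
  attr(pow, "lambda") <- lambda
  pow
}
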