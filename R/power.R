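# A-priori power for the within effect of a repeated-measures design via the
# noncentral-F distribution.

#' Power of a repeated-measures within effect
#'
#' Classical noncentral-F convention: noncentrality
#' `lambda = f^2 * N * m * epsilon / (1 - rho)`, numerator df
#' `(m - 1) * epsilon`, denominator df `(N - k) * (m - 1) * epsilon`, where
#' `f` is the Cohen effect size, `N` the total sample size, `k` the number
#' of groups, `m` the number of repeated measurements, `rho` the assumed
#' correlation among repeated measures and `epsilon` the nonsphericity
#' correction.
#'
#' @param n Total sample size (all groups).
#' @param f Effect size (Cohen's f), `> 0`.
#' @param alpha Significance level in `(0, 1)`.
#' @param k Number of groups (`>= 2`).
#' @param m Number of repeated measurements (`>= 2`).
#' @param rho Correlation among repeated measures, in `[0, 1)`.
#' @param epsilon Nonsphericity correction, in `(1/(m-1), 1]`.
#' @return Achieved power (scalar in `(0, 1)`).
#' @export
#' @examples
#' rm_power(26, f = 0.38)
rm_power <- function(n, f = 0.38, alpha = 0.05, k = 2, m = 2, rho = 0.5,
                     epsilon = 1) {
  validate_power_spec(f, alpha, 0.5, k, m, rho, epsilon)
  if (n <= k) {
    abort("n must exceed the number of groups",
          class = "dyadsync_config_error")
  }
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  df1 <- (m - 1) * epsilon
  df2 <- (n - k) * (m - 1) * epsilon
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

validate_power_spec <- function(f, alpha, power, k, m, rho, epsilon) {
  err <- function(msg) abort(msg, class = "dyadsync_config_error")
  if (f <= 0) err("effect size f must be > 0")
  if (alpha <= 0 || alpha >= 1) err("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) err("target power must lie in (0, 1)")
  if (k < 2 || m < 2) err("k and m must be >= 2")
  if (rho < 0 || rho >= 1) err("rho must lie in [0, 1)")
  if (epsilon <= 1 / (m - 1 + 1e-12) - 1e-12 && m > 2 || epsilon > 1) {
    err("epsilon must lie in (1/(m-1), 1]")
  }
  invisible(TRUE)
}

#' Minimal sample size reaching a target power
#'
#' Searches total N upward in multiples of `k` (so groups stay balanced)
#' until [rm_power()] first reaches `power`, and returns that N.
#'
#' @inheritParams rm_power
#' @param power Target power in `(0, 1)`.
#' @param n_max Search cap; exceeding it without reaching the target is an
#'   error.
#' @return Integer total sample size; the achieved power is attached as
#'   attribute `power`.
#' @export
#' @examples
#' required_sample_size(f = 0.38, power = 0.95) # 26
required_sample_size <- function(f = 0.38, alpha = 0.05, power = 0.95,
                                 k = 2, m = 2, rho = 0.5, epsilon = 1,
                                 n_max = 100000) {
  validate_power_spec(f, alpha, power, k, m, rho, epsilon)
  n <- 2 * k  # smallest balanced N with positive error df
  while (n <= n_max) {
    pw <- rm_power(n, f, alpha, k, m, rho, epsilon)
    if (pw >= power) {
      return(structure(as.integer(n), power = pw))
    }
    n <- n + k
  }
  abort("target power unreachable within n_max",
        class = "dyadsync_config_error")
}
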