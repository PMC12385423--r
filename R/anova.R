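# Repeated-measures ANOVA with Greenhouse-Geisser correction, Mauchly
# sphericity tests, partial eta squared and Bonferroni post hocs; one-way
# ANOVA for between-cluster comparisons.

# orthonormal polynomial contrasts (columns orthonormal)
orth_contrasts <- function(levels) {
  C <- stats::contr.poly(levels)
  C %*% diag(1 / sqrt(colSums(C^2)), ncol(C))
}

#' Repeated-measures ANOVA on a long table
#'
#' Full within-subject decomposition for a completely crossed, balanced
#' design with one observation per subject x cell. For every effect
#' (main effects and all interactions of `within`) the table reports the sum
#' of squares, its subject-interaction error term, F, uncorrected p, partial
#' eta squared (`SS_effect / (SS_effect + SS_error)`), the
#' Greenhouse-Geisser epsilon, the Mauchly sphericity test (for effects with
#' at least two numerator df) and the GG-corrected p. The conventionally
#' reported p (`p_reported`) is the GG-corrected one whenever the Mauchly
#' test rejects at .05, the uncorrected one otherwise; both are always
#' present.
#'
#' The decomposition is computed through orthonormal contrast projections of
#' the subject x cell matrix, which reproduces the classical univariate
#' sums of squares exactly and yields each effect's contrast covariance for
#' epsilon and Mauchly.
#'
#' @param data Long tibble or data frame.
#' @param dv Name of the response column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject identifier column.
#' @return Object of class `rm_anova` with a [tidy()] method; `tidy()`
#'   returns one row per effect.
#' @export
#' @examples
#' d <- tidyr::expand_grid(s = 1:8, phase = c("IP", "NCP", "RP"))
#' d$y <- rnorm(nrow(d)) + as.numeric(factor(d$phase))
#' tidy(rm_anova(d, "y", "phase", "s"))
rm_anova <- function(data, dv, within, subject) {
  data <- as_tibble(data)
  for (col in c(dv, within, subject)) {
    if (!col %in% names(data)) {
      abort(paste0("column not found: ", col), class = "dyadsync_input_error")
    }
  }
  facs <- lapply(within, function(f) {
    x <- data[[f]]
    if (is.factor(x)) droplevels(x) else factor(x)
  })
  names(facs) <- within
  subj <- factor(data[[subject]])
  n <- nlevels(subj)
  if (n < 3) {
    abort("repeated-measures ANOVA needs at least 3 subjects",
          class = "dyadsync_input_error")
  }
  L <- vapply(facs, nlevels, integer(1))
  P <- prod(L)
  cell <- interaction(rev(facs), lex.order = TRUE)  # first factor fastest
  tab <- table(subj, cell)
  if (any(tab != 1)) {
    abort("design must be complete and balanced (one observation per subject per cell)",
          class = "dyadsync_input_error")
  }
  Y <- matrix(NA_real_, n, P)
  idx <- cbind(as.integer(subj), as.integer(cell))
  Y[idx] <- data[[dv]]
  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- purrr::map(effects, function(E) {
    M <- matrix(1, 1, 1)
    for (f in rev(within)) {  # kron order: slowest-varying factor first
      Lf <- L[[f]]
      part <- if (f %in% E) orth_contrasts(Lf) else matrix(1 / sqrt(Lf), Lf, 1)
      M <- kronecker(M, part)
    }
    Z <- Y %*% M
    q <- ncol(Z)
    zbar <- colMeans(Z)
    ss <- n * sum(zbar^2)
    resid <- sweep(Z, 2, zbar)
    ss_err <- sum(resid^2)
    df1 <- q
    df2 <- q * (n - 1)
    ms <- ss / df1
    mse <- ss_err / df2
    tol <- 1e-12 * (sum(Y^2) / length(Y) + 1)
    F_stat <- if (mse > tol) ms / mse else if (ms <= tol) 0 else Inf
    p <- if (is.finite(F_stat)) pf(F_stat, df1, df2, lower.tail = FALSE) else 0
    if (q >= 2) {
      S <- crossprod(resid) / (n - 1)
      trS <- sum(diag(S))
      eps <- if (trS > 0) trS^2 / (q * sum(S^2)) else NA_real_
      eps <- min(max(eps, 1 / q), 1)
      detS <- det(S)
      if (is.finite(detS) && detS > 0 && trS > 0) {
        W <- detS / (trS / q)^q
        d <- n - 1
        rho <- 1 - (2 * q^2 + q + 2) / (6 * q * d)
        chi <- -d * rho * log(W)
        mdf <- q * (q + 1) / 2 - 1
        m_p <- pchisq(chi, mdf, lower.tail = FALSE)
      } else {
        W <- NA_real_
        m_p <- NA_real_
      }
    } else {
      eps <- 1
      W <- NA_real_
      m_p <- NA_real_
    }
    p_gg <- if (is.finite(F_stat) && F_stat > 0) {
      pf(F_stat, df1 * eps, df2 * eps, lower.tail = FALSE)
    } else {
      p
    }
    sphericity_violated <- is.finite(m_p) && m_p < 0.05
    tibble(
      effect = paste(E, collapse = ":"),
      df_num = df1, df_den = df2, ss = ss, ss_error = ss_err,
      F = F_stat, p = p,
      gg_epsilon = eps, mauchly_w = W, mauchly_p = m_p,
      p_gg = p_gg,
      p_reported = if (sphericity_violated) p_gg else p,
      partial_eta_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
  })
  grand <- mean(Y)
  ss_subject <- P * sum((rowMeans(Y) - grand)^2)
  ss_total <- sum((Y - grand)^2)
  structure(list(table = purrr::list_rbind(rows),
                 n_subjects = n, within = within, dv = dv,
                 ss_subject = ss_subject, ss_total = ss_total),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on '%s' (%d subjects)\n",
              x$dv, x$n_subjects))
  print(as.data.frame(x$table[, c("effect", "df_num", "df_den", "F",
                                  "p", "p_gg", "partial_eta_sq")]),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_effects = nrow(x$table),
         ss_total = x$ss_total, ss_subject = x$ss_subject)
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' Paired t tests between all level pairs of one within-subject factor,
#' computed on subject-level marginal means (averaging over any other
#' factors); adjusted p values are `min(1, p * n_pairs)`.
#'
#' @param data Long tibble.
#' @param dv,subject Column names as in [rm_anova()].
#' @param effect Name of the (single) factor whose levels are compared.
#' @return Tibble `level1`, `level2`, `mean_diff`, `t`, `df`, `p`, `p_adj`.
#' @export
bonferroni_posthoc <- function(data, dv, effect, subject) {
  data <- as_tibble(data)
  f <- if (is.factor(data[[effect]])) droplevels(data[[effect]])
       else factor(data[[effect]])
  levs <- levels(f)
  if (length(levs) < 2) {
    abort("post hoc comparisons need at least 2 levels",
          class = "dyadsync_input_error")
  }
  marg <- data %>%
    mutate(.lev = f) %>%
    summarise(value = mean(.data[[dv]]),
              .by = c(dplyr::all_of(subject), ".lev")) %>%
    tidyr::pivot_wider(names_from = ".lev", values_from = "value")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  rows <- purrr::map(pairs, function(pr) {
    d <- marg[[pr[1]]] - marg[[pr[2]]]
    nn <- length(d)
    se <- sd(d) / sqrt(nn)
    t_stat <- if (se > 0) mean(d) / se else 0
    p <- 2 * pt(abs(t_stat), nn - 1, lower.tail = FALSE)
    tibble(level1 = pr[1], level2 = pr[2], mean_diff = mean(d),
           t = t_stat, df = nn - 1, p = p,
           p_adj = min(1, p * n_pairs))
  })
  purrr::list_rbind(rows)
}

#' One-way between-groups ANOVA
#'
#' Classical between/within decomposition with
#' `eta_sq = SS_between / SS_total`, used to compare questionnaire scale
#' scores between clusters.
#'
#' @param data Tibble or data frame.
#' @param dv Name of the response column.
#' @param group Name of the grouping column.
#' @return One-row tibble `df_num`, `df_den`, `ss_between`, `ss_within`,
#'   `F`, `p`, `eta_sq`.
#' @export
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 7, 8, 9), g = rep(1:2, each = 3))
#' oneway_anova(d, "y", "g") # F = 54
oneway_anova <- function(data, dv, group) {
  data <- as_tibble(data)
  y <- data[[dv]]
  g <- factor(data[[group]])
  check_finite(y, dv)
  if (nlevels(g) < 2) {
    abort("one-way ANOVA needs at least 2 groups",
          class = "dyadsync_input_error")
  }
  if (length(y) < 3) {
    abort("one-way ANOVA needs at least 3 observations in total",
          class = "dyadsync_input_error")
  }
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  msb <- ssb / df1
  msw <- ssw / df2
  F_stat <- if (msw > 0) msb / msw else if (msb == 0) 0 else Inf
  p <- if (is.finite(F_stat)) pf(F_stat, df1, df2, lower.tail = FALSE) else 0
  sst <- ssb + ssw
  tibble(df_num = df1, df_den = df2, ss_between = ssb, ss_within = ssw,
         F = F_stat, p = p,
         eta_sq = if (sst > 0) ssb / sst else 0)
}

#' Screen a sample's distribution by skewness and kurtosis
#'
#' Sample skewness `m3 / m2^(3/2)` and excess kurtosis `m4 / m2^2 - 3`,
#' with a report-only flag raised when `|skewness| > 2` or
#' `|kurtosis| > 7`.
#'
#' @param values Numeric vector, `n >= 4`, non-constant.
#' @return One-row tibble `n`, `skewness`, `kurtosis`, `flag`.
#' @export
screen_distribution <- function(values) {
  check_finite(values, "values")
  n <- length(values)
  if (n < 4) {
    abort("need at least 4 values", class = "dyadsync_input_error")
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) {
    abort("values are constant (zero variance)",
          class = "dyadsync_input_error")
  }
  skew <- mean((values - m)^3) / m2^1.5
  kurt <- mean((values - m)^4) / m2^2 - 3
  tibble(n = n, skewness = skew, kurtosis = kurt,
         flag = abs(skew) > 2 | abs(kurt) > 7)
}
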