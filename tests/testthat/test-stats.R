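# Repeated-measures ANOVA decomposition, post hocs, one-way ANOVA, power
# analysis and distribution screening.

test_that("rm_anova reproduces the classical decomposition (aov oracle)", {
  set.seed(42)
  d <- tidyr::expand_grid(s = factor(1:13), A = factor(1:2), B = factor(1:3),
                          C = factor(1:3))
  d$y <- rnorm(nrow(d)) + 0.5 * as.numeric(d$B) +
    0.3 * as.numeric(d$A) * as.numeric(d$C)
  mine <- tidy(rm_anova(d, "y", c("A", "B", "C"), "s"))
  fit <- stats::aov(y ~ A * B * C + Error(s / (A * B * C)), data = d)
  sm <- summary(fit)
  for (i in seq_len(nrow(mine))) {
    eff <- mine$effect[i]
    stratum <- sm[[paste0("Error: s:", gsub(":", ":", eff))]][[1]]
    expect_equal(mine$ss[i], stratum["Sum Sq"][[1]][1], tolerance = 1e-10,
                 label = paste("SS", eff))
    expect_equal(mine$ss_error[i], stratum["Sum Sq"][[1]][2],
                 tolerance = 1e-10, label = paste("SS error", eff))
    expect_equal(mine$F[i], stratum["F value"][[1]][1], tolerance = 1e-10)
    expect_equal(mine$p[i], stratum["Pr(>F)"][[1]][1], tolerance = 1e-10)
  }
  # sum-of-squares conservation: total = subject + all effects + errors
  obj <- rm_anova(d, "y", c("A", "B", "C"), "s")
  expect_equal(obj$ss_subject + sum(mine$ss) + sum(mine$ss_error),
               obj$ss_total, tolerance = 1e-8)
})

test_that("two-level within factor: F equals the squared paired t", {
  set.seed(5)
  d <- tidyr::expand_grid(s = 1:12, A = c("a", "b"))
  d$y <- rnorm(24) + (d$A == "b") * 0.6
  row <- tidy(rm_anova(d, "y", "A", "s"))
  tt <- t.test(d$y[d$A == "a"], d$y[d$A == "b"], paired = TRUE)
  expect_equal(row$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(row$gg_epsilon, 1)  # forced for 2 levels
  expect_true(is.na(row$mauchly_p))
})

test_that("degenerate and invalid rm_anova inputs are handled", {
  d <- tidyr::expand_grid(s = 1:8, phase = c("IP", "NCP", "RP"))
  d$y <- 1
  row <- tidy(rm_anova(d, "y", "phase", "s"))
  expect_equal(row$F, 0)
  expect_equal(row$ss, 0)
  expect_error(rm_anova(d[-1, ], "y", "phase", "s"),
               class = "dyadsync_input_error")
  expect_error(rm_anova(dplyr::filter(d, s < 3), "y", "phase", "s"),
               class = "dyadsync_input_error")
})

test_that("Greenhouse-Geisser epsilon and Mauchly react to nonsphericity", {
  set.seed(31)
  n <- 40
  base <- rnorm(n)
  d <- tibble::tibble(
    s = rep(1:n, each = 3),
    phase = rep(c("IP", "NCP", "RP"), n),
    y = c(rbind(base + rnorm(n, sd = 0.1),    # IP ~ NCP strongly correlated
                base + rnorm(n, sd = 0.1),
                rnorm(n, sd = 3))))           # RP independent, inflated
  row <- tidy(rm_anova(d, "y", "phase", "s"))
  expect_lt(row$gg_epsilon, 0.8)
  expect_lt(row$mauchly_p, 0.05)
  expect_identical(row$p_reported, row$p_gg)
  expect_true(row$p_gg >= 0 && row$p_gg <= 1 && row$p_gg != row$p)
})

test_that("Bonferroni post hocs multiply p by the number of pairs, capped", {
  set.seed(12)
  d <- tidyr::expand_grid(s = 1:10, phase = c("IP", "NCP", "RP"))
  d$y <- rnorm(30) + (d$phase == "NCP") * 1.2
  ph <- bonferroni_posthoc(d, "y", "phase", "s")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p * 3))
  expect_true(all(ph$p_adj <= 1))
  expect_error(bonferroni_posthoc(dplyr::filter(d, phase == "IP"),
                                  "y", "phase", "s"),
               class = "dyadsync_input_error")
})

test_that("one-way ANOVA matches the hand-computed oracle", {
  d <- tibble::tibble(y = c(1, 2, 3, 7, 8, 9), g = rep(1:2, each = 3))
  out <- oneway_anova(d, "y", "g")
  expect_equal(out$F, 54)
  expect_equal(out$p, pf(54, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(out$p, 0.00182, tolerance = 0.01)
  expect_equal(out$eta_sq, 54 / 58)
  # equal group means
  d2 <- tibble::tibble(y = c(1, 2, 3, 1, 2, 3), g = rep(1:2, each = 3))
  expect_lt(oneway_anova(d2, "y", "g")$F, 1e-10)
  expect_error(oneway_anova(dplyr::filter(d, g == 1), "y", "g"),
               class = "dyadsync_input_error")
  # cross-check against stats::oneway.test on random data
  set.seed(2)
  d3 <- tibble::tibble(y = rnorm(30), g = rep(1:3, 10))
  ot <- stats::oneway.test(y ~ factor(g), data = d3, var.equal = TRUE)
  expect_equal(oneway_anova(d3, "y", "g")$F, unname(ot$statistic),
               tolerance = 1e-10)
})

test_that("power analysis reaches the target minimally and monotonically", {
  n <- required_sample_size(f = 0.38, alpha = 0.05, power = 0.95,
                            k = 2, m = 2, rho = 0.5, epsilon = 1)
  expect_gte(rm_power(n), 0.95)
  expect_lt(rm_power(n - 2), 0.95)   # minimality over multiples of k
  expect_true(n %% 2 == 0)
  # doubling f strictly decreases the requirement
  expect_lt(required_sample_size(f = 0.76), n)
  expect_error(required_sample_size(f = -1), class = "dyadsync_config_error")
  expect_error(required_sample_size(rho = 1), class = "dyadsync_config_error")
})

test_that("distribution screening computes moments and flags", {
  set.seed(99)
  x <- rnorm(10000)
  out <- screen_distribution(x)
  expect_equal(out$skewness, 0, tolerance = 0.07)
  expect_equal(out$kurtosis, 0, tolerance = 0.15)
  expect_false(out$flag)
  expect_true(screen_distribution(c(rep(0, 30), 40))$flag)
  expect_error(screen_distribution(c(1, 2, 3)), class = "dyadsync_input_error")
  expect_error(screen_distribution(rep(1, 10)), class = "dyadsync_input_error")
})
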