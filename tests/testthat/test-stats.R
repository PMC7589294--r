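# Mixed-model fitting, likelihood-ratio tests, ANOVA/Tukey, chi-squared and
# correlation layer.

# Small repeated-measures design: participants x (time, position, g) grid.
toy_design <- function(n_part, times = c(60, 180, 300),
                       pos = c(2, 1, 0), g = c(1.0, 2.4)) {
  d <- expand.grid(participant = seq_len(n_part), time = times,
                   position_code = pos, g_foot = g)
  d$participant <- factor(d$participant)
  d
}

test_that("null data recover zero fixed effects within 3 SE", {
  set.seed(101)
  d <- toy_design(12)
  b <- rnorm(12, 0, 2)
  d$delta <- b[as.integer(d$participant)] + rnorm(nrow(d), 0, 1)
  fit <- fit_lmm(d)
  fe <- fit$fixed_effects
  nonint <- fe$term != "(Intercept)"
  expect_true(all(abs(fe$estimate[nonint]) < 3 * fe$sd[nonint]))
  expect_true(fit$sigma_b >= 0 && fit$sigma_e > 0)
  expect_true(is.finite(fit$logLik))
})

test_that("with no participant variance the fit reduces to OLS", {
  set.seed(7)
  d <- toy_design(6, times = c(0, 100), pos = c(0, 2), g = 2.4)
  d$delta <- 1 + 0.01 * d$time - 0.5 * d$position_code +
    rnorm(nrow(d), 0, 0.3)
  fit <- suppressMessages(fit_lmm(d, fixed = c("time", "position_code")))
  ols <- lm(delta ~ time * position_code, data = d)
  expect_lt(max(abs(fit$fixed_effects$estimate - coef(ols))), 1e-4)
})

test_that("rank-deficient designs fail loudly, naming the collinear term", {
  d <- toy_design(4)
  d$delta <- rnorm(nrow(d))
  d$pos2 <- 2 * d$position_code
  err <- tryCatch(fit_lmm(d, fixed = c("position_code", "pos2")),
                  error = function(e) e)
  expect_s3_class(err, "sahc_rank_deficient")
  expect_match(conditionMessage(err), "pos2")
})

test_that("the LRT matches its degrees of freedom and degenerate limits", {
  set.seed(33)
  d <- toy_design(8)
  d$delta <- rnorm(8, 0, 1)[as.integer(d$participant)] +
    2.5 * d$g_foot + rnorm(nrow(d), 0, 1)
  full <- fit_lmm(d)
  red <- fit_lmm(d, fixed = c("time", "position_code"))
  r <- lrt(full, red)
  # dropping g and its interactions removes 4 of the 8 fixed parameters
  expect_equal(r$df, 4)
  expect_gt(r$statistic, 0)
  expect_lt(r$p, 0.001)  # strong simulated effect

  same <- lrt(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  expect_error(lrt(red, full), class = "sahc_not_nested")
})

test_that("the LRT statistic is invariant to affine response rescaling", {
  set.seed(12)
  d <- toy_design(6)
  d$delta <- rnorm(6, 0, 1)[as.integer(d$participant)] +
    0.4 * d$position_code + rnorm(nrow(d), 0, 1)
  s1 <- lrt_effect(d, "position_code")$statistic
  d$delta <- 7.3 * d$delta - 11
  s2 <- lrt_effect(d, "position_code")$statistic
  expect_equal(s1, s2, tolerance = 1e-5)
})

test_that("ANOVA F matches the hand-computed three-group example", {
  # groups (1,2,3), (2,3,4), (6,7,8): SSB = 42 (df 2), SSW = 6 (df 6), F = 21
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("A", "B", "C"), each = 3)
  res <- epoch_anova_tukey(v, g)
  expect_equal(res$F, 21, tolerance = 1e-10)
  expect_lt(res$p, 0.01)
  expect_equal(nrow(res$tukey), 3)

  # identical groups: no between-group variance
  res0 <- epoch_anova_tukey(rep(c(1, 2, 3), 3), rep(c("A", "B", "C"), each = 3))
  expect_equal(res0$F, 0, tolerance = 1e-12)
})

test_that("Tukey comparisons flag a shifted group and are label-symmetric", {
  set.seed(5)
  v <- c(rnorm(6, 0, 0.1), rnorm(6, 0, 0.1), rnorm(6, 10, 0.1))
  g <- rep(c("P1", "P2", "P3"), each = 6)
  res <- epoch_anova_tukey(v, g)
  tk <- res$tukey
  expect_lt(tk$p_adj[tk$comparison == "P3-P1"], 0.001)
  expect_gt(tk$p_adj[tk$comparison == "P2-P1"], 0.05)
  # relabelling the groups flips the sign but not the interval width
  res2 <- epoch_anova_tukey(v, rep(c("P3", "P2", "P1"), each = 6))
  a <- tk[tk$comparison == "P3-P1", ]
  b <- res2$tukey[res2$tukey$comparison == "P3-P1", ]
  expect_equal(b$diff, -a$diff, tolerance = 1e-10)
  expect_equal(b$upr - b$lwr, a$upr - a$lwr, tolerance = 1e-10)

  expect_error(epoch_anova_tukey(1:3, c("A", "A", "B")),
               class = "sahc_insufficient_data")
})

test_that("chi-squared matches the hand formula and its edge cases", {
  # (10,0 / 5,5): expected (7.5, 2.5 / 7.5, 2.5) -> sum (O-E)^2/E = 20/3
  res <- pss_chi_squared(matrix(c(10, 5, 0, 5), 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$df, 1)

  eq <- pss_chi_squared(matrix(c(8, 8, 8, 12, 12, 12), 3))
  expect_equal(eq$statistic, 0, tolerance = 1e-12)

  expect_error(pss_chi_squared(matrix(c(0, 0, 5, 5), 2)),
               class = "sahc_invalid_parameter")
  expect_error(pss_chi_squared(matrix(c(-1, 2, 3, 4), 2)),
               class = "sahc_invalid_parameter")
})

test_that("Pearson correlations behave on exact and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(delta_correlation(x, 2 * x)$r, 1, tolerance = 1e-12)
  set.seed(9)
  y <- -x + rnorm(5, 0, 1e-8)
  expect_equal(delta_correlation(x, y)$r, -1, tolerance = 1e-6)
  expect_error(delta_correlation(x, rep(1, 5)),
               class = "sahc_undefined_correlation")
  expect_error(delta_correlation(1:2, 2:1), class = "sahc_insufficient_data")
})

test_that("position codes follow the heart-to-crown distance convention", {
  expect_equal(position_code(c("P1", "P2", "P3")), c(2, 1, 0))
})
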