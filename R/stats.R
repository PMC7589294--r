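## Inference layer: random-intercept linear mixed models fitted by maximum
## likelihood with likelihood-ratio tests, per-epoch one-way ANOVA + Tukey
## HSD, chi-squared tests of PSS frequency and Pearson correlations.

#' Numeric position code
#'
#' Axis position expressed as a multiple of the heart-to-crown distance from
#' the rotation axis: heart-level axis (P3) = 0, crown (P2) = 1, above-head
#' (P1) = 2 for the trial's 0.49 m overhead offset.
#'
#' @param position character vector of `"P1"`, `"P2"`, `"P3"`.
#' @return numeric codes.
#' @export
position_code <- function(position) {
  unname(c(P1 = 2, P2 = 1, P3 = 0)[position])
}

#' Assemble a long epoch-delta table for model fitting
#'
#' Stacks per-run epoch deltas into the long format consumed by [fit_lmm()]:
#' one row per run x channel x epoch with the participant, numeric position
#' code and foot-level g attached.  `time` is the epoch midpoint in seconds
#' from the start of the run phase.
#'
#' @param preps list of `sahc_prep` objects (see [preprocess_run()]).
#' @return data frame with columns `participant`, `run`, `channel`, `epoch`,
#'   `phase`, `time`, `position`, `position_code`, `g_foot`, `delta`.
#' @export
long_delta_table <- function(preps) {
  rows <- lapply(preps, function(p) {
    d <- p$deltas
    if (nrow(d) == 0) return(NULL)
    data.frame(participant = p$meta$participant, run = p$meta$run_id,
               channel = d$channel, epoch = d$epoch, phase = d$phase,
               time = (d$t_start + d$t_end) / 2,
               position = p$meta$position,
               position_code = position_code(p$meta$position),
               g_foot = p$meta$g_foot, delta = d$delta)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a random-intercept linear mixed model
#'
#' Fits `value ~ time * position * g` with per-participant random intercepts
#' by maximum likelihood (ML, not REML, so that likelihood-ratio tests
#' between models differing in fixed effects are valid).  Any subset of the
#' three covariates may be supplied via `fixed`.
#'
#' @param data data frame with columns `participant`, the response named in
#'   `response`, and the covariates named in `fixed`.
#' @param response response column name (default `"delta"`).
#' @param fixed character vector of fixed-effect covariates; all two- and
#'   three-way interactions among them are included.
#' @return object of class `sahc_lmm`: `fit` (the underlying `lmerMod`),
#'   `fixed_effects` (data frame `term`, `estimate`, `sd`), `sigma_b`
#'   (random-intercept SD), `sigma_e` (residual SD), `logLik`, `n_par`,
#'   `formula`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_participants = 4, seed = 7)
#' trial <- generate_trial(cfg, channels = "HR")
#' preps <- lapply(trial$runs, preprocess_run)
#' tab <- long_delta_table(preps)
#' fit_lmm(tab[tab$channel == "HR" & tab$phase == "run", ],
#'         fixed = c("time", "position_code", "g_foot"))
#' }
#' @export
fit_lmm <- function(data, response = "delta",
                    fixed = c("time", "position_code", "g_foot")) {
  data <- data[stats::complete.cases(data[, c(response, fixed, "participant")]), ]
  if (length(unique(data$participant)) < 2)
    sahc_error("sahc_insufficient_data", "need >= 2 participants")
  rhs <- paste(fixed, collapse = " * ")
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 | participant)"))
  X <- model.matrix(stats::as.formula(paste("~", rhs)), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    sahc_error("sahc_rank_deficient",
               paste("fixed-effect design is rank deficient; collinear terms:",
                     paste(bad, collapse = ", ")))
  }
  fit <- suppressMessages(lme4::lmer(fml, data = data, REML = FALSE))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fit = fit,
    fixed_effects = data.frame(term = names(fe), estimate = unname(fe),
                               sd = unname(se)),
    sigma_b = vc$sdcor[vc$grp == "participant"],
    sigma_e = vc$sdcor[vc$grp == "Residual"],
    logLik = as.numeric(logLik(fit)),
    n_par = attr(logLik(fit), "df"),
    formula = fml, fixed = fixed, response = response),
    class = "sahc_lmm")
}

#' @export
print.sahc_lmm <- function(x, ...) {
  cat("Random-intercept LMM (ML):", deparse(x$formula), "\n")
  print(x$fixed_effects, digits = 4)
  cat(sprintf("sigma_b = %.4g, sigma_e = %.4g, logLik = %.3f (%d par)\n",
              x$sigma_b, x$sigma_e, x$logLik, x$n_par))
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' `statistic = 2 * (logLik_full - logLik_reduced)`, degrees of freedom equal
#' to the parameter-count difference, p-value from the upper chi-squared
#' tail.  The reduced model's fixed terms must be a subset of the full
#' model's.
#'
#' @param full,reduced `sahc_lmm` fits of nested models on the same data.
#' @return list of class `lrt_result`: `effect` (terms dropped), `statistic`,
#'   `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  tf <- attr(terms(stats::as.formula(
    paste("~", paste(full$fixed, collapse = " * ")))), "term.labels")
  tr <- attr(terms(stats::as.formula(
    paste("~", paste(reduced$fixed, collapse = " * ")))), "term.labels")
  if (!all(tr %in% tf) || full$n_par < reduced$n_par)
    sahc_error("sahc_not_nested", "reduced model is not nested in the full model")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$n_par - reduced$n_par
  # df 0 (identical models): the LRT is degenerate and never rejects
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  structure(list(effect = paste(setdiff(tf, tr), collapse = ", "),
                 statistic = stat, df = df, p = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT [%s]: chi2 = %.3f, df = %d, p = %.4g\n",
              x$effect, x$statistic, x$df, x$p))
  invisible(x)
}

#' Likelihood-ratio test for one covariate
#'
#' Fits the full model and the reduced model obtained by dropping `effect`
#' and every interaction containing it, and returns the LRT.
#'
#' @inheritParams fit_lmm
#' @param effect one of the entries of `fixed`.
#' @return a `lrt_result` with the two fits attached (`full`, `reduced`).
#' @export
lrt_effect <- function(data, effect, response = "delta",
                       fixed = c("time", "position_code", "g_foot")) {
  if (!effect %in% fixed)
    sahc_error("sahc_invalid_parameter",
               sprintf("'%s' is not among the fixed effects", effect))
  full <- fit_lmm(data, response, fixed)
  reduced <- fit_lmm(data, response, setdiff(fixed, effect))
  out <- lrt(full, reduced)
  out$full <- full; out$reduced <- reduced
  out
}

#' One-way ANOVA with Tukey HSD across positions at one epoch
#'
#' Per-epoch secondary analysis: a one-way ANOVA of the epoch deltas on a
#' grouping factor (position), followed by Tukey honestly-significant-
#' difference pairwise comparisons based on the studentized range.
#'
#' @param value numeric responses (epoch deltas).
#' @param group grouping factor (e.g. position), >= 2 levels with >= 2
#'   observations each.
#' @param conf_level confidence level of the Tukey intervals.
#' @return list of class `anova_tukey`: `F`, `df`, `p`, `tukey` (data frame
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
epoch_anova_tukey <- function(value, group, conf_level = 0.95) {
  group <- factor(group)
  tab <- table(group)
  if (length(tab) < 2 || any(tab < 2))
    sahc_error("sahc_insufficient_data",
               "need >= 2 groups with >= 2 observations each")
  d <- data.frame(value = value, group = group)
  fit <- aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = conf_level)$group
  structure(list(F = s[["F value"]][1], df = s[["Df"]],
                 p = s[["Pr(>F)"]][1],
                 tukey = data.frame(comparison = rownames(tk),
                                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                    row.names = NULL)),
            class = "anova_tukey")
}

#' Chi-squared test of PSS+ frequency across positions
#'
#' Pearson chi-squared test (no continuity correction) on the PSS+/PSS-
#' contingency table by position.
#'
#' @param counts a matrix or table with one row per position and two columns
#'   (PSS+ and PSS- counts), or a data frame with columns `position`,
#'   `pss_pos`, `pss_neg`.
#' @return list: `statistic`, `df`, `p`, `expected`.
#' @export
pss_chi_squared <- function(counts) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, c("pss_pos", "pss_neg")])
    rownames(m) <- counts$position
  } else m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m)))
    sahc_error("sahc_invalid_parameter", "counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    sahc_error("sahc_invalid_parameter", "contingency table has an all-zero margin")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Pearson correlation between two channels' end-of-run deltas
#'
#' Product-moment correlation (two-sided test) between paired final-run-epoch
#' deltas across runs, e.g. calf-circumference change versus heart-rate
#' change pooled over positions and g-levels.
#'
#' @param x,y paired numeric vectors (>= 3 pairs).
#' @return list: `r`, `p`, `n`.
#' @export
delta_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    sahc_error("sahc_insufficient_data", "need >= 3 paired points")
  if (var(x) == 0 || var(y) == 0)
    sahc_error("sahc_undefined_correlation",
               "correlation undefined: zero variance in one variable")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Final-run-epoch deltas of every run
#'
#' Extracts each run's delta in the last run-phase epoch ("minute 10") for
#' the requested channels, the quantity summarised in end-of-run response
#' tables and correlation plots.
#'
#' @param preps list of `sahc_prep` objects.
#' @param channels channels to extract (default: all present).
#' @return data frame: `participant`, `run`, `position`, `g_foot`, `channel`,
#'   `delta`.
#' @export
final_run_deltas <- function(preps, channels = NULL) {
  rows <- lapply(preps, function(p) {
    d <- p$deltas[p$deltas$phase == "run", ]
    if (nrow(d) == 0) return(NULL)
    d <- d[d$epoch == max(d$epoch), ]
    if (!is.null(channels)) d <- d[d$channel %in% channels, ]
    if (nrow(d) == 0) return(NULL)
    data.frame(participant = p$meta$participant, run = p$meta$run_id,
               position = p$meta$position, g_foot = p$meta$g_foot,
               channel = d$channel, delta = d$delta)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
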