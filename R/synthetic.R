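## Synthetic cohort and run generator.  Emulates the trial's structure —
## 15 participants x 3 axis positions x 3 foot-level g (1.0/1.7/2.4), the
## five-phase profile (10 min baseline, 120 s ramps, 10 min run, 10 min
## recovery), per-participant random intercepts, position/g-dependent
## response magnitudes calibrated to the published end-of-run deltas,
## measurement noise, injected artifacts and pre-syncope events — with full
## ground truth for recovery testing.

#' Default channel response parameters
#'
#' One row per channel: baseline level, native sampling rate, measurement
#' noise SD, between-participant baseline SD (`base_sd`), end-of-run delta
#' means at 2.4 g for the three axis positions (`eff_P1..eff_P3`) and their
#' between-run SDs (`sd_P1..sd_P3`).  The effect means and SDs are the
#' published tenth-minute responses at +2.4 Gz (e.g. HR +50.0/+24.0/+8.0
#' bpm, CC +5.46/+4.11/+2.23 mm, cTSI -2.85/-1.88/-0.95% for P1/P2/P3);
#' baselines, noise and baseline SDs are realistic values for resting,
#' supine adults chosen here (the source trial reports deltas only).
#'
#' @return data frame, one row per channel.
#' @export
channel_params <- function() {
  data.frame(
    channel = c("HR", "MAP", "SV", "TPR", "CO", "CC", "cTSI"),
    baseline = c(65, 85, 80, 1150, 5.5, 350, 68),
    rate_hz = c(1, 1, 1, 1, 1, 10, 10),
    noise_sd = c(2, 2, 3, 50, 0.25, 0.3, 0.4),
    base_sd = c(6, 6, 8, 150, 0.6, 15, 3),
    eff_P1 = c(50.0, 4.43, -37.7, 204, -0.64, 5.46, -2.85),
    eff_P2 = c(24.0, 4.60, -27.2, 223, -0.59, 4.11, -1.88),
    eff_P3 = c(8.0, -3.87, -19.4, 169, -0.69, 2.23, -0.95),
    sd_P1 = c(15.5, 18.10, 12.0, 290, 1.32, 2.09, 1.86),
    sd_P2 = c(11.62, 9.10, 9.30, 205, 0.77, 2.44, 1.43),
    sd_P3 = c(7.75, 3.25, 6.58, 136, 0.39, 1.63, 1.32))
}

#' Simulation configuration
#'
#' Parameters of the synthetic trial.  The defaults are the study
#' conditions: n = 15 participants (the number of complete data sets in the
#' trial), positions P1/P2/P3, foot-level g 1.0/1.7/2.4, the five-phase
#' schedule, and channel effects calibrated to the published tenth-minute
#' deltas at +2.4 Gz (see [channel_params()]).  Effects scale linearly with
#' foot-level g (zero at zero g).  The between-run delta SD at each position
#' is split into a per-participant responsiveness intercept
#' (`between_frac`, SD fraction 0.6) and run-to-run variation (the
#' complementary fraction), both scaling with g like the mean.
#'
#' Pre-syncope events follow a per-run logistic probability
#' `plogis(pss_intercept + pss_g_coef * g + pss_pos_coef * offset)` with
#' `offset` 0/1/2 for P1/P2/P3, so PSS+ probability increases with g and
#' decreases from P1 to P3.  A configurable fraction of PSS+ runs carries a
#' synthesized concurrent HR/MAP drop (exercising the signal criterion);
#' the remainder split between symptom events and run termination.
#'
#' @param n_participants cohort size.
#' @param positions,g_levels trial factors.
#' @param phases a [phase_schedule()].
#' @param channels a [channel_params()] data frame.
#' @param between_frac fraction of the delta SD attributed to the
#'   per-participant responsiveness intercept.
#' @param artifact_rate per-sample probability of an injected out-of-range
#'   spike.
#' @param pss_intercept,pss_g_coef,pss_pos_coef logistic PSS model
#'   coefficients.
#' @param pss_signal_fraction,pss_symptom_fraction fractions of PSS+ runs
#'   realised as an HR/MAP drop trace and as a symptom event; the remainder
#'   are terminations.
#' @param drop_hr,drop_map amplitude (bpm, mmHg) of the synthesized
#'   concurrent drop.
#' @param tau_s time constant of the exponential approach to the run-phase
#'   plateau (s).
#' @param onset_frac fraction of the plateau response reached by the end of
#'   ramp-up.
#' @param stature_mean,stature_sd cohort stature distribution (m).
#' @param seed root seed; all run-level randomness derives from it through
#'   named substreams.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 15,
                       positions = c("P1", "P2", "P3"),
                       g_levels = c(1.0, 1.7, 2.4),
                       phases = phase_schedule(),
                       channels = channel_params(),
                       between_frac = 0.6,
                       artifact_rate = 0.01,
                       pss_intercept = -3.2, pss_g_coef = 1.5,
                       pss_pos_coef = -1.2,
                       pss_signal_fraction = 0.4,
                       pss_symptom_fraction = 0.4,
                       drop_hr = 30, drop_map = 25,
                       tau_s = 60, onset_frac = 0.5,
                       stature_mean = 1.73, stature_sd = 0.08,
                       seed = 1) {
  if (n_participants < 2)
    sahc_error("sahc_invalid_parameter", "need n_participants >= 2")
  structure(as.list(environment()), class = "sim_config")
}

## Deterministic per-run substream seed below 2^31.
run_seed <- function(root, pid, pos_idx, g_idx, salt = 0) {
  (as.numeric(root) * 100003 + pid * 9973 + pos_idx * 101 + g_idx * 7 +
     salt) %% 2147483647
}

#' Generate a synthetic cohort
#'
#' Draws participant statures around the trial's 1.73 +/- 0.08 m and the
#' per-participant random intercepts: a baseline offset and a responsiveness
#' offset for every channel.  Deterministic given the configuration seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sahc_cohort`: `participants` (data frame `id`,
#'   `stature`), `baseline_intercepts` and `response_intercepts`
#'   (participant x channel matrices).
#' @export
generate_cohort <- function(config) {
  ch <- config$channels
  with_seed(run_seed(config$seed, 0, 0, 0), {
    stature <- rnorm(config$n_participants, config$stature_mean,
                     config$stature_sd)
    base_i <- matrix(rnorm(config$n_participants * nrow(ch)),
                     config$n_participants, nrow(ch))
    resp_i <- matrix(rnorm(config$n_participants * nrow(ch)),
                     config$n_participants, nrow(ch))
  })
  base_i <- sweep(base_i, 2, ch$base_sd, `*`)
  # responsiveness intercept SD: between_frac of the mid-position delta SD
  resp_i <- sweep(resp_i, 2, config$between_frac * ch$sd_P2, `*`)
  colnames(base_i) <- colnames(resp_i) <- ch$channel
  structure(list(
    participants = data.frame(id = seq_len(config$n_participants),
                              stature = stature),
    baseline_intercepts = base_i,
    response_intercepts = resp_i), class = "sahc_cohort")
}

## Deterministic response trajectory: 0 at baseline, linear rise to
## onset_frac*delta over ramp-up, exponential approach to the plateau during
## the run, linear fall back to onset_frac*delta over ramp-down and
## exponential decay to 0 in recovery.
response_trajectory <- function(t, delta, phases, tau, onset_frac) {
  m <- numeric(length(t))
  ru <- t >= phases$rampup_start & t < phases$run_start
  m[ru] <- delta * onset_frac *
    (t[ru] - phases$rampup_start) / (phases$run_start - phases$rampup_start)
  rn <- t >= phases$run_start & t < phases$rampdown_start
  m[rn] <- delta * (1 - (1 - onset_frac) * exp(-t[rn] / tau))
  m_end <- delta * (1 - (1 - onset_frac) *
                      exp(-phases$rampdown_start / tau))
  rd <- t >= phases$rampdown_start & t < phases$recovery_start
  frac <- (t[rd] - phases$rampdown_start) /
    (phases$recovery_start - phases$rampdown_start)
  m[rd] <- m_end + (delta * onset_frac - m_end) * frac
  rc <- t >= phases$recovery_start
  m[rc] <- delta * onset_frac * exp(-(t[rc] - phases$recovery_start) / tau)
  m
}

## Position effect interpolated linearly in g: effect(g) = effect_2.4 * g/2.4.
effect_at <- function(eff_24, g) eff_24 * g / 2.4

## Autocorrelated measurement noise (AR(1), correlation time ~2 s, unit
## marginal SD).  Physiological noise — beat-to-beat variability, NIRS and
## plethysmograph drift — is smooth at the sampling rates used here; white
## noise would make consecutive-sample jumps that the artifact change rule
## rightly treats as glitches.
ar_noise <- function(n, dt, tau = 2) {
  rho <- exp(-dt / tau)
  e <- rnorm(n)
  if (n == 1) return(e)
  as.numeric(stats::filter(c(e[1], sqrt(1 - rho^2) * e[-1]), rho,
                           method = "recursive"))
}

#' Generate one synthetic centrifuge run
#'
#' Produces the multi-channel time series of a single run: channel baseline
#' + participant baseline intercept + a smooth response trajectory whose
#' final-run-epoch mean equals the configured delta (position effect scaled
#' linearly in g, plus the participant responsiveness intercept and a
#' run-level deviation), additive Gaussian noise, out-of-range artifact
#' spikes, and — for PSS+ runs — either a synthesized concurrent HR/MAP
#' drop, a symptom event or a termination flag.  Bit-for-bit reproducible
#' from (config, participant, position, g).
#'
#' @param cohort a [generate_cohort()] result.
#' @param participant participant id (row of the cohort).
#' @param position `"P1"`, `"P2"` or `"P3"`.
#' @param g_foot foot-level g, one of `config$g_levels`.
#' @param config a [sim_config()].
#' @param channels optional subset of channel names to generate.
#' @return list of class `sahc_run`: `meta` (`run_id`, `participant`,
#'   `position`, `g_foot`), `phases`, `channels` (named list of data frames
#'   `time`, `value`), `events`, `terminated`, `termination_time`, `truth`
#'   (true deltas, PSS label/criterion, intercepts).
#' @export
generate_run <- function(cohort, participant, position, g_foot, config,
                         channels = NULL) {
  pos_idx <- match(position, config$positions)
  g_idx <- match(g_foot, config$g_levels)
  if (is.na(pos_idx) || is.na(g_idx))
    sahc_error("sahc_invalid_parameter",
               sprintf("unknown position '%s' or g level %s", position,
                       format(g_foot)))
  ch <- config$channels
  if (!is.null(channels)) ch <- ch[ch$channel %in% channels, , drop = FALSE]
  phases <- config$phases
  eff_col <- paste0("eff_", position)
  sd_col <- paste0("sd_", position)
  lim <- default_limits()

  with_seed(run_seed(config$seed, participant, pos_idx, g_idx), {
    ## PSS outcome
    p_pss <- plogis(config$pss_intercept + config$pss_g_coef * g_foot +
                      config$pss_pos_coef * (pos_idx - 1))
    pss <- runif(1) < p_pss
    crit <- "none"; drop_start <- NA_real_
    events <- data.frame(time = numeric(), label = character())
    terminated <- FALSE; term_time <- NA_real_
    if (pss) {
      u <- runif(1)
      if (u < config$pss_signal_fraction) {
        crit <- "hr_bp_drop"
        # drop + rebound (40 s) end before the final run epoch [480, 600)
        drop_start <- runif(1, 60, 430)
      } else if (u < config$pss_signal_fraction +
                 config$pss_symptom_fraction) {
        crit <- "symptom"
        events <- data.frame(
          time = runif(1, 60, 560),
          label = sample(c("nausea", "paleness", "dizziness"), 1))
      } else {
        crit <- "termination"
        terminated <- TRUE
        term_time <- runif(1, 120, 560)
      }
    }

    ## per-run effect deviations (scale with g like the mean)
    within_sd <- sqrt(pmax(ch[[sd_col]]^2 -
                             (config$between_frac * ch$sd_P2)^2,
                           (0.2 * ch[[sd_col]])^2))
    e_run <- rnorm(nrow(ch), 0, within_sd)

    series <- list(); truth_delta <- numeric(nrow(ch))
    for (i in seq_len(nrow(ch))) {
      name <- ch$channel[i]
      rate <- ch$rate_hz[i]
      if (rate >= 10) {
        t <- seq(phases$baseline_start, phases$recovery_end - 1 / rate,
                 by = 1 / rate)
      } else {
        t <- seq(phases$baseline_start, phases$recovery_end - 1, by = 1)
        t <- t + runif(length(t), 0, 0.35)  # beat-like jitter, still increasing
      }
      delta <- effect_at(ch[[eff_col]][i] +
                           cohort$response_intercepts[participant, name] +
                           e_run[i], g_foot)
      truth_delta[i] <- delta
      base <- ch$baseline[i] + cohort$baseline_intercepts[participant, name]
      v <- base + response_trajectory(t, delta, phases, config$tau_s,
                                      config$onset_frac)
      if (crit == "hr_bp_drop" && name %in% c("HR", "MAP")) {
        amp <- if (name == "HR") config$drop_hr else config$drop_map
        v <- v - amp * pmax(0, pmin((t - drop_start) / 20,
                                    1 - (t - drop_start - 20) / 20,
                                    1))
      }
      v <- v + ch$noise_sd[i] * ar_noise(length(t), 1 / rate)
      if (config$artifact_rate > 0) {
        art <- runif(length(t)) < config$artifact_rate
        if (any(art)) {
          l <- lim[[name]]
          spike <- if (!is.null(l) && is.null(names(l)))
            l[2] + 0.3 * (l[2] - l[1]) else v[art] + 100
          v[art] <- spike
        }
      }
      series[[name]] <- data.frame(time = t, value = v)
    }
  })

  run_id <- sprintf("S%02d_%s_g%.1f", participant, position, g_foot)
  structure(list(
    meta = list(run_id = run_id, participant = participant,
                position = position, g_foot = g_foot),
    phases = phases, channels = series, events = events,
    terminated = terminated, termination_time = term_time,
    truth = list(pss = pss, criterion = crit, drop_start = drop_start,
                 p_pss = p_pss,
                 delta = setNames(truth_delta, ch$channel))),
    class = "sahc_run")
}

#' @export
print.sahc_run <- function(x, ...) {
  cat(sprintf("Run %s: %s at %.1f g; channels: %s%s\n", x$meta$run_id,
              x$meta$position, x$meta$g_foot,
              paste(names(x$channels), collapse = ", "),
              if (isTRUE(x$truth$pss)) sprintf(" [PSS+ %s]", x$truth$criterion)
              else ""))
  invisible(x)
}

#' Generate a full synthetic trial
#'
#' One run per participant x position x g-level (9 runs each; 135 runs at
#' the default n = 15), with the cohort and a ground-truth table.
#'
#' @param config a [sim_config()].
#' @param channels optional subset of channel names to generate.
#' @return list of class `sahc_trial`: `runs` (list of `sahc_run`), `cohort`,
#'   `truth` (data frame: `run_id`, `participant`, `position`, `g_foot`,
#'   `pss`, `criterion`, `p_pss`, and one `delta_<channel>` column per
#'   channel), `config`.
#' @examples
#' \donttest{
#' trial <- generate_trial(sim_config(n_participants = 3, seed = 1),
#'                         channels = c("HR", "MAP"))
#' length(trial$runs)  # 3 x 9 = 27
#' }
#' @export
generate_trial <- function(config, channels = NULL) {
  cohort <- generate_cohort(config)
  runs <- list(); truth <- list()
  for (pid in seq_len(config$n_participants))
    for (pos in config$positions)
      for (g in config$g_levels) {
        r <- generate_run(cohort, pid, pos, g, config, channels)
        runs[[r$meta$run_id]] <- r
        td <- as.list(r$truth$delta)
        names(td) <- paste0("delta_", names(td))
        truth[[r$meta$run_id]] <- data.frame(
          run_id = r$meta$run_id, participant = pid, position = pos,
          g_foot = g, pss = r$truth$pss, criterion = r$truth$criterion,
          p_pss = r$truth$p_pss, td)
      }
  structure(list(runs = runs, cohort = cohort,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 config = config),
            class = "sahc_trial")
}
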