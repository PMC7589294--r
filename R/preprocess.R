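## Channel preprocessing: artifact rejection, validity gating, 4 Hz spline
## resampling and baseline-referenced 2-minute epoch deltas.
##
## Time origin convention: t = 0 at the start of the constant-speed run
## phase.  With the default schedule the baseline occupies [-720, -120) s,
## the 120 s ramp-up [-120, 0), the run [0, 600), the ramp-down [600, 720)
## and the recovery [720, 1320) s.

#' Phase schedule of a centrifuge run
#'
#' Phase boundary times (s) for the five-phase profile: baseline, ramp-up,
#' constant-speed run, ramp-down, recovery.  Defaults are the trial profile:
#' 10 min baseline, 120 s ramps, 10 min run, 10 min recovery.
#'
#' @param baseline_s,ramp_s,run_s,recovery_s phase durations in seconds.
#' @return named list of boundary times: `baseline_start`, `baseline_end`
#'   (= `rampup_start`), `run_start` (0), `rampdown_start`, `recovery_start`,
#'   `recovery_end`.
#' @examples
#' phase_schedule()
#' @export
phase_schedule <- function(baseline_s = 600, ramp_s = 120, run_s = 600,
                           recovery_s = 600) {
  list(baseline_start = -(baseline_s + ramp_s),
       baseline_end = -ramp_s,
       rampup_start = -ramp_s,
       run_start = 0,
       rampdown_start = run_s,
       recovery_start = run_s + ramp_s,
       recovery_end = run_s + ramp_s + recovery_s)
}

#' Default physiological plausibility limits
#'
#' Wide physiologic envelopes intended to remove hardware glitches only, per
#' channel: HR 25-240 bpm, MAP 20-200 mmHg, SV 5-200 ml, TPR 100-6000
#' dyn.s/cm^5, cTSI 0-100%, CO 0.5-15 l/min.  Calf circumference (CC) uses a
#' relative limit of +/- 30 mm around the channel's early-record level,
#' resolved at scan time by [preprocess_run()].
#'
#' @return named list of `c(min, max)` pairs; the CC entry is the half-width
#'   of the relative band.
#' @export
default_limits <- function() {
  list(HR = c(25, 240), MAP = c(20, 200), SV = c(5, 200),
       TPR = c(100, 6000), cTSI = c(0, 100), CO = c(0.5, 15),
       CC = c(rel = 30))
}

#' Frame-wise artifact scan of one channel
#'
#' Flags a sample invalid when it falls outside the plausibility limits or
#' when its change from the previous valid sample exceeds `max_sd_multiple`
#' times the channel's whole-record standard deviation (computed over
#' in-limit samples so that spikes do not inflate their own threshold).  A
#' sample that agrees with its immediate raw predecessor is never flagged by
#' the change rule, so a single level shift costs one sample rather than
#' cascading until the signal returns to its old level.  Validity is
#' additionally summarised over consecutive 10 s inspection frames.
#'
#' @param time sample times (s), strictly increasing.
#' @param value sample values.
#' @param limits `c(min, max)` plausibility limits.
#' @param max_sd_multiple maximal allowed jump between consecutive valid
#'   samples, in whole-record SDs (default 3).
#' @param frame_s inspection frame length in seconds (default 10).
#' @return list of class `artifact_mask`: `valid` (logical, per sample),
#'   `frames` (data frame `frame_start`, `n`, `fraction_valid`),
#'   `fraction_valid` (overall).
#' @export
scan_artifacts <- function(time, value, limits, max_sd_multiple = 3,
                           frame_s = 10) {
  if (length(value) == 0)
    sahc_error("sahc_empty_input", "empty channel series")
  if (length(time) != length(value))
    sahc_error("sahc_schema_error", "time and value lengths differ")
  if (max_sd_multiple <= 0)
    sahc_error("sahc_invalid_parameter", "max_sd_multiple must be positive")
  in_lim <- is.finite(value) & value >= limits[1] & value <= limits[2]
  s <- if (sum(in_lim) > 1) sd(value[in_lim]) else NA_real_
  max_step <- if (is.finite(s)) max_sd_multiple * s else Inf
  valid <- artifact_scan_cpp(as.numeric(value), limits[1], limits[2], max_step)
  frame <- as.integer(floor((time - time[1]) / frame_s)) + 1L
  n_per <- tabulate(frame, nbins = max(frame))
  v_per <- tabulate(frame[valid], nbins = max(frame))
  keep <- n_per > 0
  frames <- data.frame(
    frame_start = time[1] + (which(keep) - 1L) * frame_s,
    n = n_per[keep],
    fraction_valid = v_per[keep] / n_per[keep])
  structure(list(valid = valid, frames = frames,
                 fraction_valid = mean(valid)),
            class = "artifact_mask")
}

#' Fraction of valid samples in an artifact mask
#'
#' @param mask an `artifact_mask` from [scan_artifacts()], or a logical
#'   vector of validity flags.
#' @return fraction in \[0, 1\].
#' @export
validity_fraction <- function(mask) {
  if (inherits(mask, "artifact_mask")) mean(mask$valid) else mean(mask)
}

#' Resample a gated channel to a uniform grid by cubic splines
#'
#' Fits a piecewise cubic spline (Forsythe-Malcolm-Moler end conditions,
#' exact for cubic polynomials) through the valid samples only and evaluates
#' it on a uniform grid (default 4 Hz) aligned to multiples of the sampling
#' interval and spanning no more than the valid time range (no
#' extrapolation).  Channels with more than 5% artifacts are rejected rather
#' than resampled.
#'
#' @param time,value raw channel samples.
#' @param mask `artifact_mask` or logical validity vector.
#' @param rate target sampling rate in Hz (default 4).
#' @param min_valid minimum validity fraction for acceptance (default 0.95,
#'   strict: fraction must exceed it).
#' @return list of class `clean_channel`: `time`, `value`, `rate`,
#'   `artifact_fraction`.
#' @export
resample_clean <- function(time, value, mask, rate = 4, min_valid = 0.95) {
  valid <- if (inherits(mask, "artifact_mask")) mask$valid else mask
  frac <- mean(valid)
  if (!(frac > min_valid))
    sahc_error("sahc_channel_rejected",
               sprintf("channel rejected: validity %.3f <= %.2f",
                       frac, min_valid))
  tv <- time[valid]; vv <- value[valid]
  if (length(tv) < 4)
    sahc_error("sahc_insufficient_data",
               "need at least 4 valid samples for spline resampling")
  dt <- 1 / rate
  t0 <- ceiling(round(tv[1] / dt, 7)) * dt
  t1 <- floor(round(tv[length(tv)] / dt, 7)) * dt
  grid <- seq(t0, t1, by = dt)
  f <- splinefun(tv, vv, method = "fmm")
  structure(list(time = grid, value = f(grid), rate = rate,
                 artifact_fraction = 1 - frac),
            class = "clean_channel")
}

#' @export
print.clean_channel <- function(x, ...) {
  cat(sprintf("Clean channel: %d samples at %g Hz, t in [%.2f, %.2f] s, artifact fraction %.3f\n",
              length(x$time), x$rate, x$time[1], x$time[length(x$time)],
              x$artifact_fraction))
  invisible(x)
}

#' Baseline reference of a clean channel
#'
#' Arithmetic mean over the final 5 minutes of the pre-run baseline, i.e.
#' over `[baseline_end - window_s, baseline_end)`.
#'
#' @param clean a `clean_channel`.
#' @param phases a [phase_schedule()].
#' @param window_s reference window length (default 300 s).
#' @return scalar reference value.
#' @export
baseline_reference <- function(clean, phases, window_s = 300) {
  if (phases$baseline_end - phases$baseline_start < window_s)
    sahc_error("sahc_invalid_parameter",
               "baseline shorter than the reference window")
  sel <- clean$time >= phases$baseline_end - window_s &
    clean$time < phases$baseline_end
  if (!any(sel))
    sahc_error("sahc_insufficient_data",
               "no clean samples overlap the baseline reference window")
  mean(clean$value[sel])
}

#' Baseline-referenced 2-minute epoch deltas
#'
#' Tiles non-overlapping bins (default 120 s) from the start of ramp-up
#' through the end of recovery and returns each bin's mean change from the
#' baseline reference.  With the default schedule this yields 12 epochs:
#' ramp-up (1), run (5), ramp-down (1), recovery (5); the final run epoch is
#' the "minute 10" value used in end-of-run summaries.  Bins with no clean
#' samples carry `NA` deltas (flagged in `n`), never a silent zero.
#'
#' @param clean a `clean_channel`.
#' @param phases a [phase_schedule()].
#' @param epoch_s epoch length in seconds (default 120).
#' @return data frame with columns `epoch`, `phase`, `t_start`, `t_end`, `n`,
#'   `mean`, `delta`; the baseline reference is attached as attribute
#'   `baseline`.
#' @export
epoch_deltas <- function(clean, phases, epoch_s = 120) {
  ref <- baseline_reference(clean, phases)
  starts <- seq(phases$rampup_start, phases$recovery_end - epoch_s,
                by = epoch_s)
  bin <- floor((clean$time - phases$rampup_start) / epoch_s) + 1
  ok <- bin >= 1 & bin <= length(starts)
  n <- tabulate(bin[ok], nbins = length(starts))
  sums <- rep(NA_real_, length(starts))
  if (any(ok)) {
    present <- sort(unique(bin[ok]))
    sums[present] <- rowsum(clean$value[ok], bin[ok])[, 1]
  }
  m <- ifelse(n > 0, sums / n, NA_real_)
  phase <- ifelse(starts < phases$run_start, "ramp_up",
           ifelse(starts < phases$rampdown_start, "run",
           ifelse(starts < phases$recovery_start, "ramp_down", "recovery")))
  out <- data.frame(epoch = seq_along(starts), phase = phase,
                    t_start = starts, t_end = starts + epoch_s, n = n,
                    mean = m, delta = m - ref)
  attr(out, "baseline") <- ref
  out
}

#' Preprocess all channels of a run
#'
#' Applies the artifact scan, the 95% validity gate, 4 Hz spline resampling
#' and epoch-delta computation to every channel of a run record.  A channel
#' failing the gate invalidates only that channel; the run is kept and the
#' rejection is reported.
#'
#' @param run a `sahc_run` (see [generate_run()] / [read_run_csv()]).
#' @param limits named list of plausibility limits as in [default_limits()].
#' @param max_sd_multiple jump threshold in whole-record SDs.
#' @param rate resampling rate in Hz.
#' @return list of class `sahc_prep`: `meta` (run metadata), `clean` (named
#'   list of `clean_channel`), `deltas` (long data frame: `channel`, `epoch`,
#'   `phase`, `t_start`, `t_end`, `delta`, `baseline`), `artifact_fraction`
#'   (named numeric), `rejected` (character vector of channel names).
#' @export
preprocess_run <- function(run, limits = default_limits(),
                           max_sd_multiple = 3, rate = 4) {
  phases <- run$phases
  clean <- list(); rejected <- character(); af <- numeric()
  delta_rows <- list()
  for (ch in names(run$channels)) {
    x <- run$channels[[ch]]
    lim <- limits[[ch]]
    if (is.null(lim)) lim <- c(-Inf, Inf)
    if (ch == "CC" && !is.null(names(lim)) && "rel" %in% names(lim)) {
      # relative band around the early-record (first minute) level
      early <- x$value[x$time < x$time[1] + 60]
      lim <- median(early) + c(-1, 1) * lim[["rel"]]
    }
    mask <- scan_artifacts(x$time, x$value, lim, max_sd_multiple)
    af[ch] <- 1 - mask$fraction_valid
    cl <- tryCatch(resample_clean(x$time, x$value, mask, rate = rate),
                   sahc_channel_rejected = function(e) NULL)
    if (is.null(cl)) { rejected <- c(rejected, ch); next }
    clean[[ch]] <- cl
    d <- epoch_deltas(cl, phases)
    delta_rows[[ch]] <- data.frame(channel = ch, d,
                                   baseline = attr(d, "baseline"))
  }
  deltas <- if (length(delta_rows)) do.call(rbind, delta_rows) else
    data.frame(channel = character(), epoch = integer(), phase = character(),
               t_start = numeric(), t_end = numeric(), n = integer(),
               mean = numeric(), delta = numeric(), baseline = numeric())
  rownames(deltas) <- NULL
  structure(list(meta = run$meta, phases = phases, clean = clean,
                 deltas = deltas, artifact_fraction = af,
                 rejected = rejected, events = run$events,
                 terminated = isTRUE(run$terminated),
                 termination_time = run$termination_time),
            class = "sahc_prep")
}
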