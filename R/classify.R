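## Pre-syncope classification.  A run is PSS+ when any of:
##   (i)   a sustained (>= 15 s) concurrent reduction of heart rate and blood
##         pressure during rotation,
##   (ii)  a reported symptom (nausea, paleness, dizziness),
##   (iii) participant-requested run termination.

pss_symptoms <- c("nausea", "paleness", "dizziness")

## Maximal concurrent-decrease intervals of two uniformly sampled series:
## strictly negative first differences in both channels, with gaps up to
## `merge_gap_s` bridged.  Returns a data frame of start/end times.
concurrent_drop_intervals <- function(time, neg_both, merge_gap_s) {
  r <- rle(neg_both)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(iv) == 0) return(iv)
  dt <- time[2] - time[1]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    gap <- (iv$start[k] - merged$end[nrow(merged)] - 1) * dt
    if (gap <= merge_gap_s) merged$end[nrow(merged)] <- iv$end[k]
    else merged <- rbind(merged, iv[k, ])
  }
  merged
}

#' Classify a run as pre-syncopal (PSS+) or not
#'
#' Scans the rotation phase (ramp-up through ramp-down) of the cleaned heart
#' rate and mean arterial pressure for a sustained concurrent reduction, and
#' combines that signal criterion with the symptom event log and the
#' termination flag.  The earliest criterion met (in time) is reported.
#'
#' Criterion (i) requires a maximal interval during which the local
#' least-squares slopes (centered `slope_window_s` windows) of both channels
#' are negative; interruptions up to `merge_gap_s` are bridged so that
#' measurement noise does not shatter a genuine decline.  Because a centered
#' slope window dilates the apparent extent of a decline by up to the window
#' length, the interval's span minus `slope_window_s` is the effective
#' decline duration, and must reach `min_duration_s` (15 s).  The net
#' smoothed drop over the interval must additionally exceed
#' `max(3 * noise scale, min_drop)` in each channel — the noise scale being
#' the robust spread (MAD) of `min_duration_s` changes of the smoothed
#' signal across the rotation window, i.e. the size of drift the channel
#' produces over the criterion's own timescale — at a mean decline rate of
#' at least `min_rate` — an acute pre-syncopal fall, not a slow drift of the
#' run-phase response accumulating the same net change over minutes.  Duration is thus measured
#' on the decline itself, not on an enclosing analysis window, so a decline
#' shorter than 15 s can never trigger the criterion no matter how steep.
#'
#' @param hr,map `clean_channel` objects (4 Hz) covering the rotation window.
#' @param events data frame with columns `time`, `label`, or `NULL`; labels
#'   `nausea`, `paleness`, `dizziness` trigger criterion (ii).
#' @param terminated logical termination flag (criterion (iii)).
#' @param termination_time time of termination (s), optional.
#' @param window rotation window `c(start, end)` in seconds; default the
#'   trial's ramp-up start to ramp-down end.
#' @param min_duration_s minimal effective duration of the concurrent
#'   reduction (s).
#' @param min_drop named floor on the net drop, `c(hr = 5, map = 5)`
#'   (bpm / mmHg).
#' @param min_rate floor on the mean decline rate over the interval
#'   (bpm/s, mmHg/s).
#' @param merge_gap_s maximal bridged interruption (s); autocorrelated
#'   physiological noise produces slope-sign excursions of a few seconds
#'   even inside a genuine decline, so interruptions up to 4 s are bridged.
#' @param slope_window_s centered window for the local slope estimate (s);
#'   the default (4 s) spans a few beats of beat-to-beat channels so that
#'   interpolation wiggle between beats does not shatter a genuine decline.
#' @param smooth_s running-mean window used for net-drop measurement and
#'   noise estimation (s).
#' @return list of class `pss_result`: `label` ("PSS+" or "PSS-"),
#'   `criterion` ("hr_bp_drop", "symptom", "termination" or "none"), `time`
#'   (s, `NA` if PSS-).
#' @examples
#' ph <- phase_schedule()
#' t <- seq(-120, 720, 0.25)
#' hr <- structure(list(time = t, value = rep(70, length(t)), rate = 4),
#'                 class = "clean_channel")
#' classify_run(hr, hr)  # flat traces, no events -> PSS-
#' @export
classify_run <- function(hr, map, events = NULL, terminated = FALSE,
                         termination_time = NA_real_,
                         window = c(-120, 720), min_duration_s = 15,
                         min_drop = c(hr = 5, map = 5), min_rate = 0.25,
                         merge_gap_s = 4, slope_window_s = 4, smooth_s = 2) {
  if (is.null(hr) || is.null(map))
    sahc_error("sahc_unclassifiable",
               "HR and MAP channels are required for PSS classification")
  hits <- list()
  if (isTRUE(terminated))
    hits[[length(hits) + 1]] <- list(criterion = "termination",
                                     time = termination_time)
  if (!is.null(events) && nrow(events) > 0) {
    sym <- events[events$label %in% pss_symptoms, , drop = FALSE]
    if (nrow(sym) > 0)
      hits[[length(hits) + 1]] <- list(criterion = "symptom",
                                       time = min(sym$time))
  }
  drop_hit <- detect_hr_bp_drop(hr, map, window, min_duration_s, min_drop,
                                min_rate, merge_gap_s, slope_window_s,
                                smooth_s)
  if (!is.null(drop_hit)) hits[[length(hits) + 1]] <- drop_hit
  if (length(hits) == 0)
    return(structure(list(label = "PSS-", criterion = "none",
                          time = NA_real_), class = "pss_result"))
  times <- vapply(hits, function(h)
    if (is.finite(h$time)) h$time else Inf, numeric(1))
  first <- hits[[which.min(times)]]
  structure(list(label = "PSS+", criterion = first$criterion,
                 time = first$time), class = "pss_result")
}

## Centered least-squares slope over a window of k samples (k odd).
local_slope <- function(v, k, dt) {
  i <- seq_len(k) - (k + 1) / 2
  w <- i / (sum(i^2) * dt)
  s <- stats::filter(v, rev(w), sides = 2)
  as.numeric(s)  # NA at the edges
}

detect_hr_bp_drop <- function(hr, map, window, min_duration_s, min_drop,
                              min_rate, merge_gap_s, slope_window_s,
                              smooth_s) {
  sel_h <- hr$time >= window[1] & hr$time <= window[2]
  sel_m <- map$time >= window[1] & map$time <= window[2]
  th <- hr$time[sel_h]; tm <- map$time[sel_m]
  shared <- intersect(round(th * 4), round(tm * 4)) / 4
  if (length(shared) < min_duration_s * 4 + 1) return(NULL)
  vh <- hr$value[sel_h][match(round(shared * 4), round(th * 4))]
  vm <- map$value[sel_m][match(round(shared * 4), round(tm * 4))]
  dt <- shared[2] - shared[1]
  k <- round(slope_window_s / dt) + 1L; if (k %% 2 == 0) k <- k + 1L
  slope_h <- local_slope(vh, k, dt)
  slope_m <- local_slope(vm, k, dt)
  neg <- !is.na(slope_h) & !is.na(slope_m) & slope_h < 0 & slope_m < 0
  iv <- concurrent_drop_intervals(shared, neg, merge_gap_s)
  if (nrow(iv) == 0) return(NULL)
  # running means for net-drop measurement; residual SD as the noise floor
  ks <- max(1L, round(smooth_s / dt)); if (ks %% 2 == 0) ks <- ks + 1L
  sm <- function(v) {
    s <- stats::filter(v, rep(1 / ks, ks), sides = 2)
    s[is.na(s)] <- v[is.na(s)]
    as.numeric(s)
  }
  sh <- sm(vh); smv <- sm(vm)
  # noise floor: robust spread of changes over the criterion timescale
  lag <- round(min_duration_s / dt)
  noise_h <- mad(diff(sh, lag = lag))
  noise_m <- mad(diff(smv, lag = lag))
  thr_h <- max(3 * noise_h, min_drop[["hr"]], na.rm = TRUE)
  thr_m <- max(3 * noise_m, min_drop[["map"]], na.rm = TRUE)
  for (k2 in seq_len(nrow(iv))) {
    i0 <- iv$start[k2]; i1 <- iv$end[k2]
    # centered slope windows dilate a decline by up to the window length
    dur <- (i1 - i0) * dt - slope_window_s
    if (dur < min_duration_s) next
    drop_h <- sh[i0] - sh[i1]
    drop_m <- smv[i0] - smv[i1]
    if (drop_h >= thr_h && drop_m >= thr_m &&
        drop_h / dur >= min_rate && drop_m / dur >= min_rate)
      return(list(criterion = "hr_bp_drop",
                  time = shared[i0] + slope_window_s / 2))
  }
  NULL
}

#' @export
print.pss_result <- function(x, ...) {
  cat(sprintf("%s (criterion: %s%s)\n", x$label, x$criterion,
              if (is.finite(x$time)) sprintf(" at t = %.1f s", x$time) else ""))
  invisible(x)
}

#' Classify a preprocessed run
#'
#' Convenience wrapper pulling the cleaned HR and MAP channels, event log and
#' termination flag out of an [preprocess_run()] result.
#'
#' @param prep an `sahc_prep` object.
#' @param ... passed to [classify_run()].
#' @return a `pss_result`.
#' @export
classify_prep <- function(prep, ...) {
  classify_run(prep$clean[["HR"]], prep$clean[["MAP"]],
               events = prep$events, terminated = prep$terminated,
               termination_time = prep$termination_time,
               window = c(prep$phases$rampup_start,
                          prep$phases$recovery_start), ...)
}
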