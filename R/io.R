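## Readers, writers and the pipeline driver.  Run data travel as one CSV per
## run (columns time_s, channel, value; comma-separated, UTF-8, '.' decimal,
## header mandatory, times in seconds) plus a JSON sidecar holding the
## metadata: participant, position, foot-level g, phase times, events and
## the termination flag.

#' Write a run record to CSV + JSON sidecar
#'
#' @param run a `sahc_run`.
#' @param path CSV path.
#' @param sidecar_path JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return invisibly, `path`.
#' @export
write_run_csv <- function(run, path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- sub("\\.csv$", ".json", path)
  rows <- lapply(names(run$channels), function(ch)
    data.frame(time_s = run$channels[[ch]]$time, channel = ch,
               value = run$channels[[ch]]$value))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(run_id = run$meta$run_id, participant = run$meta$participant,
               position = run$meta$position, g_foot = run$meta$g_foot,
               phases = run$phases,
               events = if (nrow(run$events)) run$events else NULL,
               terminated = isTRUE(run$terminated),
               termination_time = if (is.finite(run$termination_time))
                 run$termination_time else NULL)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run record from CSV + JSON sidecar
#'
#' Rows are sorted by time within each channel; unknown channels (not in
#' [channel_params()]) are preserved with a warning.
#'
#' @param path CSV path with columns `time_s`, `channel`, `value`.
#' @param sidecar_path JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return a `sahc_run`.
#' @export
read_run_csv <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- sub("\\.csv$", ".json", path)
  if (!file.exists(path) || !file.exists(sidecar_path))
    sahc_error("sahc_schema_error", "run CSV or JSON sidecar not found")
  d <- read.csv(path)
  for (col in c("time_s", "channel", "value"))
    if (!col %in% names(d))
      sahc_error("sahc_schema_error",
                 sprintf("missing required column '%s'", col))
  if (!is.numeric(d$time_s) || !is.numeric(d$value) || anyNA(d$time_s))
    sahc_error("sahc_schema_error", "time_s and value must be numeric")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("run_id", "participant", "position", "g_foot", "phases"))
    if (is.null(meta[[f]]))
      sahc_error("sahc_schema_error",
                 sprintf("missing required sidecar field '%s'", f))
  known <- channel_params()$channel
  unknown <- setdiff(unique(d$channel), known)
  if (length(unknown))
    warning("preserving unknown channel(s): ",
            paste(unknown, collapse = ", "))
  channels <- lapply(split(d, d$channel), function(x) {
    x <- x[order(x$time_s), ]
    data.frame(time = x$time_s, value = x$value)
  })
  ev <- meta$events
  events <- if (is.null(ev) || length(ev) == 0)
    data.frame(time = numeric(), label = character())
  else as.data.frame(ev)
  structure(list(
    meta = list(run_id = meta$run_id, participant = meta$participant,
                position = meta$position, g_foot = meta$g_foot),
    phases = as.list(meta$phases), channels = channels, events = events,
    terminated = isTRUE(meta$terminated),
    termination_time = if (is.null(meta$termination_time)) NA_real_
    else meta$termination_time,
    truth = NULL), class = "sahc_run")
}

#' Read or write a flat key/value configuration file
#'
#' Configurations (geometry, physical constants, landmark heights,
#' preprocessing and classifier parameters, seeds) travel as a flat JSON
#' object of scalars; scalar values round-trip losslessly.
#'
#' @param x named list of scalar values.
#' @param path file path.
#' @return `read_config()`: a named list; `write_config()`: `path`,
#'   invisibly.
#' @export
write_config <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    sahc_error("sahc_schema_error", paste("config file not found:", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a trial to a directory
#'
#' One CSV + JSON sidecar per run, plus `truth.json` and `config.json`
#' (scalar generator settings, including the seed) when present.
#'
#' @param trial a `sahc_trial` (or plain list of `sahc_run`).
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs <- if (inherits(trial, "sahc_trial")) trial$runs else trial
  for (r in runs)
    write_run_csv(r, file.path(dir, paste0(r$meta$run_id, ".csv")))
  if (inherits(trial, "sahc_trial") && !is.null(trial$truth))
    jsonlite::write_json(trial$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (inherits(trial, "sahc_trial") && !is.null(trial$config)) {
    cfg <- trial$config
    scalars <- cfg[vapply(cfg, function(v)
      is.atomic(v) && length(v) <= 3 && !is.null(v), logical(1))]
    write_config(scalars, file.path(dir, "config.json"))
  }
  invisible(dir)
}

#' Read all runs from a trial directory
#'
#' @param dir directory written by [write_trial()].
#' @return named list of `sahc_run`.
#' @export
read_trial <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  runs <- lapply(files, read_run_csv)
  names(runs) <- vapply(runs, function(r) r$meta$run_id, character(1))
  runs
}

#' Run the full analysis pipeline on a set of runs
#'
#' Preprocesses every run, classifies pre-syncope, and assembles the
#' trial-level result tables: the long epoch-delta table, the end-of-run
#' (final run epoch) deltas, per-position PSS counts with the chi-squared
#' test, per-channel mixed-model likelihood-ratio tests, and the
#' calf-circumference correlations with heart rate and cerebral saturation.
#'
#' @param runs list of `sahc_run`.
#' @param limits,max_sd_multiple,rate passed to [preprocess_run()].
#' @param lmm_channels channels to fit mixed models for (default: all with
#'   data); set `character(0)` to skip model fitting.
#' @return list of class `sahc_analysis`: `preps`, `pss` (data frame),
#'   `pss_counts`, `chisq`, `deltas` (long table), `final_deltas`,
#'   `lrt` (per channel x effect data frame), `correlations`.
#' @export
analyze_trial <- function(runs, limits = default_limits(),
                          max_sd_multiple = 3, rate = 4,
                          lmm_channels = NULL) {
  preps <- lapply(runs, preprocess_run, limits = limits,
                  max_sd_multiple = max_sd_multiple, rate = rate)
  pss <- do.call(rbind, lapply(preps, function(p) {
    r <- tryCatch(classify_prep(p),
                  sahc_unclassifiable = function(e)
                    list(label = NA_character_, criterion = NA_character_,
                         time = NA_real_))
    data.frame(run = p$meta$run_id, participant = p$meta$participant,
               position = p$meta$position, g_foot = p$meta$g_foot,
               label = r$label, criterion = r$criterion, time = r$time)
  }))
  rownames(pss) <- NULL
  ok <- !is.na(pss$label)
  pss_counts <- do.call(rbind, lapply(split(pss[ok, ], pss$position[ok]),
                                      function(x)
    data.frame(position = x$position[1],
               pss_pos = sum(x$label == "PSS+"),
               pss_neg = sum(x$label == "PSS-"))))
  if (is.null(pss_counts))
    pss_counts <- data.frame(position = character(), pss_pos = integer(),
                             pss_neg = integer())
  rownames(pss_counts) <- NULL
  chisq <- if (nrow(pss_counts) >= 2 && sum(pss_counts$pss_pos) > 0 &&
               sum(pss_counts$pss_neg) > 0)
    pss_chi_squared(pss_counts) else NULL
  deltas <- long_delta_table(preps)
  final <- final_run_deltas(preps)
  if (is.null(lmm_channels))
    lmm_channels <- unique(deltas$channel)
  lrt_rows <- list()
  for (ch in lmm_channels) {
    sub <- deltas[deltas$channel == ch & is.finite(deltas$delta), ]
    if (length(unique(sub$participant)) < 2) next
    for (eff in c("time", "position_code", "g_foot")) {
      res <- tryCatch(lrt_effect(sub, eff), sahc_error = function(e) NULL)
      if (!is.null(res))
        lrt_rows[[paste(ch, eff)]] <- data.frame(
          channel = ch, effect = eff, statistic = res$statistic,
          df = res$df, p = res$p)
    }
  }
  wide <- function(chn) {
    x <- final[final$channel == chn, c("run", "delta")]
    setNames(x$delta, x$run)
  }
  correlations <- NULL
  if (all(c("CC", "HR") %in% final$channel)) {
    cc <- wide("CC"); hr <- wide("HR")
    shared <- intersect(names(cc), names(hr))
    correlations <- list(cc_hr = delta_correlation(cc[shared], hr[shared]))
    if ("cTSI" %in% final$channel) {
      ts <- wide("cTSI"); shared <- intersect(names(cc), names(ts))
      correlations$cc_ctsi <- delta_correlation(cc[shared], ts[shared])
    }
  }
  structure(list(preps = preps, pss = pss, pss_counts = pss_counts,
                 chisq = chisq, deltas = deltas, final_deltas = final,
                 lrt = if (length(lrt_rows)) do.call(rbind, lrt_rows)
                 else NULL,
                 correlations = correlations),
            class = "sahc_analysis")
}

#' Write analysis report tables
#'
#' Emits delimited text and JSON summaries of an analysis: the end-of-run
#' delta table by position, PSS counts and chi-squared, the long epoch-delta
#' table, and the mixed-model LRT table.  Output is deterministic for fixed
#' input.
#'
#' @param analysis a `sahc_analysis` (or a named list of data frames).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (inherits(analysis, "sahc_analysis")) {
    emit(analysis$final_deltas, "final_run_deltas")
    emit(analysis$pss, "pss_classification")
    emit(analysis$pss_counts, "pss_counts")
    emit(analysis$deltas, "epoch_deltas")
    if (!is.null(analysis$lrt)) emit(analysis$lrt, "lmm_lrt")
    summ <- list(chisq = analysis$chisq[c("statistic", "df", "p")],
                 correlations = analysis$correlations)
    jp <- file.path(dir, "summary.json")
    jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, jp)
  } else {
    for (nm in names(analysis)) emit(analysis[[nm]], nm)
  }
  invisible(paths)
}
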