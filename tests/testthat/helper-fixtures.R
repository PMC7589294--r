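# Shared fixtures: clean-channel constructor, hand-built run records, and
# the published hydrostatic reference table used by the biomechanics checks.

make_clean <- function(time, value, rate = 4) {
  structure(list(time = time, value = value, rate = rate,
                 artifact_fraction = 0), class = "clean_channel")
}

# Uniform 4 Hz grid over the rotation window used by classifier tests.
rot_grid <- function(from = -120, to = 720) seq(from, to, by = 0.25)

# Build a minimal sahc_run from raw channel data frames.
make_run <- function(channels, phases = phase_schedule(), events = NULL,
                     terminated = FALSE, termination_time = NA_real_,
                     participant = 1, position = "P1", g_foot = 2.4,
                     run_id = "T01") {
  if (is.null(events)) events <- data.frame(time = numeric(),
                                            label = character())
  structure(list(meta = list(run_id = run_id, participant = participant,
                             position = position, g_foot = g_foot),
                 phases = phases, channels = channels, events = events,
                 terminated = terminated, termination_time = termination_time,
                 truth = NULL),
            class = "sahc_run")
}

# Published heart-referenced pressure offsets (mmHg) for the 1.73 m
# reference body at 2.4 g feet: centrifuge rows P1/P2/P3 and standing.
# Landmarks ordered crown, eye, carotid, aortic, heart, foot.
table5_reference <- function() {
  lm <- c("crown", "eye", "carotid", "aortic", "heart", "foot")
  list(landmarks = lm,
       P1 = c(-29.7, -24.8, -18.9, -4.3, 0, 166),
       P2 = c(-12.7, -12.0, -10.2, -2.7, 0, 148),
       P3 = c(17.6, 10.7, 5.4, 0.2, 0, 115),
       standing = c(-37.6, -29.2, -20.9, -4.2, 0, 96.0))
}

expect_within <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("|%s - %s| <= %s", format(actual),
                              format(expected), format(tol)))
}
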