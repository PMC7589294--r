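# Artifact scan, validity gating, spline resampling, baseline reference and
# epoch deltas.

phases <- phase_schedule()

test_that("artifact scan flags limit violations and abrupt jumps", {
  t <- 0:99
  hr <- rep(70, 100)
  m <- scan_artifacts(t, hr, c(25, 240))
  expect_true(all(m$valid))
  expect_equal(validity_fraction(m), 1)

  spike <- hr; spike[50] <- 300
  m2 <- scan_artifacts(t, spike, c(25, 240))
  expect_identical(which(!m2$valid), 50L)
  expect_equal(validity_fraction(m2), 0.99)

  # sinusoid with a single step of 10 whole-record SDs
  s <- sin(2 * pi * t / 20)
  step <- s; step[60] <- s[60] + 10 * sd(s)
  m3 <- scan_artifacts(t, step, c(-100, 100), max_sd_multiple = 3)
  expect_identical(which(!m3$valid), 60L)

  # frame summary covers the record in 10 s frames; the step at t = 59
  # lands in the sixth frame
  expect_equal(nrow(m3$frames), 10)
  expect_equal(m3$frames$fraction_valid[6], 0.9)

  expect_error(scan_artifacts(numeric(), numeric(), c(0, 1)),
               class = "sahc_empty_input")
})

test_that("validity fractions count flagged samples", {
  expect_equal(validity_fraction(c(rep(TRUE, 50), rep(FALSE, 50))), 0.5)
  expect_equal(validity_fraction(c(rep(TRUE, 96), rep(FALSE, 4))), 0.96)
})

test_that("spline resampling reproduces cubics exactly and sines closely", {
  set.seed(42)
  t <- sort(runif(200, 0, 50))
  f <- function(x) 2 - 0.3 * x + 0.05 * x^2 - 0.001 * x^3
  cl <- resample_clean(t, f(t), rep(TRUE, 200))
  expect_lt(max(abs(cl$value - f(cl$time))), 1e-9)
  expect_equal(unique(round(diff(cl$time), 10)), 0.25)

  # 0.1 Hz sine sampled at 1 Hz: spline error ~ h^4 f'''' / 384 away from
  # the ends (the FMM end cubic, fitted through the outer 4 knots, dominates
  # the error inside the first/last three intervals)
  t2 <- 0:60
  cl2 <- resample_clean(t2, sin(2 * pi * 0.1 * t2), rep(TRUE, 61))
  inner <- cl2$time >= 3 & cl2$time <= 57
  expect_lt(max(abs(cl2$value - sin(2 * pi * 0.1 * cl2$time))[inner]), 1e-3)

  # constant signal with 3% masked stays constant
  mask <- rep(TRUE, 200); mask[sample(200, 6)] <- FALSE
  cl3 <- resample_clean(t, rep(5, 200), mask)
  expect_equal(cl3$value, rep(5, length(cl3$time)), tolerance = 1e-12)
})

test_that("resampling an already-uniform channel is idempotent", {
  t <- seq(0, 100, by = 0.25)
  v <- cumsum(rnorm(length(t), 0, 0.1))
  cl <- resample_clean(t, v, rep(TRUE, length(t)))
  shared <- match(round(cl$time * 4), round(t * 4))
  expect_lt(max(abs(cl$value - v[shared])), 1e-9)
})

test_that("masked samples never influence the spline", {
  set.seed(7)
  t <- sort(runif(300, 0, 100))
  v <- sin(t / 5)
  mask <- runif(300) > 0.03
  a <- resample_clean(t, v, mask)
  v2 <- v; v2[!mask] <- rnorm(sum(!mask), 0, 1e6)
  b <- resample_clean(t, v2, mask)
  expect_identical(a$value, b$value)
})

test_that("the 95% validity gate rejects at 6% artifacts and keeps 4%", {
  t <- seq(0, 999.9, by = 0.1)
  v <- rep(70, length(t))
  for (rate in c(0.04, 0.06)) {
    mask <- rep(TRUE, length(t))
    mask[seq_len(rate * length(t))] <- FALSE
    if (rate > 0.05) {
      expect_error(resample_clean(t, v, mask),
                   class = "sahc_channel_rejected")
    } else {
      expect_s3_class(resample_clean(t, v, mask), "clean_channel")
    }
  }
  expect_error(resample_clean(1:3, c(1, 2, 3), rep(TRUE, 3)),
               class = "sahc_insufficient_data")
})

test_that("baseline reference is the mean of the final 5 min of baseline", {
  t <- seq(phases$baseline_start, phases$recovery_end, by = 0.25)
  cl <- make_clean(t, rep(70, length(t)))
  expect_equal(baseline_reference(cl, phases), 70)

  # ramp 0 -> 600 across the 600 s baseline: mean of the last half is 450
  ramp <- pmin(pmax(t - phases$baseline_start, 0), 600)
  clr <- make_clean(t, ramp)
  expect_equal(baseline_reference(clr, phases), 450, tolerance = 1e-3)

  short <- phase_schedule(baseline_s = 200)
  expect_error(baseline_reference(cl, short),
               class = "sahc_invalid_parameter")
})

test_that("epoch deltas tile ramp-up through recovery in 120 s bins", {
  t <- seq(phases$baseline_start, phases$recovery_end - 0.25, by = 0.25)
  cl <- make_clean(t, rep(10, length(t)))
  d <- epoch_deltas(cl, phases)
  expect_equal(nrow(d), 12)
  expect_equal(d$phase, c("ramp_up", rep("run", 5), "ramp_down",
                          rep("recovery", 5)))
  expect_equal(d$delta, rep(0, 12))

  # step of +10 at run start
  stepv <- ifelse(t >= 0, 80, 70)
  ds <- epoch_deltas(make_clean(t, stepv), phases)
  expect_equal(ds$delta[ds$phase == "run"], rep(10, 5))
  expect_equal(ds$delta[1], 0)

  # linear signal: bin means are the analytic midpoints
  lin <- 0.01 * t
  dl <- epoch_deltas(make_clean(t, lin), phases)
  mid <- (dl$t_start + dl$t_end - 0.25) / 2   # grid covers [t0, t1-dt]
  ref <- 0.01 * (-270 - 0.125)                # mean of [-420, -120) grid
  expect_equal(dl$delta, 0.01 * mid - ref, tolerance = 1e-10)
})

test_that("adding a constant shifts the baseline but not the deltas", {
  set.seed(11)
  t <- seq(phases$baseline_start, phases$recovery_end - 0.25, by = 0.25)
  v <- 70 + 5 * sin(t / 100) + rnorm(length(t), 0, 0.5)
  d1 <- epoch_deltas(make_clean(t, v), phases)
  d2 <- epoch_deltas(make_clean(t, v + 13.7), phases)
  expect_equal(attr(d2, "baseline"), attr(d1, "baseline") + 13.7)
  expect_equal(d2$delta, d1$delta, tolerance = 1e-9)
})

test_that("an empty epoch is reported as missing, never silent zero", {
  t <- seq(phases$baseline_start, phases$recovery_end - 0.25, by = 0.25)
  keep <- t < 100 | t >= 260
  cl <- make_clean(t[keep], rep(70, sum(keep)))
  d <- epoch_deltas(cl, phases)
  gap <- d$t_start >= 120 & d$t_end <= 240
  expect_true(all(is.na(d$delta[gap])))
  expect_true(all(d$n[gap] == 0))
  expect_true(all(is.finite(d$delta[!gap])))
})

test_that("preprocess_run cleans channels and drops only failing ones", {
  ph <- phases
  t1 <- seq(ph$baseline_start, ph$recovery_end - 1, by = 1)
  hr <- data.frame(time = t1, value = 70 + 0.01 * pmax(t1, 0))
  bad <- hr; bad$value[seq(1, nrow(bad), by = 12)] <- 500  # ~8% artifacts
  run <- make_run(list(HR = hr, MAP = bad))
  prep <- preprocess_run(run)
  expect_named(prep$clean, "HR")
  expect_identical(prep$rejected, "MAP")
  expect_true(prep$artifact_fraction[["MAP"]] > 0.05)
  expect_equal(sort(unique(prep$deltas$channel)), "HR")
})
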