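# Hydrostatic forward model: angular velocity, signed g, gradients,
# pressure offsets, profiles.

body <- body_landmarks()

test_that("angular velocity solves omega^2 * r_foot = g_foot * g0", {
  # hand-derived: omega = sqrt(2.4 * 9.81 / 2.22) = 3.2566 rad/s
  w <- omega_from_foot_g(2.4, 2.22)
  expect_equal(w^2 * 2.22, 2.4 * 9.81, tolerance = 1e-12)
  expect_equal(w, 3.25659, tolerance = 1e-4)
  # hand-derived: omega^2 = 2.4 * 9.81 / 1.24 = 18.987
  expect_equal(omega_from_foot_g(2.4, 1.24)^2, 18.98710, tolerance = 1e-5)
  expect_equal(omega_from_foot_g(0, 1.73), 0)
  expect_error(omega_from_foot_g(2.4, 0), class = "sahc_invalid_geometry")
  expect_error(omega_from_foot_g(2.4, -1), class = "sahc_invalid_geometry")
})

test_that("signed g-levels follow the +Gz convention and the axis is at 0 g", {
  p1 <- centrifuge_config("P1", 2.4, body)
  p2 <- centrifuge_config("P2", 2.4, body)
  p3 <- centrifuge_config("P3", 2.4, body)
  expect_equal(signed_g_at(p2, body, "crown"), 0)
  # published head g-levels at 2.4 g feet: +0.5 (P1, crown), -0.7 (P3, eye)
  expect_equal(signed_g_at(p1, body, "crown"), 0.5297, tolerance = 1e-3)
  expect_equal(signed_g_at(p3, body, "eye"), -0.7355, tolerance = 1e-3)
  expect_equal(signed_g_at(p1, body, "foot"), 2.4, tolerance = 1e-12)
  # magnitudes grow linearly with distance from the axis
  r <- abs(p3$axis_height - c(0.2, 0.4, 0.8))
  g <- vapply(c(0.2, 0.4, 0.8), function(h) signed_g_at(p3, body, h),
              numeric(1))
  expect_equal(g / r, rep(g[1] / r[1], 3), tolerance = 1e-12)
})

test_that("g-gradient percentages match the trial geometry", {
  p2 <- centrifuge_config("P2", 2.4, body)
  p3 <- centrifuge_config("P3", 2.4, body)
  expect_equal(g_gradient(p2, body, "crown"), 100, tolerance = 1e-12)
  # hand-derived: 100 * (1 + 0.38/1.24) = 130.645 (~printed 130)
  expect_equal(g_gradient(p3, body, "eye"), 130.6452, tolerance = 1e-4)
  # equal signed g at the evaluation point and the feet -> no gradient
  p1 <- centrifuge_config("P1", 2.4, body)
  expect_equal(g_gradient(p1, body, head_landmark = 0), 0, tolerance = 1e-12)
  zero <- centrifuge_config("P2", 0, body)
  expect_error(g_gradient(zero, body), class = "sahc_undefined_gradient")
})

test_that("hydrostatic and standing offsets vanish at the heart and match print", {
  for (p in c("P1", "P2", "P3")) {
    cfg <- centrifuge_config(p, 2.4, body)
    expect_identical(hydrostatic_delta(cfg, body, "heart"), 0)
  }
  expect_equal(standing_delta(body, "heart"), 0)
  p1 <- centrifuge_config("P1", 2.4, body)
  p3 <- centrifuge_config("P3", 2.4, body)
  expect_equal(hydrostatic_delta(p1, body, "foot"), 166, tolerance = 0.005)
  expect_equal(hydrostatic_delta(p3, body, "crown"), 17.6, tolerance = 0.025)
  expect_equal(standing_delta(body, "foot"), 95.79, tolerance = 1e-3)
  expect_equal(standing_delta(body, "carotid"), -20.9, tolerance = 0.005)
})

test_that("centrifuge pressure is even in distance from the axis", {
  cfg <- centrifuge_config("P3", 2.4, body)
  for (d in c(0.1, 0.25, 0.49))
    expect_equal(hydrostatic_delta(cfg, body, cfg$axis_height + d),
                 hydrostatic_delta(cfg, body, cfg$axis_height - d),
                 tolerance = 1e-12)
})

test_that("foot-level pressure rises strictly with foot-level g", {
  dps <- vapply(c(0.5, 1.0, 1.7, 2.4, 3.0), function(g)
    hydrostatic_delta(centrifuge_config("P1", g, body), body, "foot"),
    numeric(1))
  expect_true(all(diff(dps) > 0))
})

test_that("closed form agrees with the numeric path integral", {
  cfg <- centrifuge_config("P2", 1.7, body)
  for (lm in c("crown", "aortic", "foot"))
    expect_within(hydrostatic_delta(cfg, body, lm),
                  trapz_pressure(cfg, body, lm), 0.01)
})

test_that("large-radius centrifugation converges to standing", {
  for (g in c(1.0, 2.4)) {
    cfg <- centrifuge_config(1000, g, body)
    for (lm in c("crown", "eye", "carotid", "aortic", "foot")) {
      cf <- hydrostatic_delta(cfg, body, lm)
      st <- standing_delta(body, lm, g = g)
      expect_within(abs(cf - st) / abs(st), 0, 0.01)
    }
  }
})

test_that("pressure profiles have the right shape and agree with the point model", {
  p3 <- centrifuge_config("P3", 2.4, body)
  pp <- pressure_profile(p3, body, n_samples = 347)
  expect_equal(pp$position_m[which.min(pp$delta_p_mmhg)], body$heart,
               tolerance = 0.005)
  expect_true(all(pp$delta_p_mmhg >= 0))
  # landmark evaluations agree exactly with hydrostatic_delta
  pp2 <- pressure_profile(centrifuge_config("P2", 2.4, body), body, 200)
  expect_equal(min(pp2$delta_p_mmhg),
               hydrostatic_delta(centrifuge_config("P2", 2.4, body), body,
                                 "crown"), tolerance = 1e-9)
  st <- pressure_profile(NULL, body, n_samples = 100, g = 1)
  # standing profile is linear through 0 at heart height
  fit <- lm(delta_p_mmhg ~ position_m, data = st)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
  expect_equal(st$delta_p_mmhg[which.min(abs(st$position_m - body$heart))],
               0, tolerance = 1)
  expect_error(pressure_profile(p3, body, n_samples = 1),
               class = "sahc_invalid_geometry")
})

test_that("configuration summary reproduces comparator rows", {
  tab <- summarize_configs(
    list(LAHC = centrifuge_config(8.00, 2.4, body),
         P2 = centrifuge_config("P2", 2.4, body),
         still = centrifuge_config("P1", 0, body)),
    body, head_landmark = "crown")
  # long-arm 8.00 m: head g ~ +1.9, gradient ~ +22%
  expect_equal(tab$g_head[1], 1.88, tolerance = 0.005)
  expect_equal(tab$gradient_pct[1], 22, tolerance = 0.02)
  expect_equal(tab$delta_g[2], 2.4, tolerance = 1e-12)
  expect_equal(tab$g_head[3], 0)
  expect_equal(tab$delta_g[3], 0)
  expect_true(is.na(tab$gradient_pct[3]))
})

test_that("landmark validation rejects malformed bodies", {
  expect_error(body_landmarks(heart = 1.6, carotid = 1.5),
               class = "sahc_invalid_geometry")
  expect_error(body_landmarks(stature = NA), class = "sahc_invalid_geometry")
  b2 <- scale_body(1.60)
  expect_equal(b2$heart / b2$stature, body$heart / body$stature,
               tolerance = 1e-12)
})
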