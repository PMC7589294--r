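## Hydrostatic biomechanics of centrifugation and standing.
##
## Body coordinates: axial position in metres measured from the sole of the
## foot (foot = 0), increasing towards the crown.  The rotation axis sits at
## `axis_height` on that same axis and may exceed the stature (axis above the
## head).  The radius of any body point is |axis_height - height|.  Signed
## g-levels follow the +Gz convention: positive footward (point on the foot
## side of the axis), negative headward.  Pressure offsets are relative to
## heart level: positive means higher pressure than at the heart.

#' Anthropometric landmark set
#'
#' Axial positions (m from the sole of the foot) of the cardiovascular
#' landmarks used by the hydrostatic model.  The default values are the
#' reference body of the trial: a 1.73 m stature with the heart (third
#' intercostal space) at 1.24 m, aortic baroreceptor at 1.30 m, carotid
#' baroreceptor at 1.51 m, eye level at 1.62 m and the crown at stature.
#'
#' @param stature body length in metres (crown height).
#' @param heart,aortic,carotid,eye landmark heights in metres.
#' @param crown crown height; defaults to `stature`.
#' @return An object of class `body_landmarks`: a list with fields `foot`,
#'   `heart`, `aortic`, `carotid`, `eye`, `crown`, `stature`.
#' @examples
#' body_landmarks()
#' scale_body(1.60)
#' @export
body_landmarks <- function(stature = 1.73, heart = 1.24, aortic = 1.30,
                           carotid = 1.51, eye = 1.62, crown = stature) {
  h <- c(foot = 0, heart = heart, aortic = aortic, carotid = carotid,
         eye = eye, crown = crown)
  if (any(!is.finite(h)) || !is.finite(stature))
    sahc_error("sahc_invalid_geometry", "landmark heights must be finite")
  if (any(diff(h) <= 0) || abs(crown - stature) > 1e-9)
    sahc_error("sahc_invalid_geometry",
               "landmarks must satisfy 0 = foot < heart < aortic < carotid < eye < crown = stature")
  structure(c(as.list(h), list(stature = stature)), class = "body_landmarks")
}

#' @rdname body_landmarks
#' @description `scale_body()` rescales all landmark heights of a reference
#'   body affinely with stature (heights multiply by `stature / reference
#'   stature`), the convention used by the synthetic cohort generator.
#' @param reference a `body_landmarks` object to rescale.
#' @export
scale_body <- function(stature, reference = body_landmarks()) {
  s <- stature / reference$stature
  body_landmarks(stature = stature, heart = reference$heart * s,
                 aortic = reference$aortic * s, carotid = reference$carotid * s,
                 eye = reference$eye * s)
}

#' @export
print.body_landmarks <- function(x, ...) {
  cat("Body landmarks (m from sole of foot):\n")
  print(unlist(x[c("foot", "heart", "aortic", "carotid", "eye", "crown")]))
  invisible(x)
}

landmark_height <- function(body, landmark) {
  if (is.numeric(landmark)) return(landmark)
  if (!landmark %in% c("foot", "heart", "aortic", "carotid", "eye", "crown"))
    sahc_error("sahc_invalid_geometry",
               sprintf("unknown landmark '%s'", landmark))
  body[[landmark]]
}

#' Angular velocity from the prescribed foot-level g
#'
#' Solves `omega^2 * r_foot = g_foot * g0` for the angular velocity, i.e. the
#' spin rate at which a point at radius `r_foot` experiences `g_foot` times
#' standard gravity.
#'
#' @param g_foot foot-level acceleration in multiples of g0 (>= 0).
#' @param r_foot foot radius in metres (> 0).
#' @param g0 standard gravity, m/s^2.
#' @return angular velocity in rad/s.
#' @examples
#' omega_from_foot_g(2.4, 2.22)  # ~3.257 rad/s
#' @export
omega_from_foot_g <- function(g_foot, r_foot, g0 = 9.81) {
  if (!is.finite(r_foot) || r_foot <= 0)
    sahc_error("sahc_invalid_geometry", "foot radius must be positive")
  if (!is.finite(g_foot) || g_foot < 0)
    sahc_error("sahc_invalid_geometry", "g_foot must be non-negative")
  sqrt(g_foot * g0 / r_foot)
}

#' Centrifuge configuration
#'
#' Geometry and physical constants for one rotation-axis position.  The three
#' trial positions place the axis above the head (`P1`, stature + overhead
#' offset), at the crown (`P2`) or at heart level (`P3`); an arbitrary axis
#' height in metres is also accepted.
#'
#' @param axis axis position: `"P1"`, `"P2"`, `"P3"` or a height in metres
#'   (body coordinates, m from the sole of the foot).
#' @param g_foot prescribed g-level at the feet, multiples of g0.
#' @param body a [body_landmarks()] object.
#' @param overhead_m overhead offset of the P1 axis above the crown (m); the
#'   trial geometry uses 0.49 m (axis at 2.22 m for the 1.73 m reference body).
#' @param rho blood density, kg/m^3.
#' @param k_bp pascal-to-mmHg conversion factor.
#' @param g0 standard gravity, m/s^2.
#' @return An object of class `centrifuge_config` with fields `axis_height`,
#'   `g_foot`, `omega` (rad/s), `r_foot` and the constants.
#' @examples
#' centrifuge_config("P3", g_foot = 2.4)
#' @export
centrifuge_config <- function(axis, g_foot, body = body_landmarks(),
                              overhead_m = 0.49, rho = 1050, k_bp = 0.0075,
                              g0 = 9.81) {
  axis_height <- if (is.character(axis)) {
    switch(axis,
           P1 = body$stature + overhead_m,
           P2 = body$crown,
           P3 = body$heart,
           sahc_error("sahc_invalid_geometry",
                      sprintf("unknown axis position '%s'", axis)))
  } else axis
  r_foot <- abs(axis_height - body$foot)
  omega <- if (g_foot == 0) 0 else omega_from_foot_g(g_foot, r_foot, g0)
  structure(list(axis_height = axis_height, g_foot = g_foot, omega = omega,
                 r_foot = r_foot, rho = rho, k_bp = k_bp, g0 = g0,
                 label = if (is.character(axis)) axis else
                   sprintf("axis %.2f m", axis_height)),
            class = "centrifuge_config")
}

#' @export
print.centrifuge_config <- function(x, ...) {
  cat(sprintf("Centrifuge config [%s]: axis %.3f m, g_foot %.2f, omega %.3f rad/s\n",
              x$label, x$axis_height, x$g_foot, x$omega))
  invisible(x)
}

#' Signed g-level at a body landmark
#'
#' The centripetal acceleration at a landmark, in multiples of g0 and signed
#' along the +Gz convention: positive for landmarks on the foot side of the
#' rotation axis, negative (headward, -Gz) on the opposite side.  A landmark
#' sitting exactly on the axis experiences 0 g.
#'
#' @param config a [centrifuge_config()].
#' @param body a [body_landmarks()].
#' @param landmark landmark name or height in metres.
#' @return signed g-level in multiples of g0.
#' @examples
#' cfg <- centrifuge_config("P3", 2.4)
#' signed_g_at(cfg, body_landmarks(), "eye")  # ~ -0.74 (headward)
#' @export
signed_g_at <- function(config, body, landmark) {
  h <- landmark_height(body, landmark)
  r <- config$axis_height - h
  # r > 0: landmark below the axis (foot side) -> +Gz
  sign(r) * config$omega^2 * abs(r) / config$g0
}

#' Head-to-foot g-gradient
#'
#' The g-gradient expressed as the percentage difference between the g-level
#' at the head and at the feet, `100 * (g_foot - g_head) / g_foot`, using the
#' signed head-level value, so a headward (negative) head g yields a gradient
#' above 100 percent.  The head landmark defaults to the crown but is an
#' explicit parameter because gradient figures in the literature mix crown
#' and eye-level conventions.
#'
#' @inheritParams signed_g_at
#' @param head_landmark landmark used as "head" (default `"crown"`).
#' @return gradient in percent.
#' @examples
#' g_gradient(centrifuge_config("P2", 2.4), body_landmarks())  # exactly 100
#' @export
g_gradient <- function(config, body, head_landmark = "crown") {
  if (config$g_foot == 0)
    sahc_error("sahc_undefined_gradient",
               "g-gradient is undefined at zero foot-level g")
  g_head <- signed_g_at(config, body, head_landmark)
  100 * (config$g_foot - g_head) / config$g_foot
}

#' Hydrostatic pressure offset from heart level under centrifugation
#'
#' Blood pressure difference between a body point and heart level in a
#' rotating fluid column: `dP = rho * k_bp * omega^2 * (r_p^2 - r_heart^2) / 2`
#' where `r_x` is the distance of point x from the rotation axis.  Pressure
#' grows quadratically away from the axis on both sides, so the offset is
#' positive wherever the point is further from the axis than the heart.
#' (The factor 1/2 comes from integrating the radial acceleration
#' `omega^2 * r` along the column.)
#'
#' @inheritParams signed_g_at
#' @return pressure offset in mmHg (positive = above heart-level pressure).
#' @examples
#' cfg <- centrifuge_config("P1", 2.4)
#' hydrostatic_delta(cfg, body_landmarks(), "foot")  # ~166 mmHg
#' @export
hydrostatic_delta <- function(config, body, landmark) {
  h <- landmark_height(body, landmark)
  r_p <- abs(config$axis_height - h)
  r_heart <- abs(config$axis_height - body$heart)
  config$rho * config$k_bp * config$omega^2 * (r_p^2 - r_heart^2) / 2
}

#' Hydrostatic pressure offset from heart level when standing
#'
#' Upright-standing comparator in a uniform gravity field g:
#' `dP = -rho * k_bp * g * g0 * (h_landmark - h_heart)`, negative above the
#' heart and positive below it.
#'
#' @param body a [body_landmarks()].
#' @param landmark landmark name or height in metres.
#' @param g gravity in multiples of g0 (>= 0).
#' @param rho blood density, kg/m^3.
#' @param k_bp pascal-to-mmHg conversion factor.
#' @param g0 standard gravity, m/s^2.
#' @return pressure offset in mmHg.
#' @examples
#' standing_delta(body_landmarks(), "foot")  # ~95.8 mmHg
#' @export
standing_delta <- function(body, landmark, g = 1, rho = 1050, k_bp = 0.0075,
                           g0 = 9.81) {
  if (!is.finite(g) || g < 0)
    sahc_error("sahc_invalid_geometry", "g must be non-negative")
  h <- landmark_height(body, landmark)
  -rho * k_bp * g * g0 * (h - body$heart)
}

#' Pressure profile along the body
#'
#' Dense heart-referenced pressure curve over axial positions 0 to stature,
#' either for a centrifuge configuration (quadratic in distance from the
#' axis, minimum at the axis) or for upright standing (linear in height,
#' zero at heart level).
#'
#' @param config a [centrifuge_config()], or `NULL` for standing mode.
#' @param body a [body_landmarks()].
#' @param n_samples number of equally spaced axial positions (>= 2).
#' @param g standing-mode gravity in multiples of g0 (ignored in centrifuge
#'   mode).
#' @return A data frame of class `pressure_profile` with columns `position_m`
#'   and `delta_p_mmhg`, and attributes `mode` ("centrifuge" or "standing")
#'   and `config`.
#' @examples
#' pp <- pressure_profile(centrifuge_config("P3", 2.4), n_samples = 50)
#' pp$position_m[which.min(pp$delta_p_mmhg)]  # minimum at heart height
#' @export
pressure_profile <- function(config = NULL, body = body_landmarks(),
                             n_samples = 200, g = 1) {
  if (n_samples < 2)
    sahc_error("sahc_invalid_geometry", "need at least 2 samples")
  pos <- seq(0, body$stature, length.out = n_samples)
  if (is.null(config)) {
    dp <- vapply(pos, function(h) standing_delta(body, h, g = g), numeric(1))
    mode <- "standing"
  } else {
    dp <- vapply(pos, function(h) hydrostatic_delta(config, body, h),
                 numeric(1))
    mode <- "centrifuge"
  }
  structure(data.frame(position_m = pos, delta_p_mmhg = dp),
            mode = mode, config = config,
            class = c("pressure_profile", "data.frame"))
}

#' Summary table of g-levels and gradients across configurations
#'
#' One row per configuration with the signed head-level g, foot-level g,
#' their difference (delta g) and the percentage g-gradient — the layout used
#' to compare axis positions with long-arm (8.00 m) and plain short-arm
#' (2.80 m) centrifugation at matched foot-level g.
#'
#' @param configs a named list of [centrifuge_config()] objects.
#' @param body a [body_landmarks()].
#' @param head_landmark landmark used as "head" (default `"crown"`).
#' @return data frame with columns `config`, `g_head`, `g_foot`, `delta_g`,
#'   `gradient_pct` (gradient `NA` at zero spin).
#' @examples
#' body <- body_landmarks()
#' summarize_configs(list(
#'   LAHC = centrifuge_config(8.00, 2.4, body),
#'   P2   = centrifuge_config("P2", 2.4, body)), body)
#' @export
summarize_configs <- function(configs, body = body_landmarks(),
                              head_landmark = "crown") {
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    g_head <- signed_g_at(cfg, body, head_landmark)
    data.frame(
      config = if (!is.null(names(configs)) && nzchar(names(configs)[i]))
        names(configs)[i] else cfg$label,
      g_head = g_head, g_foot = cfg$g_foot, delta_g = cfg$g_foot - g_head,
      gradient_pct = if (cfg$g_foot > 0)
        100 * (cfg$g_foot - g_head) / cfg$g_foot else NA_real_)
  })
  do.call(rbind, rows)
}
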