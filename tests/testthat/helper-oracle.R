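# Independent oracles, deliberately kept separate from the implementation
# paths they check.

# Numeric path integral of the radial pressure gradient rho * omega^2 * r
# from the heart radius to the landmark radius (trapezoid rule).
trapz_pressure <- function(config, body, landmark, n = 1e4) {
  h <- if (is.character(landmark)) body[[landmark]] else landmark
  r_p <- abs(config$axis_height - h)
  r_h <- abs(config$axis_height - body$heart)
  r <- seq(r_h, r_p, length.out = n + 1)
  f <- config$rho * config$omega^2 * r
  sum((f[-1] + f[-length(f)]) / 2 * diff(r)) * config$k_bp
}

# Profiled maximum-likelihood log-likelihood of the random-intercept model
# y = X b + u_id + e on a (sigma_b, sigma_e) grid, via the closed-form
# inverse of V_i = se2 I + sb2 J (one block per participant).  Independent
# of lme4.
lmm_grid_loglik <- function(y, X, id, sb_grid, se_grid) {
  groups <- split(seq_along(y), id)
  best <- -Inf
  n <- length(y)
  for (sb in sb_grid) for (se in se_grid) {
    sb2 <- sb^2; se2 <- se^2
    XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X))
    logdet <- 0
    for (g in groups) {
      ni <- length(g)
      Xi <- X[g, , drop = FALSE]; yi <- y[g]
      a <- sb2 / (se2 * (se2 + ni * sb2))
      XtVX <- XtVX + (crossprod(Xi) / se2 - a * tcrossprod(colSums(Xi)))
      XtVy <- XtVy + (crossprod(Xi, yi) / se2 - a * colSums(Xi) * sum(yi))
      logdet <- logdet + (ni - 1) * log(se2) + log(se2 + ni * sb2)
    }
    beta <- solve(XtVX, XtVy)
    quad <- 0
    for (g in groups) {
      ri <- y[g] - X[g, , drop = FALSE] %*% beta
      ni <- length(ri)
      quad <- quad + sum(ri^2) / se2 -
        sb2 / (se2 * (se2 + ni * sb2)) * sum(ri)^2
    }
    ll <- -0.5 * (n * log(2 * pi) + logdet + quad)
    if (ll > best) best <- ll
  }
  best
}
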