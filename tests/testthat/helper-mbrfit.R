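# Shared helpers for the mbrfit test suite. Fixtures are built in code.

# Independent brute-force weighted least-squares oracle: explicit direct-sum
# normal equations solved as a 2x2 system. Deliberately uses a different
# algebraic route than fit_wlr (no centering).
wls_oracle <- function(t, y, w) {
  s0 <- sum(w); s1 <- sum(w * t); s2 <- sum(w * t * t)
  sy <- sum(w * y); sty <- sum(w * t * y)
  det <- s0 * s2 - s1 * s1
  slope <- (s0 * sty - s1 * sy) / det
  intercept <- (s2 * sy - s1 * sty) / det
  list(slope = slope, intercept = intercept)
}

# Independent adjusted weighted R^2 via plain loops.
adj_r2_oracle <- function(y, yhat, w, p = 2) {
  n <- length(y)
  ybar <- sum(w * y) / sum(w)
  sse <- 0; sst <- 0
  for (i in seq_len(n)) {
    sse <- sse + w[i] * (y[i] - yhat[i])^2
    sst <- sst + w[i] * (y[i] - ybar)^2
  }
  r2 <- 1 - sse / sst
  1 - (1 - r2) * (n - 1) / (n - p)
}

# A raw-well tibble from vectors.
raw_well <- function(backscatter, dt_h = 0.15) {
  tibble::tibble(time_h = seq_along(backscatter) * dt_h - dt_h,
                 backscatter = backscatter)
}

# A blanked-curve tibble from vectors.
blanked <- function(value, error = 0, dt_h = 0.15) {
  tibble::tibble(time_h = seq_along(value) * dt_h - dt_h,
                 value = value, error = rep(error, length(value)))
}

# Noise-free single-phase spec whose lag and phase-1 boundary sit on the
# sampling grid, so the stationary level equals the last exponential sample
# (no mid-phase plateau cap): exact recovery is then well defined.
exact_spec <- function(mu, c0 = 0.2, t_lag = 3, growth_to = 40 * c0,
                       cycle_min = 9, seed = 1) {
  dt <- cycle_min / 60
  t_lag <- round(t_lag / dt) * dt
  len <- ceiling(log(growth_to / c0) / mu / dt) * dt
  curve_spec(blank_level = 20, noise_sd = 0, c0 = c0, mu1 = mu,
             t_lag = t_lag, t_phase1_end = t_lag + len,
             plateau = 4 * growth_to, t_total = t_lag + len + 2,
             cycle_min = cycle_min, seed = seed)
}
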