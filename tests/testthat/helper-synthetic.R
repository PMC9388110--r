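# Shared small fixtures and independent oracles used across test files.

grid96 <- seq(0, 96, by = 0.2)

cosine_trace <- function(period = 26, first_peak = 5, duration = 96,
                         dt = 0.2, amplitude = 1, baseline = 1) {
  t <- seq(0, duration, by = dt)
  trace_series(t, baseline + amplitude * cos(2 * pi * (t - first_peak) / period),
               channel = "reporter", cell_id = "cosine")
}

# brute-force per-point OLS slope (independent oracle for slope_estimate)
ols_slope_oracle <- function(time, value, half_window = 4) {
  dt <- time[2] - time[1]
  h <- round(half_window / dt)
  n <- length(value)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    unname(coef(lm(value[w] ~ time[w]))[2])
  }, numeric(1))
}

# Mann-Whitney AUC oracle with tie credit
mw_auc_oracle <- function(stat_pos, stat_neg) {
  s <- 0
  for (x in stat_pos) s <- s + sum(x > stat_neg) + 0.5 * sum(x == stat_neg)
  s / (length(stat_pos) * length(stat_neg))
}

# plain fixed-step RK4 integrator over the exported scalar right-hand side
# (independent of the package's vectorized ensemble integrator)
rk4_cell_oracle <- function(params, noise, t_end, output_dt = 12, dt = 2) {
  times <- seq(0, t_end, by = output_dt)
  y <- rep(0, 7)
  out <- matrix(NA_real_, length(times), 7)
  out[1, ] <- y
  ki <- 2
  nstep <- round(t_end / dt)
  f <- function(t, y) as.numeric(clock_derivatives(pmax(y, 0), t, params, noise))
  for (i in seq_len(nstep)) {
    t0 <- (i - 1) * dt
    k1 <- f(t0, y); k2 <- f(t0 + dt / 2, y + dt / 2 * k1)
    k3 <- f(t0 + dt / 2, y + dt / 2 * k2); k4 <- f(t0 + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (ki <= length(times) && abs(i * dt - times[ki]) < dt / 2) {
      out[ki, ] <- y
      ki <- ki + 1
    }
  }
  colnames(out) <- c("mPPARG", "PPARG", "PPARG_star", "mCEBPA", "CEBPA",
                     "mSlowFBP", "SlowFBP")
  list(times = times, states = out, total = out[, 2] + out[, 3])
}

circ_dist <- function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi)

retrace_test <- function(tr, values) {
  trace_series(tr$time, values, tr$channel, tr$cell_id)
}
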