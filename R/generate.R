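#' Configuration for the synthetic dual-reporter trace generator
#'
#' Builds and validates the parameter set for [generate_population()]. The
#' defaults emulate the statistical structure of dual-reporter (PPARG +
#' Rev-Erb-alpha) adipogenesis imaging data: 12-min sampling over 4 days, a
#' ~26-h reporter period with 5% cell-to-cell CV, a ~12-h delayed first
#' reporter peak under a DMI-like stimulus, lengthened periods under a
#' LH846-like treatment, a flat reporter under Bmal1 knockdown, bimodal
#' terminal PPARG fates with a ~4-h commitment switch, commitment phases
#' gated to the rising reporter half-cycle, and rare (<5%), early, exact
#' H2B halvings marking divisions.
#'
#' @param n_cells Number of cells.
#' @param condition One of `"control"`, `"rosi"`, `"dmi"`, `"lh846"`,
#'   `"bmal1_kd"`.
#' @param dt Sampling interval in hours (default 0.2, i.e. 12 min).
#' @param duration Trace duration in hours (default 96); must be a multiple
#'   of `dt` and contain at least one full reporter cycle.
#' @param reporter_period_mean,reporter_period_cv Mean (h) and CV of the
#'   per-cell reporter period (defaults 26 and 0.05).
#' @param reporter_amplitude,reporter_baseline Reporter waveform amplitude
#'   and baseline (a.u.).
#' @param dmi_first_peak_delay Delay of the first reporter peak under the
#'   DMI-like condition (default 12 h).
#' @param lh846_period_factor Multiplicative period lengthening under the
#'   LH846-like condition (default 1.25).
#' @param frac_differentiating Fraction of cells that differentiate;
#'   defaults to 0 for `"control"` and 0.5 otherwise.
#' @param gating_window Phase interval (radians, subset of `[0, 2*pi]`) to
#'   which commitment phases are gated (default `c(pi, 2*pi)`, the rising
#'   reporter half-cycle).
#' @param commit_switch_duration 10-90% rise time of the commitment switch
#'   (default 4 h).
#' @param pparg_low,pparg_high,pparg_threshold_true Low-state baseline,
#'   high-state plateau and true commitment threshold of PPARG (a.u.).
#' @param slope_modulation_depth Depth of the circadian modulation of the
#'   pre-commitment PPARG slope (default 0.3); the modulation peaks at
#'   reporter phase 1.4*pi.
#' @param measurement_noise_cv Multiplicative lognormal measurement noise CV
#'   per time point (default 0.05).
#' @param division_prob Probability that a cell divides (once, within the
#'   first 24 h; default 0.05).
#' @param commit_cycle_p Success parameter of the truncated-geometric choice
#'   of the commitment cycle (default 0.35).
#' @param seed Master seed; identical seeds reproduce identical populations
#'   bit for bit, and each cell consumes its own random substream so cell
#'   `i`'s trace does not depend on `n_cells`.
#' @return A validated list of class `cg_generator_config`.
#' @export
generator_config <- function(n_cells = 100,
                             condition = c("control", "rosi", "dmi",
                                           "lh846", "bmal1_kd"),
                             dt = 0.2, duration = 96,
                             reporter_period_mean = 26,
                             reporter_period_cv = 0.05,
                             reporter_amplitude = 1,
                             reporter_baseline = 1,
                             dmi_first_peak_delay = 12,
                             lh846_period_factor = 1.25,
                             frac_differentiating = NULL,
                             gating_window = c(pi, 2 * pi),
                             commit_switch_duration = 4,
                             pparg_low = 0.2, pparg_high = 2,
                             pparg_threshold_true = 1.2,
                             slope_modulation_depth = 0.3,
                             measurement_noise_cv = 0.05,
                             division_prob = 0.05,
                             commit_cycle_p = 0.35,
                             seed = 1) {
  condition <- match.arg(condition)
  if (is.null(frac_differentiating))
    frac_differentiating <- if (condition == "control") 0 else 0.5
  stopifnot(n_cells >= 0, dt > 0, duration > 0)
  if (abs(duration / dt - round(duration / dt)) > 1e-8)
    stop("duration must be an integer multiple of dt", call. = FALSE)
  if (gating_window[1] < 0 || gating_window[2] > 2 * pi ||
      gating_window[1] >= gating_window[2])
    stop("gating_window must be an increasing interval within [0, 2*pi]",
         call. = FALSE)
  if (!(pparg_low < pparg_threshold_true && pparg_threshold_true < pparg_high))
    stop("require pparg_low < pparg_threshold_true < pparg_high",
         call. = FALSE)
  if (2 * pparg_threshold_true - pparg_high <= pparg_low)
    stop("commitment switch geometry needs 2*threshold - high > low",
         call. = FALSE)
  if (frac_differentiating < 0 || frac_differentiating > 1)
    stop("frac_differentiating must be in [0, 1]", call. = FALSE)
  if (lh846_period_factor <= 1)
    stop("lh846_period_factor must exceed 1", call. = FALSE)
  if (division_prob < 0 || division_prob > 1)
    stop("division_prob must be in [0, 1]", call. = FALSE)
  structure(list(
    n_cells = as.integer(n_cells), condition = condition, dt = dt,
    duration = duration, reporter_period_mean = reporter_period_mean,
    reporter_period_cv = reporter_period_cv,
    reporter_amplitude = reporter_amplitude,
    reporter_baseline = reporter_baseline,
    dmi_first_peak_delay = dmi_first_peak_delay,
    lh846_period_factor = lh846_period_factor,
    frac_differentiating = frac_differentiating,
    gating_window = gating_window,
    commit_switch_duration = commit_switch_duration,
    pparg_low = pparg_low, pparg_high = pparg_high,
    pparg_threshold_true = pparg_threshold_true,
    slope_modulation_depth = slope_modulation_depth,
    measurement_noise_cv = measurement_noise_cv,
    division_prob = division_prob, commit_cycle_p = commit_cycle_p,
    seed = as.integer(seed)),
    class = "cg_generator_config")
}

# internal: multiplicative lognormal measurement noise with unit mean
apply_noise <- function(values, cv) {
  if (cv <= 0) return(values)
  s <- sqrt(log(1 + cv^2))
  values * exp(rnorm(length(values), -s^2 / 2, s))
}

#' Generate one synthetic reporter trace
#'
#' Draws a per-cell circadian period and produces a raised-cosine
#' Rev-Erb-alpha-like reporter trace with the condition rules: under the
#' DMI-like condition the whole oscillation (hence the first peak) is
#' shifted later by `dmi_first_peak_delay` with unchanged subsequent
#' periods; under the LH846-like condition all periods are multiplied by
#' `lh846_period_factor`; under Bmal1 knockdown the trace is a flat baseline
#' plus noise. Consumes the current RNG stream (callers seed per cell).
#'
#' @param cfg A [generator_config()].
#' @return A list: `trace` (noisy [trace_series()], channel `"reporter"`),
#'   `anchors` (exact noise-free peak/trough times as an [anchor_set()]),
#'   `period` (the cell's drawn period, h), `first_peak` (h, `NA` for
#'   Bmal1 knockdown).
#' @export
generate_reporter_trace <- function(cfg) {
  t <- seq(0, cfg$duration, by = cfg$dt)
  period <- rnorm(1, cfg$reporter_period_mean,
                  cfg$reporter_period_cv * cfg$reporter_period_mean)
  period <- max(period, 0.5 * cfg$reporter_period_mean)
  t1 <- runif(1, 2, 8)
  if (cfg$condition == "bmal1_kd") {
    level <- cfg$reporter_baseline + cfg$reporter_amplitude / 2
    tr <- trace_series(t, apply_noise(rep(level, length(t)),
                                      cfg$measurement_noise_cv),
                       channel = "reporter")
    return(list(trace = tr,
                anchors = anchor_set(numeric(0), character(0),
                                     flag = "no_oscillation"),
                period = NA_real_, first_peak = NA_real_))
  }
  if (cfg$condition == "dmi") t1 <- t1 + cfg$dmi_first_peak_delay
  if (cfg$condition == "lh846") period <- period * cfg$lh846_period_factor
  u <- (t - t1) / period
  clean <- cfg$reporter_baseline +
    cfg$reporter_amplitude * (1 + cos(2 * pi * u)) / 2
  kmin <- ceiling(-t1 / period)                # first cycle index with anchors
  kmax <- floor((cfg$duration - t1) / period)
  anchor_t <- numeric(0); anchor_k <- character(0)
  for (k in seq(kmin, kmax + 1L)) {
    tp <- t1 + k * period
    tt <- t1 + (k - 0.5) * period
    if (tt >= 0 && tt <= cfg$duration) {
      anchor_t <- c(anchor_t, tt); anchor_k <- c(anchor_k, "trough")
    }
    if (tp >= 0 && tp <= cfg$duration) {
      anchor_t <- c(anchor_t, tp); anchor_k <- c(anchor_k, "peak")
    }
  }
  o <- order(anchor_t)
  spac <- diff(anchor_t[o][anchor_k[o] == "peak"])
  list(trace = trace_series(t, apply_noise(clean, cfg$measurement_noise_cv),
                            channel = "reporter"),
       anchors = anchor_set(anchor_t[o], anchor_k[o],
                            mean_period = if (length(spac)) mean(spac)
                                          else NA_real_,
                            period_sd = if (length(spac) > 1L) sd(spac)
                                        else NA_real_),
       period = period, first_peak = t1)
}

#' Generate one synthetic PPARG trace
#'
#' Produces the gradual multi-day PPARG rise with its slope multiplicatively
#' modulated at the reporter's rising phase (modulation peaking at reporter
#' phase 1.4*pi, depth `slope_modulation_depth`). Differentiated cells add a
#' logistic commitment switch centered at `commit_time` whose 10-90% rise
#' time equals `commit_switch_duration` and whose geometry guarantees the
#' noise-free trace first crosses `pparg_threshold_true` exactly at
#' `commit_time` and plateaus at `pparg_high`; undifferentiated cells stay
#' strictly below the threshold. Consumes the current RNG stream.
#'
#' @param cfg A [generator_config()].
#' @param anchors The cell's true [anchor_set()] (may be empty).
#' @param fate `"differentiated"` or `"undifferentiated"`.
#' @param commit_time Commitment time in hours (required iff
#'   differentiated); must lie in `[0, duration]`.
#' @return A noisy PPARG [trace_series()].
#' @export
generate_pparg_trace <- function(cfg, anchors, fate, commit_time = NULL) {
  t <- seq(0, cfg$duration, by = cfg$dt)
  diffed <- identical(fate, "differentiated")
  if (diffed && is.null(commit_time))
    stop("differentiated cells need a commit_time", call. = FALSE)
  if (!diffed && !is.null(commit_time))
    stop("undifferentiated cells cannot have a commit_time", call. = FALSE)
  if (diffed && (commit_time < 0 || commit_time > cfg$duration))
    stop("commit_time outside the trace duration", call. = FALSE)
  mod <- rep(1, length(t))
  if (length(anchors$anchor_times) >= 2L) {
    map <- build_phase_map(anchors)
    ph <- phase_at_time(map, t)
    in_map <- !is.na(ph)
    mod[in_map] <- 1 + cfg$slope_modulation_depth * cos(ph[in_map] - 1.4 * pi)
  }
  G <- cumsum(mod) * cfg$dt
  low <- cfg$pparg_low; thr <- cfg$pparg_threshold_true; high <- cfg$pparg_high
  if (diffed) {
    A <- 2 * (high - thr)
    b_tc <- 2 * thr - high
    Gc <- approx(t, G, xout = commit_time)$y
    base <- low + (b_tc - low) * pmin(G / Gc, 1)
    s <- cfg$commit_switch_duration / log(81)   # 10-90% rise = switch duration
    clean <- base + A / (1 + exp(-(t - commit_time) / s))
  } else {
    f_end <- runif(1, 0.5, 0.85)
    target <- low + f_end * (thr - low)
    clean <- low + (target - low) * G / G[length(G)]
  }
  trace_series(t, apply_noise(clean, cfg$measurement_noise_cv),
               channel = "pparg")
}

#' Generate a synthetic dual-reporter cell population with ground truth
#'
#' Generates `n_cells` cells with three channels each (`pparg`, `reporter`,
#' `h2b_total`) plus complete ground truth. Differentiated cells draw a
#' commitment cycle from a truncated geometric distribution over the
#' complete reporter cycles (excluding cycles ending within 6 h of the
#' experiment end so the switch can complete), then a phase uniform in the
#' gating window, converted to time through the cell's exact anchors. H2B
#' is constant except for an exact halving at the division time (at most
#' one division, within the first 24 h, probability `division_prob`).
#' Bmal1-knockdown cells have no reporter phase; their commitment times are
#' drawn from a single Gaussian (48 +/- 6 h), reproducing the single
#' commitment wave seen without a functional clock.
#'
#' @param cfg A [generator_config()].
#' @return An object of class `cg_population`: `traces` (a `data.table` with
#'   columns `cell_id,time_h,channel,value`), `ground_truth` (per-cell list
#'   with `fate`, `true_commit_time`, `true_commit_phase`,
#'   `true_anchor_times`, `true_anchor_kinds`, `division_times`, `period`,
#'   `first_peak`), and `config`.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "cg_generator_config"))
  if (cfg$duration < cfg$reporter_period_mean)
    stop("duration too short to contain one full reporter cycle",
         call. = FALSE)
  set.seed(cfg$seed)
  cell_seeds <- floor(runif(cfg$n_cells, 1, 2^31 - 1))
  traces <- vector("list", cfg$n_cells)
  truth <- vector("list", cfg$n_cells)
  t <- seq(0, cfg$duration, by = cfg$dt)
  for (i in seq_len(cfg$n_cells)) {
    set.seed(cell_seeds[i])
    id <- sprintf("cell_%04d", i)
    rep_out <- generate_reporter_trace(cfg)
    anchors <- rep_out$anchors
    fate <- if (runif(1) < cfg$frac_differentiating) "differentiated"
            else "undifferentiated"
    tc <- NULL; phi <- NA_real_
    if (fate == "differentiated") {
      if (cfg$condition == "bmal1_kd") {
        tc <- min(max(rnorm(1, 48, 6), 12), cfg$duration - 12)
      } else {
        map <- build_phase_map(anchors)
        peaks_u <- map$phase_unwrapped[map$anchor_kinds == "peak"]
        u_last <- max(map$phase_unwrapped)
        ok <- which(peaks_u + 2 * pi <= u_last &
                    vapply(peaks_u + 2 * pi, function(u)
                      time_at_phase(map, u) <= cfg$duration - 6, logical(1)))
        if (length(ok) == 0L) {
          fate <- "undifferentiated"
        } else {
          K <- length(ok)
          w <- cfg$commit_cycle_p * (1 - cfg$commit_cycle_p)^(seq_len(K) - 1L)
          k <- ok[sample.int(K, 1L, prob = w / sum(w))]
          phi <- runif(1, cfg$gating_window[1], cfg$gating_window[2])
          tc <- time_at_phase(map, peaks_u[k] + phi)
        }
      }
    }
    pparg <- generate_pparg_trace(cfg, anchors, fate, tc)
    h <- 100 * exp(rnorm(1, 0, 0.2))
    div_t <- numeric(0)
    if (runif(1) < cfg$division_prob) {
      div_t <- round(runif(1, 0, 24) / cfg$dt) * cfg$dt
    }
    h2b_clean <- rep(h, length(t))
    if (length(div_t)) h2b_clean[t >= div_t] <- h / 2
    h2b <- trace_series(t, apply_noise(h2b_clean, cfg$measurement_noise_cv),
                        channel = "h2b_total")
    traces[[i]] <- data.table::data.table(
      cell_id = id,
      time_h = rep(t, 3L),
      channel = rep(c("pparg", "reporter", "h2b_total"), each = length(t)),
      value = c(pparg$value, rep_out$trace$value, h2b$value))
    truth[[i]] <- list(
      cell_id = id, fate = fate,
      true_commit_time = if (is.null(tc)) NA_real_ else tc,
      true_commit_phase = phi,
      true_anchor_times = anchors$anchor_times,
      true_anchor_kinds = anchors$anchor_kinds,
      division_times = div_t,
      period = rep_out$period, first_peak = rep_out$first_peak,
      h2b_baseline = h)
  }
  names(truth) <- vapply(truth, `[[`, character(1), "cell_id")
  structure(list(traces = data.table::rbindlist(traces),
                 ground_truth = truth, config = cfg),
            class = "cg_population")
}

#' @export
print.cg_population <- function(x, ...) {
  nd <- sum(vapply(x$ground_truth, function(g) g$fate == "differentiated",
                   logical(1)))
  cat(sprintf("<cg_population> %d cells (%s), %d differentiated; %d trace rows\n",
              x$config$n_cells, x$config$condition, nd, nrow(x$traces)))
  invisible(x)
}

#' Extract per-cell traces of one channel from a population
#'
#' @param pop A [generate_population()] result (or any trace table with
#'   columns `cell_id,time_h,channel,value`).
#' @param channel Channel to extract.
#' @return A named list of [trace_series()] objects.
#' @export
population_traces <- function(pop, channel = "pparg") {
  tab <- if (inherits(pop, "cg_population")) pop$traces else pop
  tab <- tab[tab$channel == channel, ]
  sp <- split(tab, tab$cell_id)
  lapply(sp, function(d) trace_series(d$time_h, d$value, channel,
                                      d$cell_id[1]))
}
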