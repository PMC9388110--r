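#' Piecewise-linear reporter phase map
#'
#' Converts the anchor skeleton of a reporter trace into circadian phase by
#' defining each peak as phase 0 (mod 2*pi) and each trough as phase pi, with
#' linear interpolation in between. The map is valid between the first and
#' last anchor; phase increases by pi across every anchor-to-anchor segment.
#'
#' @param anchors A [anchor_set()] with at least two alternating anchors.
#' @return An object of class `cg_phasemap` with `anchor_times`,
#'   `anchor_kinds`, `phase_unwrapped` (knot values, radians), and
#'   `valid_interval`. `NULL` (with a message attribute-free return) is never
#'   used: fewer than two anchors is an error so callers can exclude the
#'   cell.
#' @export
build_phase_map <- function(anchors) {
  stopifnot(inherits(anchors, "cg_anchors"))
  t <- anchors$anchor_times
  if (length(t) < 2L)
    stop("at least two alternating anchors are required", call. = FALSE)
  u0 <- if (anchors$anchor_kinds[1] == "peak") 0 else pi
  u <- u0 + pi * (seq_along(t) - 1L)
  structure(list(anchor_times = t, anchor_kinds = anchors$anchor_kinds,
                 phase_unwrapped = u, valid_interval = range(t)),
            class = "cg_phasemap")
}

#' Phase of a time point under a phase map
#'
#' @param map A [build_phase_map()] object.
#' @param time Times in hours (inside the valid interval).
#' @param wrap Return phase wrapped to `[0, 2*pi)` (default) or unwrapped.
#' @return Phase in radians; `NA` outside the valid interval.
#' @export
phase_at_time <- function(map, time, wrap = TRUE) {
  u <- approx(map$anchor_times, map$phase_unwrapped, xout = time,
              rule = 1)$y
  if (wrap) u %% (2 * pi) else u
}

#' Time at an unwrapped phase under a phase map
#'
#' Inverse of [phase_at_time()] on the unwrapped phase axis.
#'
#' @param map A [build_phase_map()] object.
#' @param phase_unwrapped Unwrapped phase in radians.
#' @return Time in hours; `NA` outside the mapped phase range.
#' @export
time_at_phase <- function(map, phase_unwrapped) {
  approx(map$phase_unwrapped, map$anchor_times, xout = phase_unwrapped,
         rule = 1)$y
}

#' Project a commitment event into phase-time space
#'
#' Computes the circadian phase of a commitment time relative to the cell's
#' reporter oscillation, together with the time since the last reporter
#' peak. Commitments before the first detected peak or after the last anchor
#' are excluded (returned as `NULL`) rather than extrapolated.
#'
#' @param map A [build_phase_map()] object.
#' @param commit_time Commitment time in hours.
#' @param cell_id Optional cell identifier carried through.
#' @return A one-row data.frame (`cell_id`, `commit_time`, `commit_phase`,
#'   `time_since_last_peak`) or `NULL` when the commitment is outside the
#'   mapped interval.
#' @export
commitment_phase <- function(map, commit_time, cell_id = NA_character_) {
  peaks <- map$anchor_times[map$anchor_kinds == "peak"]
  if (length(peaks) == 0L) return(NULL)
  if (commit_time < peaks[1] || commit_time > map$valid_interval[2])
    return(NULL)
  ph <- phase_at_time(map, commit_time)
  last_peak <- max(peaks[peaks <= commit_time])
  data.frame(cell_id = cell_id, commit_time = commit_time,
             commit_phase = ph, time_since_last_peak = commit_time - last_peak,
             stringsAsFactors = FALSE)
}

#' Gaussian-mixture fit of commitment-time distributions
#'
#' Fits univariate Gaussian mixtures with 1 to `k_max` components to a set
#' of commitment times by EM and selects the number of components by BIC
#' (via \pkg{mclust}, whose model-based hierarchical initialization makes the
#' fit deterministic). Components are reported sorted by mean; daily bursts
#' of commitment show up as components spaced by about one circadian period.
#'
#' @param commit_times Commitment times in hours (>= 50 recommended).
#' @param k_max Maximum number of components (default 5).
#' @return An object of class `cg_gmm`: `k`, `weights`, `means`, `sds`,
#'   `loglik`, `bic`.
#' @export
fit_commitment_time_gmm <- function(commit_times, k_max = 5) {
  x <- as.numeric(commit_times)
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    stop("need at least two commitment times", call. = FALSE)
  if (length(x) < 50L)
    warning("fewer than 50 commitment times; mixture fit is unstable")
  if (diff(range(x)) < sqrt(.Machine$double.eps)) {
    return(structure(list(k = 1L, weights = 1, means = mean(x),
                          sds = 1e-3, loglik = NA_real_, bic = NA_real_),
                     class = "cg_gmm"))
  }
  fit <- mclust::Mclust(x, G = seq_len(k_max), modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit))
    stop("Gaussian mixture fit failed", call. = FALSE)
  p <- fit$parameters
  mu <- as.numeric(p$mean)
  w <- if (length(mu) == 1L) 1 else as.numeric(p$pro)
  s <- sqrt(as.numeric(p$variance$sigmasq))
  if (length(s) == 1L) s <- rep(s, length(mu))
  o <- order(mu)
  structure(list(k = length(mu), weights = w[o], means = mu[o],
                 sds = pmax(s[o], 1e-6), loglik = fit$loglik, bic = fit$bic),
            class = "cg_gmm")
}

#' @export
print.cg_gmm <- function(x, ...) {
  cat(sprintf("<cg_gmm> k = %d components\n", x$k))
  print(data.frame(weight = round(x$weights, 3), mean = round(x$means, 2),
                   sd = round(x$sds, 2)))
  invisible(x)
}

#' One-term Fourier fit of a phase distribution
#'
#' Bins commitment phases on `[0, 2*pi)`, converts counts to a density, and
#' least-squares fits `a0 + a1*cos(phase) + b1*sin(phase)`. The implied peak
#' phase `atan2(b1, a1)` localizes the preferred commitment phase of the
#' population.
#'
#' @param phases Phases in radians (>= 50 recommended).
#' @param n_bins Number of histogram bins (default 24).
#' @return An object of class `cg_fourier`: `a0`, `a1`, `b1`, `peak_phase`
#'   (radians in `[0, 2*pi)`), `gof` (R^2), `density`, `bin_centers`.
#' @export
fit_phase_fourier <- function(phases, n_bins = 24) {
  x <- as.numeric(phases) %% (2 * pi)
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least two phases", call. = FALSE)
  if (length(x) < 50L)
    warning("fewer than 50 phases; Fourier fit is unstable")
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  if (sum(counts > 0L) < 2L)
    stop("degenerate phase distribution: all mass in one bin", call. = FALSE)
  width <- 2 * pi / n_bins
  dens <- counts / (length(x) * width)
  mid <- breaks[-1] - width / 2
  fit <- lm(dens ~ cos(mid) + sin(mid))
  cf <- coef(fit)
  gof <- 1 - sum(fit$residuals^2) / sum((dens - mean(dens))^2)
  structure(list(a0 = unname(cf[1]), a1 = unname(cf[2]), b1 = unname(cf[3]),
                 peak_phase = unname(atan2(cf[3], cf[2])) %% (2 * pi),
                 gof = gof, density = dens, bin_centers = mid),
            class = "cg_fourier")
}

#' @export
print.cg_fourier <- function(x, ...) {
  cat(sprintf("<cg_fourier> peak phase %.3f rad (%.2f pi), R^2 = %.3f\n",
              x$peak_phase, x$peak_phase / pi, x$gof))
  invisible(x)
}

#' Phase-folded slope statistics with bootstrap confidence bands
#'
#' Aligns and rescales slope traces to circadian phase 0 to 2*pi for every
#' complete peak-to-peak reporter period, averages periods within each cell
#' and then cells, and attaches 95% percentile bootstrap confidence
#' intervals obtained by resampling cells (periods within a cell are
#' correlated, so the cell is the resampling unit). The phase of the maximum
#' of the mean curve localizes when during the circadian cycle the synthesis
#' rate peaks.
#'
#' @param slope_traces Named list of slope [trace_series()] objects (see
#'   [slope_estimate()]).
#' @param phase_maps Named list of [build_phase_map()] objects (matched by
#'   name).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param grid Number of phase grid points (default 48).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `cg_phasefold`: `phase` (grid), `mean`,
#'   `ci_lower`, `ci_upper`, `argmax_phase`, `n_cells`, `n_periods`.
#' @export
phase_fold_slopes <- function(slope_traces, phase_maps, n_boot = 1000,
                              grid = 48, seed = 1) {
  ids <- intersect(names(slope_traces), names(phase_maps))
  phi <- (seq_len(grid) - 1L) * 2 * pi / grid
  cell_curves <- list()
  n_periods <- 0L
  for (id in ids) {
    map <- phase_maps[[id]]
    tr <- as_trace(slope_traces[[id]])
    peaks_u <- map$phase_unwrapped[map$anchor_kinds == "peak"]
    if (length(peaks_u) < 2L) next
    per_curves <- list()
    for (k in seq_len(length(peaks_u) - 1L)) {
      uq <- peaks_u[k] + phi
      tq <- time_at_phase(map, uq)
      if (anyNA(tq)) next
      vq <- approx(tr$time, tr$value, xout = tq, rule = 1)$y
      if (anyNA(vq)) next
      per_curves[[length(per_curves) + 1L]] <- vq
    }
    if (length(per_curves) == 0L) next
    n_periods <- n_periods + length(per_curves)
    cell_curves[[id]] <- colMeans(do.call(rbind, per_curves))
  }
  if (length(cell_curves) == 0L)
    stop("no complete peak-to-peak periods available", call. = FALSE)
  cmat <- do.call(rbind, cell_curves)
  mean_curve <- colMeans(cmat)
  nc <- nrow(cmat)
  if (!is.null(seed)) set.seed(seed)
  boots <- matrix(NA_real_, n_boot, grid)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    boots[b, ] <- colMeans(cmat[idx, , drop = FALSE])
  }
  ci <- apply(boots, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(phase = phi, mean = mean_curve,
                 ci_lower = ci[1, ], ci_upper = ci[2, ],
                 argmax_phase = phi[which.max(mean_curve)],
                 n_cells = nc, n_periods = n_periods),
            class = "cg_phasefold")
}

#' @export
print.cg_phasefold <- function(x, ...) {
  cat(sprintf("<cg_phasefold> %d cells, %d periods; mean slope peaks at %.2f pi\n",
              x$n_cells, x$n_periods, x$argmax_phase / pi))
  invisible(x)
}

#' Permutation cosinor rhythmicity test
#'
#' Tests whether a time series is rhythmic at a stated period: the cosinor
#' amplitude (least-squares fit of `a0 + a1*cos + b1*sin` at the period) is
#' compared against its permutation distribution under random shuffling of
#' the time labels. Optionally the series is detrended first by subtracting
#' a centered moving average with a one-period span, which removes secular
#' trends that would otherwise inflate the amplitude.
#'
#' @param values Numeric series.
#' @param times Observation times (same units as `period`).
#' @param period Tested period.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation draw.
#' @param detrend Subtract a one-period moving average first (default
#'   `FALSE`).
#' @return A list: `p_value`, `amplitude`, `acrophase` (radians),
#'   `relative_amplitude` (amplitude over the mean absolute trend;
#'   `NA` unless `detrend = TRUE`), `n`.
#' @export
rhythmicity_test <- function(values, times, period, n_perm = 1000,
                             seed = 1, detrend = FALSE) {
  v <- as.numeric(values)
  t <- as.numeric(times)
  ok <- !is.na(v) & !is.na(t)
  v <- v[ok]; t <- t[ok]
  if (length(v) < 6L)
    stop("at least six time points are required", call. = FALSE)
  rel_amp <- NA_real_
  if (detrend) {
    dt <- median(diff(sort(t)))
    k <- max(3L, round(period / dt))
    if (k %% 2 == 0) k <- k + 1
    tr <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
    keep <- !is.na(tr)
    rel_trend <- mean(abs(tr[keep]))
    v <- v[keep] - tr[keep]
    t <- t[keep]
    if (length(v) < 6L)
      stop("too few points remain after detrending", call. = FALSE)
  }
  if (sd(v) < sqrt(.Machine$double.eps))
    return(list(p_value = 1, amplitude = 0, acrophase = NA_real_,
                relative_amplitude = 0, n = length(v)))
  cw <- cos(2 * pi * t / period)
  sw <- sin(2 * pi * t / period)
  amp_of <- function(y) {
    cf <- coef(lm(y ~ cw + sw))
    c(sqrt(cf[2]^2 + cf[3]^2), atan2(cf[3], cf[2]) %% (2 * pi))
  }
  obs <- amp_of(v)
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, amp_of(sample(v))[1])
  if (detrend) rel_amp <- unname(obs[1]) / rel_trend
  list(p_value = (1 + sum(perm >= obs[1])) / (n_perm + 1),
       amplitude = unname(obs[1]), acrophase = unname(obs[2]),
       relative_amplitude = rel_amp, n = length(v))
}
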