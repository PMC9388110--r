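#' Moving-average smoothing of a trace
#'
#' Centered moving average with a fixed span in hours (default 6 h, the span
#' used for all single-cell reporter trajectories in this workflow). At the
#' trace ends the window shrinks symmetrically, so no data are fabricated by
#' padding and the output stays on the input grid.
#'
#' @param ts A [trace_series()] object.
#' @param span Window width in hours (default 6). Must be at least one
#'   sampling interval.
#' @return A smoothed `cg_trace` on the same grid.
#' @examples
#' tr <- trace_series(seq(0, 96, 0.2), rnorm(481, 10), "pparg", "c1")
#' sm <- smooth_moving_average(tr)
#' @export
smooth_moving_average <- function(ts, span = 6) {
  ts <- as_trace(ts)
  dt <- trace_dt(ts)
  if (span < dt)
    stop("smoothing span must be at least one sampling interval", call. = FALSE)
  v <- ts$value
  n <- length(v)
  k <- round(span / dt)
  if (k %% 2 == 0) k <- k + 1       # force odd, centered window
  h <- (k - 1L) %/% 2L
  half <- pmin(h, seq_len(n) - 1L, n - seq_len(n))  # symmetric shrinkage
  cs <- cumsum(c(0, v))
  lo <- seq_len(n) - half
  hi <- seq_len(n) + half
  retrace(ts, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Windowed-regression slope of a trace
#'
#' At every time point, the ordinary least-squares slope of the trace over a
#' segment extending `half_window` hours to each side (default +/- 4 h, an
#' 8-h segment), truncated at the trace boundaries. Units are a.u. per hour.
#' This is the synthesis-rate proxy used throughout the phase analysis.
#'
#' @param ts A [trace_series()] object.
#' @param half_window Half-width of the regression window in hours
#'   (default 4).
#' @return A `cg_trace` of slopes on the same grid.
#' @examples
#' tr <- trace_series(seq(0, 96, 0.2), 2 + 0.5 * seq(0, 96, 0.2), "pparg")
#' all.equal(slope_estimate(tr)$value, rep(0.5, 481))
#' @export
slope_estimate <- function(ts, half_window = 4) {
  ts <- as_trace(ts)
  dt <- trace_dt(ts)
  h <- round(half_window / dt)
  n <- length(ts$value)
  if (n < h + 1L)
    stop("trace shorter than the regression window", call. = FALSE)
  if (h < 2L)
    stop("regression windows need at least 3 points", call. = FALSE)
  t <- ts$time
  v <- ts$value
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  c0 <- c(0, cumsum(rep(1, n)))
  ct <- c(0, cumsum(t))
  cv <- c(0, cumsum(v))
  ctt <- c(0, cumsum(t * t))
  ctv <- c(0, cumsum(t * v))
  m <- c0[hi + 1L] - c0[lo]
  st <- ct[hi + 1L] - ct[lo]
  sv <- cv[hi + 1L] - cv[lo]
  stt <- ctt[hi + 1L] - ctt[lo]
  stv <- ctv[hi + 1L] - ctv[lo]
  retrace(ts, (m * stv - st * sv) / (m * stt - st * st))
}

# internal: indices of local maxima of x with topographic prominence >= thr,
# separated by >= mpd samples (higher-prominence extrema win conflicts).
# A flank that reaches the trace boundary without a higher point and without
# descending by thr is uninformative (truncated by the observation window);
# prominence is then taken from the other flank alone.
prominent_extrema <- function(x, thr, mpd) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    higher_l <- which(x[seq_len(i - 1L)] > x[i])
    lo_l <- if (length(higher_l)) min(x[(max(higher_l)):(i - 1L)])
            else min(x[seq_len(i)])
    inf_l <- length(higher_l) > 0L || (x[i] - lo_l) >= thr
    right <- if (i < n) x[(i + 1L):n] else numeric(0)
    higher_r <- which(right > x[i])
    lo_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))])
            else min(x[i:n])
    inf_r <- length(higher_r) > 0L || (x[i] - lo_r) >= thr
    if (inf_l && inf_r) return(x[i] - max(lo_l, lo_r))
    # boundary-truncated flank: only accept candidates near the top of the
    # range, so mid-limb noise bumps next to the trace ends are rejected
    if (x[i] < max(x) - 2 * thr) return(0)
    if (inf_l) x[i] - lo_l else if (inf_r) x[i] - lo_r else 0
  }, numeric(1))
  keep <- cand[prom >= thr]
  prom <- prom[prom >= thr]
  if (length(keep) <= 1L) return(keep)
  o <- order(prom, decreasing = TRUE)
  sel <- integer(0)
  for (i in keep[o]) {
    if (all(abs(sel - i) >= mpd)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Peak/trough anchors of an oscillatory reporter trace
#'
#' Detects alternating peaks and troughs in a (smoothed) circadian reporter
#' trace. Candidate extrema are kept if their topographic prominence is at
#' least `min_prominence` of the trace range and they are separated by at
#' least `min_period` (higher-prominence extrema win conflicts); peaks and
#' troughs are then merged and forced to alternate by inserting the
#' extremal point between any two same-kind anchors. Finally the trace
#' must pass an affine-invariant rhythmicity gate: a cosine at the median
#' peak spacing has to explain at least `r2_min` of the variance, otherwise
#' the trace is treated as non-oscillatory (e.g. after Bmal1 knockdown) and
#' an empty anchor set is returned with a flag.
#'
#' @param ts A smoothed [trace_series()].
#' @param min_period Minimum peak separation in hours (default 12).
#' @param min_prominence Minimum peak-to-trough amplitude as a fraction of
#'   the trace range (default 0.1).
#' @param r2_min Minimum cosine fit R^2 for the trace to count as rhythmic
#'   (default 0.5).
#' @return An object of class `cg_anchors`: `anchor_times` (hours),
#'   `anchor_kinds` ("peak"/"trough"), `mean_period` and `period_sd` (hours,
#'   from successive peak spacings), and `flag` (`NA` when anchors were
#'   found; `"no_peaks"` or `"arrhythmic"` otherwise).
#' @export
detect_anchors <- function(ts, min_period = 12, min_prominence = 0.1,
                           r2_min = 0.5) {
  ts <- as_trace(ts)
  v <- ts$value
  t <- ts$time
  dt <- trace_dt(ts)
  rng <- diff(range(v))
  empty <- function(flag) anchor_set(numeric(0), character(0), flag = flag)
  if (rng <= 0) return(empty("no_peaks"))
  mpd <- max(1L, round(min_period / dt))
  thr <- min_prominence * rng
  ip <- prominent_extrema(v, thr, mpd)
  it <- prominent_extrema(-v, thr, mpd)
  if (length(ip) == 0L) return(empty("no_peaks"))
  idx <- c(ip, it)
  kind <- rep(c("peak", "trough"), c(length(ip), length(it)))
  o <- order(idx)
  idx <- idx[o]; kind <- kind[o]
  # force alternation: insert the extremum between two same-kind anchors
  repeat {
    same <- which(kind[-1] == kind[-length(kind)])
    if (length(same) == 0L) break
    j <- same[1]
    seg <- (idx[j] + 1L):(idx[j + 1L] - 1L)
    if (length(seg) == 0L) {         # adjacent duplicates: drop the weaker
      drop <- if (kind[j] == "peak") j + (v[idx[j]] >= v[idx[j + 1L]])
              else j + (v[idx[j]] <= v[idx[j + 1L]])
      idx <- idx[-drop]; kind <- kind[-drop]
      next
    }
    k <- if (kind[j] == "peak") seg[which.min(v[seg])] else seg[which.max(v[seg])]
    idx <- append(idx, k, after = j)
    kind <- append(kind, if (kind[j] == "peak") "trough" else "peak", after = j)
  }
  if (sum(kind == "peak") == 0L) return(empty("no_peaks"))
  # rhythmicity gate (affine invariant): cosine at median peak spacing
  pk <- t[idx[kind == "peak"]]
  per <- if (length(pk) >= 2L) median(diff(pk)) else {
    tr <- t[idx[kind == "trough"]]
    if (length(tr) >= 1L) 2 * min(abs(pk[1] - tr)) else NA_real_
  }
  if (!is.na(per) && per > 0) {
    fit <- lm(v ~ cos(2 * pi * t / per) + sin(2 * pi * t / per))
    r2 <- 1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
    if (r2 < r2_min) return(empty("arrhythmic"))
  } else return(empty("no_peaks"))
  spac <- diff(pk)
  anchor_set(t[idx], kind,
             mean_period = if (length(spac)) mean(spac) else NA_real_,
             period_sd = if (length(spac) > 1L) sd(spac) else NA_real_)
}

#' Anchor set constructor
#'
#' Ordered, strictly alternating peak/trough times of one reporter trace.
#'
#' @param anchor_times Increasing times in hours.
#' @param anchor_kinds Character vector of `"peak"`/`"trough"`, alternating.
#' @param mean_period,period_sd Summary of successive peak spacings (hours).
#' @param flag `NA` for a valid set, otherwise the reason it is empty.
#' @return A `cg_anchors` object.
#' @export
anchor_set <- function(anchor_times, anchor_kinds,
                       mean_period = NA_real_, period_sd = NA_real_,
                       flag = NA_character_) {
  anchor_times <- as.numeric(anchor_times)
  anchor_kinds <- as.character(anchor_kinds)
  if (length(anchor_times) != length(anchor_kinds))
    stop("anchor times and kinds differ in length", call. = FALSE)
  if (length(anchor_times)) {
    if (is.unsorted(anchor_times, strictly = TRUE))
      stop("anchor times must be strictly increasing", call. = FALSE)
    if (!all(anchor_kinds %in% c("peak", "trough")))
      stop("anchor kinds must be 'peak' or 'trough'", call. = FALSE)
    if (any(anchor_kinds[-1] == anchor_kinds[-length(anchor_kinds)]))
      stop("anchor kinds must alternate", call. = FALSE)
  }
  structure(list(anchor_times = anchor_times, anchor_kinds = anchor_kinds,
                 mean_period = mean_period, period_sd = period_sd,
                 flag = flag),
            class = "cg_anchors")
}

#' @export
print.cg_anchors <- function(x, ...) {
  if (length(x$anchor_times) == 0L) {
    cat(sprintf("<cg_anchors> empty (%s)\n", x$flag))
  } else {
    cat(sprintf("<cg_anchors> %d anchors (%d peaks), mean period %.2f h (sd %.2f)\n",
                length(x$anchor_times), sum(x$anchor_kinds == "peak"),
                x$mean_period, x$period_sd))
  }
  invisible(x)
}

#' Call cell divisions from total-H2B traces
#'
#' A division is called at the frame where both of the two nearest future
#' candidate cells carry a total nuclear H2B signal of 45 to 55% of the
#' original cell's. To be robust to frame-level intensity noise, the parent
#' reference is averaged over `window_h` hours before the frame and each
#' candidate over `window_h` hours after it. Consecutive qualifying frames
#' are collapsed to the first.
#'
#' @param h2b Parent total-H2B [trace_series()].
#' @param lineage_candidates List of exactly two candidate daughter traces on
#'   the same grid.
#' @param band Accepted daughter/parent ratio band (default `c(0.45, 0.55)`).
#' @param window_h Averaging window in hours (default 1).
#' @return Numeric vector of division times (hours); empty when none qualify.
#' @export
call_divisions <- function(h2b, lineage_candidates, band = c(0.45, 0.55),
                           window_h = 1) {
  h2b <- as_trace(h2b)
  if (length(lineage_candidates) != 2L)
    stop("exactly two lineage candidates are required", call. = FALSE)
  dt <- trace_dt(h2b)
  n <- length(h2b$value)
  k <- max(1L, round(window_h / dt))
  pre_mean <- function(v) {       # mean over window ending at i
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    lo <- pmax(1L, i - k + 1L)
    (cs[i + 1L] - cs[lo]) / (i - lo + 1L)
  }
  post_mean <- function(v) {      # mean over window starting at i
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    hi <- pmin(n, i + k - 1L)
    (cs[hi + 1L] - cs[i]) / (hi - i + 1L)
  }
  parent <- pre_mean(h2b$value)
  ok <- rep(TRUE, n)
  for (cand in lineage_candidates) {
    cand <- as_trace(cand)
    if (length(cand$value) != n)
      stop("candidate traces must share the parent's grid", call. = FALSE)
    ratio <- c(post_mean(cand$value)[-1L], NA) / parent
    ok <- ok & !is.na(ratio) & ratio >= band[1] & ratio <= band[2]
  }
  hits <- which(ok)
  if (length(hits) == 0L) return(numeric(0))
  first <- hits[c(TRUE, diff(hits) > 1L)]
  h2b$time[pmin(n, first + 1L)]
}
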