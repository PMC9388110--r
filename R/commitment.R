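#' Ground-truth fate cutoff from control cells
#'
#' The preset cutoff separating terminally differentiated from
#' undifferentiated cells is calibrated on unstimulated control cells: it is
#' the smallest observed terminal value such that strictly fewer than
#' `max_control_fraction` (default 3%) of control cells lie above it.
#' Implemented as the `ceiling((1 - f) * n)`-th order statistic, moved upward
#' through ties until the strict-fraction condition holds.
#'
#' @param control_terminals Numeric terminal PPARG values of control cells.
#' @param max_control_fraction Maximum tolerated fraction of control cells
#'   above the cutoff (default 0.03, strict).
#' @return The cutoff value (a.u.).
#' @examples
#' ground_truth_cutoff(1:100)  # 98: leaves 2% of controls above
#' @export
ground_truth_cutoff <- function(control_terminals, max_control_fraction = 0.03) {
  x <- as.numeric(control_terminals)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("no control terminal values supplied", call. = FALSE)
  if (n < 50L)
    warning("fewer than 50 control cells; cutoff calibration is unstable")
  s <- sort(x)
  k <- ceiling((1 - max_control_fraction) * n)
  while (k <= n && mean(x > s[k]) >= max_control_fraction) k <- k + 1L
  s[min(k, n)]
}

#' Terminal fate labels
#'
#' Scores each cell as differentiated or undifferentiated by comparing its
#' terminal PPARG value against a preset cutoff (see
#' [ground_truth_cutoff()]).
#'
#' @param terminal_values Named numeric vector (names are cell ids) of
#'   terminal PPARG values.
#' @param cutoff Cutoff value (a.u.).
#' @return A data.frame with `cell_id`, `terminal_value`, `label`
#'   (`"differentiated"`/`"undifferentiated"`) and `cutoff_used`.
#' @export
fate_labels <- function(terminal_values, cutoff) {
  ids <- names(terminal_values)
  if (is.null(ids)) ids <- as.character(seq_along(terminal_values))
  data.frame(
    cell_id = ids,
    terminal_value = as.numeric(terminal_values),
    label = ifelse(terminal_values > cutoff, "differentiated",
                   "undifferentiated"),
    cutoff_used = cutoff,
    stringsAsFactors = FALSE)
}

# internal: per-cell running-max prediction statistic
cell_max_stat <- function(traces) {
  vapply(traces, function(tr) max(as_trace(tr)$value), numeric(1))
}

#' ROC threshold scan for commitment-threshold calibration
#'
#' Surveys candidate PPARG thresholds to find the one that best predicts
#' terminal cell fate from the running maximum of each (smoothed) PPARG
#' trace: a cell is predicted differentiated if its trace ever exceeds the
#' threshold before the end of the experiment. True- and false-positive
#' rates are computed against the supplied fate labels, the area under the
#' ROC curve by the trapezoid rule, and the optimal threshold as the point
#' closest to the ideal corner (0, 1), with ties broken toward the lower
#' threshold.
#'
#' The evaluated threshold set is the union of `n_thresholds` quantiles of
#' the pooled per-cell maxima and every distinct observed maximum, so the
#' reported AUC is exact (it equals the Mann-Whitney statistic of the
#' per-cell maxima, with tie credit).
#'
#' @param traces Named list of smoothed PPARG [trace_series()] objects.
#' @param labels Data.frame from [fate_labels()] (matched to `traces` by
#'   `cell_id`).
#' @param n_thresholds Number of quantile-grid thresholds (default 200).
#' @return An object of class `cg_roc`: `thresholds`, `tpr`, `fpr`
#'   (ordered by increasing threshold), `auc`, `optimal_threshold`,
#'   `corner_distance`.
#' @export
roc_threshold_scan <- function(traces, labels, n_thresholds = 200) {
  stat <- cell_max_stat(traces)
  ids <- names(traces)
  if (is.null(ids)) ids <- as.character(seq_along(traces))
  lab <- labels$label[match(ids, labels$cell_id)]
  if (anyNA(lab)) stop("labels missing for some traces", call. = FALSE)
  pos <- lab == "differentiated"
  if (!any(pos) || all(pos))
    stop("both fate classes are required for a ROC scan", call. = FALSE)
  thr <- sort(unique(c(
    quantile(stat, probs = seq(0, 1, length.out = n_thresholds),
             names = FALSE, type = 7),
    stat)))
  npos <- sum(pos); nneg <- sum(!pos)
  tpr <- vapply(thr, function(th) sum(stat[pos] > th), numeric(1)) / npos
  fpr <- vapply(thr, function(th) sum(stat[!pos] > th), numeric(1)) / nneg
  # append the all-positive endpoint so the curve spans (0,0) to (1,1)
  fpr_c <- c(1, fpr); tpr_c <- c(1, tpr)
  o <- order(fpr_c, tpr_c)
  auc <- sum(diff(fpr_c[o]) * (head(tpr_c[o], -1) + tail(tpr_c[o], -1)) / 2)
  auc <- abs(auc)
  corner <- sqrt(fpr^2 + (1 - tpr)^2)
  j <- which(corner == min(corner))[1]       # ties -> lower threshold
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 optimal_threshold = thr[j], corner_distance = corner[j]),
            class = "cg_roc")
}

#' @export
print.cg_roc <- function(x, ...) {
  cat(sprintf("<cg_roc> AUC %.4f, optimal threshold %.4g (corner distance %.4f)\n",
              x$auc, x$optimal_threshold, x$corner_distance))
  invisible(x)
}

#' First-crossing commitment times
#'
#' The differentiation-commitment time of a cell is the moment its
#' (smoothed) PPARG trace first crosses the optimal threshold, linearly
#' interpolated between the bracketing samples. Cells whose trace never
#' exceeds the threshold yield no commitment record.
#'
#' @param traces Named list of smoothed PPARG [trace_series()] objects.
#' @param optimal_threshold Threshold value (a.u.), typically
#'   `roc$optimal_threshold`.
#' @return A data.frame with one row per predicted-differentiated cell:
#'   `cell_id`, `commit_time` (hours), `threshold`, `fate`.
#' @export
assign_commitment_times <- function(traces, optimal_threshold) {
  ids <- names(traces)
  if (is.null(ids)) ids <- as.character(seq_along(traces))
  ct <- vapply(traces, function(tr) {
    tr <- as_trace(tr)
    i <- which(tr$value > optimal_threshold)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(tr$time[1])
    t0 <- tr$time[i - 1L]; t1 <- tr$time[i]
    v0 <- tr$value[i - 1L]; v1 <- tr$value[i]
    t0 + (optimal_threshold - v0) / (v1 - v0) * (t1 - t0)
  }, numeric(1))
  keep <- !is.na(ct)
  data.frame(cell_id = ids[keep], commit_time = unname(ct[keep]),
             threshold = optimal_threshold, fate = "differentiated",
             stringsAsFactors = FALSE)
}

#' Align PPARG traces to the commitment point
#'
#' Re-indexes each committed cell's trace so that its commitment time is
#' relative time 0 and summarizes the population with the median and
#' percentile envelopes (5th-95th and 25th-75th by default), exposing the
#' bimodal low-to-high PPARG switch.
#'
#' @param traces Named list of [trace_series()] objects.
#' @param records Commitment records from [assign_commitment_times()].
#' @param window Half-width of the relative-time window in hours.
#' @param probs Percentiles for the envelopes.
#' @return A list: `rel_time`, `matrix` (cells x relative time), `median`,
#'   and `bands` (a named list of percentile vectors).
#' @export
align_to_commitment <- function(traces, records, window = 24,
                                probs = c(0.05, 0.25, 0.75, 0.95)) {
  if (nrow(records) == 0L)
    stop("no commitment records to align", call. = FALSE)
  tr1 <- as_trace(traces[[records$cell_id[1]]])
  dt <- trace_dt(tr1)
  rel <- seq(-window, window, by = dt)
  mat <- t(vapply(seq_len(nrow(records)), function(i) {
    tr <- as_trace(traces[[records$cell_id[i]]])
    approx(tr$time - records$commit_time[i], tr$value, xout = rel,
           rule = 1)$y
  }, numeric(length(rel))))
  rownames(mat) <- records$cell_id
  med <- apply(mat, 2, median, na.rm = TRUE)
  bands <- lapply(probs, function(p) apply(mat, 2, quantile, probs = p,
                                           na.rm = TRUE, names = FALSE))
  names(bands) <- paste0("p", probs * 100)
  list(rel_time = rel, matrix = mat, median = med, bands = bands)
}
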