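#' Single-cell fluorescence trace
#'
#' A `cg_trace` holds one uniformly sampled fluorescence trajectory for one
#' channel of one cell: a strictly increasing, uniformly spaced time grid (in
#' hours) and finite intensity values (arbitrary units).
#'
#' @param time Numeric vector of times in hours; uniform grid, length >= 2.
#' @param value Numeric vector of intensities, same length as `time`.
#' @param channel Channel name, e.g. `"pparg"`, `"reporter"`, `"h2b_total"`.
#' @param cell_id Cell identifier.
#' @return An object of class `cg_trace`: a list with elements `time`,
#'   `value`, `channel`, `cell_id` and attribute-free uniform spacing `dt`.
#' @examples
#' tr <- trace_series(seq(0, 10, 0.2), sin(seq(0, 10, 0.2)), "reporter", "c1")
#' trace_dt(tr)
#' @export
trace_series <- function(time, value, channel = "pparg", cell_id = "cell") {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) < 2L)
    stop("a trace needs at least two time points", call. = FALSE)
  if (length(time) != length(value))
    stop("`time` and `value` lengths differ", call. = FALSE)
  if (anyNA(time) || anyNA(value) || any(!is.finite(value)))
    stop("trace times and values must be finite", call. = FALSE)
  dts <- diff(time)
  if (any(dts <= 0))
    stop("trace times must be strictly increasing", call. = FALSE)
  if (diff(range(dts)) > 1e-6 * mean(dts))
    stop("trace times must form a uniform grid", call. = FALSE)
  structure(
    list(time = time, value = value,
         channel = as.character(channel), cell_id = as.character(cell_id)),
    class = "cg_trace")
}

#' @rdname trace_series
#' @param x A `cg_trace`.
#' @export
trace_dt <- function(x) {
  stopifnot(inherits(x, "cg_trace"))
  (x$time[length(x$time)] - x$time[1]) / (length(x$time) - 1L)
}

#' @export
print.cg_trace <- function(x, ...) {
  cat(sprintf("<cg_trace> cell %s, channel %s: %d points, %.3g-%.3g h (dt = %.3g h)\n",
              x$cell_id, x$channel, length(x$time),
              x$time[1], x$time[length(x$time)], trace_dt(x)))
  invisible(x)
}

# internal: rebuild a trace keeping identity fields
retrace <- function(x, value, time = x$time) {
  structure(list(time = time, value = as.numeric(value),
                 channel = x$channel, cell_id = x$cell_id),
            class = "cg_trace")
}

as_trace <- function(x, channel = "pparg", cell_id = "cell") {
  if (inherits(x, "cg_trace")) return(x)
  stop("expected a `cg_trace` (see trace_series())", call. = FALSE)
}
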