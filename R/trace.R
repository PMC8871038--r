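#' Receiver time series
#'
#' A uniformly sampled receiver trace with `t = 0` at source onset.
#'
#' @param samples Numeric vector of samples.
#' @param dt Sample interval (s).
#' @param label Receiver label, e.g. `"A"` or `"B"`.
#' @return An object of class `"us_trace"`.
#' @export
us_trace <- function(samples, dt, label = "") {
  stopifnot(is.numeric(samples), is.numeric(dt), dt > 0)
  structure(list(samples = as.numeric(samples), dt = dt, t0 = 0,
                 label = as.character(label)), class = "us_trace")
}

#' Sample times of a trace
#' @param x A `us_trace`.
#' @return Numeric vector of times (s).
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "us_trace"))
  x$t0 + (seq_along(x$samples) - 1) * x$dt
}

#' @export
print.us_trace <- function(x, ...) {
  cat(sprintf("<us_trace> '%s': %d samples, dt = %.4g ns, span = %.3g us\n",
              x$label, length(x$samples), x$dt * 1e9,
              (length(x$samples) - 1) * x$dt * 1e6))
  invisible(x)
}

#' @export
as.data.frame.us_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), amplitude = x$samples)
}

#' @export
plot.us_trace <- function(x, ..., xlab = "time (us)", ylab = "amplitude") {
  plot(trace_times(x) * 1e6, x$samples, type = "l",
       xlab = xlab, ylab = ylab, main = x$label, ...)
}

# restrict a trace to a time window; indices of samples inside [gate1, gate2]
gate_index <- function(trace, gate) {
  tt <- trace_times(trace)
  which(tt >= gate[1] & tt <= gate[2])
}
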