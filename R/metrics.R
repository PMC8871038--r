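# Receive-side metrics: gated peak amplitude, phase-relation classification,
# peak-pair timing, amplitude ratios. All metrics are invariant under a
# common positive rescaling of the traces.

#' Default echo gate for a tip at a given depth
#'
#' Window centred on the expected round-trip arrival `2 * depth / c_water`,
#' opening `pre` before it and closing `post` after it (guided-wave arrivals
#' trail the direct tip echo). The gate never opens before 1.5 times the
#' source duration, excluding transmit breakthrough.
#'
#' @param depth Tip depth (m), or a `us_scene` whose deepest geometry is used.
#' @param c_water Water speed (m/s).
#' @param pre,post Gate margins (s).
#' @param f,n Source frequency and cycles (used for the breakthrough floor).
#' @return `c(t_open, t_close)` in seconds.
#' @export
echo_gate <- function(depth, c_water = 1500, pre = 1.5e-6, post = 5e-6,
                      f = 7e6, n = 2) {
  if (inherits(depth, "us_scene")) {
    f <- depth$frequency
    n <- depth$cycles
    depth <- depth$params$deepest
  }
  t0 <- 2 * depth / c_water
  c(max(t0 - pre, 1.5 * n / f), t0 + post)
}

#' Gated peak amplitude of a trace
#'
#' Maximum absolute sample within the gate and its time.
#'
#' @param trace A [us_trace].
#' @param gate `c(t_open, t_close)` in seconds.
#' @return A list of class `"echo_metrics"`: `peak` (>= 0), `t_peak` (s),
#'   `label`.
#' @export
gated_peak <- function(trace, gate) {
  stopifnot(inherits(trace, "us_trace"), length(gate) == 2)
  idx <- gate_index(trace, gate)
  if (length(idx) == 0) stop("empty gate", call. = FALSE)
  s <- trace$samples[idx]
  k <- which.max(abs(s))
  structure(list(peak = abs(s[k]), t_peak = trace_times(trace)[idx[k]],
                 label = trace$label), class = "echo_metrics")
}

#' @export
print.echo_metrics <- function(x, ...) {
  cat(sprintf("<echo_metrics> %s: peak %.4g at %.3f us\n",
              x$label, x$peak, x$t_peak * 1e6))
  invisible(x)
}

#' Gated energy of a trace
#'
#' `sum(samples^2) * dt` within the gate; the energy-style alternative to the
#' peak-amplitude intensity reading.
#'
#' @inheritParams gated_peak
#' @return Scalar energy (trace units squared times seconds).
#' @export
gated_energy <- function(trace, gate) {
  idx <- gate_index(trace, gate)
  if (length(idx) == 0) stop("empty gate", call. = FALSE)
  sum(trace$samples[idx]^2) * trace$dt
}

#' Phase relation of two traces within a gate
#'
#' Sign of the normalised cross-correlation at the lag of maximum magnitude:
#' positive -> `"in_phase"`, negative -> `"anti_phase"`; if the maximum
#' `|correlation|` is below `threshold` (or either gated trace has zero
#' variance) the relation is `"indeterminate"`.
#'
#' @param trace_a,trace_b Two [us_trace]s sharing `dt`.
#' @param gate `c(t_open, t_close)` (s); default spans the whole trace.
#' @param threshold Correlation-magnitude floor (default 0.5).
#' @param max_lag Largest lag searched (s); default half the gate.
#' @return `"in_phase"`, `"anti_phase"` or `"indeterminate"`.
#' @export
phase_relation <- function(trace_a, trace_b, gate = NULL, threshold = 0.5,
                           max_lag = NULL) {
  stopifnot(inherits(trace_a, "us_trace"), inherits(trace_b, "us_trace"))
  if (abs(trace_a$dt - trace_b$dt) > 1e-15 * trace_a$dt)
    stop("traces must share dt", call. = FALSE)
  if (is.null(gate))
    gate <- range(trace_times(trace_a))
  a <- trace_a$samples[gate_index(trace_a, gate)]
  b <- trace_b$samples[gate_index(trace_b, gate)]
  nmin <- min(length(a), length(b))
  a <- a[seq_len(nmin)]; b <- b[seq_len(nmin)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return("indeterminate")
  if (is.null(max_lag)) max_lag <- (gate[2] - gate[1]) / 2
  L <- min(nmin - 1, max(1, round(max_lag / trace_a$dt)))
  na <- sqrt(sum(a^2) * sum(b^2))
  best <- 0
  for (lag in -L:L) {
    if (lag >= 0) {
      v <- sum(a[seq_len(nmin - lag)] * b[seq_len(nmin - lag) + lag])
    } else {
      v <- sum(a[seq_len(nmin + lag) - lag] * b[seq_len(nmin + lag)])
    }
    if (abs(v) > abs(best)) best <- v
  }
  r <- best / na
  if (abs(r) < threshold) "indeterminate" else if (r > 0) "in_phase" else "anti_phase"
}

#' Separation of the dominant positive and negative peaks
#'
#' Absolute time difference between the largest positive and largest negative
#' sample within the gate.
#'
#' @inheritParams gated_peak
#' @return Time separation in seconds.
#' @export
peak_pair_separation <- function(trace, gate) {
  idx <- gate_index(trace, gate)
  if (length(idx) == 0) stop("empty gate", call. = FALSE)
  s <- trace$samples[idx]
  tt <- trace_times(trace)[idx]
  if (max(s) <= 0 || min(s) >= 0)
    stop("gate holds no opposite-sign peak pair", call. = FALSE)
  abs(tt[which.max(s)] - tt[which.min(s)])
}

#' Amplitude ratio of two echo metrics, in percent
#'
#' `100 * peak_num / peak_den`.
#'
#' @param metrics_num,metrics_den `echo_metrics` (or numbers).
#' @return Percentage.
#' @export
amplitude_ratio <- function(metrics_num, metrics_den) {
  p1 <- if (inherits(metrics_num, "echo_metrics")) metrics_num$peak else metrics_num
  p2 <- if (inherits(metrics_den, "echo_metrics")) metrics_den$peak else metrics_den
  if (p2 <= 0) stop("zero denominator peak", call. = FALSE)
  100 * p1 / p2
}
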