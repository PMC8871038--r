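#' Hann-windowed tone-burst drive
#'
#' The transmission waveform applied as a surface force on the transmitting
#' element: `y(t) = -cos(2 pi f t) * (1 - cos(2 pi f t / n))` for
#' `0 <= t <= n / f` and 0 outside. The value at `t = 0` is exactly 0 and the
#' burst integrates to (numerically) zero over its support.
#'
#' @param t Time in seconds (vectorised).
#' @param f Center frequency in Hz (default 7 MHz).
#' @param n Number of cycles (default 2).
#' @param amplitude Peak scale factor (the extreme value is `-2 * amplitude`
#'   for even `n`).
#' @return Waveform value(s), same length as `t`.
#' @examples
#' tone_burst_value(0)                      # 0
#' tone_burst_value(2 / (2 * 7e6))          # -2 at burst midpoint (f = 7 MHz, n = 2)
#' @export
tone_burst_value <- function(t, f = 7e6, n = 2, amplitude = 1) {
  stopifnot(f > 0, n >= 1)
  y <- -cos(2 * pi * f * t) * (1 - cos(2 * pi * f * t / n)) * amplitude
  y[t < 0 | t > n / f] <- 0
  y
}

#' Sampled tone burst
#'
#' @param dt Sample interval (s).
#' @param nt Number of samples; default covers the burst support only.
#' @inheritParams tone_burst_value
#' @return A `us_trace` holding the sampled drive.
#' @export
tone_burst <- function(f = 7e6, n = 2, dt, nt = NULL, amplitude = 1) {
  if (is.null(nt)) nt <- ceiling(n / f / dt) + 1
  us_trace(tone_burst_value((seq_len(nt) - 1) * dt, f, n, amplitude),
           dt = dt, label = "source")
}

#' Duration of the tone burst
#' @inheritParams tone_burst_value
#' @return `n / f` in seconds.
#' @export
tone_burst_duration <- function(f = 7e6, n = 2) n / f
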