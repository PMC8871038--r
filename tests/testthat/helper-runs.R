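# Shared lazy cache for expensive solver runs so that unit and acceptance
# tests reuse the same simulations within one test session.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# small, fast resolution policy for property-style solver tests
test_res <- function(ppw = 8, sponge = 24) resolution_policy(ppw = ppw, sponge = sponge)

# synthetic two-pulse trace: narrow Gaussian pulses of given signs and times
two_pulse_trace <- function(t1, t2, dt = 1e-8, span = 1e-5, s1 = 1, s2 = -1,
                            width = 5e-8) {
  tt <- seq(0, span, by = dt)
  y <- s1 * exp(-((tt - t1) / width)^2) + s2 * exp(-((tt - t2) / width)^2)
  us_trace(y, dt, "synthetic")
}
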