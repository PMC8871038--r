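#' Run a time-domain elastodynamic simulation
#'
#' Propagates the scene's tone-burst surface force with the 2D velocity-stress
#' staggered-grid solver (leapfrog update: velocities from the stress
#' divergence scaled by inverse density, then stresses from velocity gradients
#' scaled by the Lame parameters; void cells carry zero moduli so their
#' boundaries are traction-free; a Cerjan sponge absorbs the left/right/bottom
#' frames). Transmitting elements add the waveform to the normal stress over
#' their face cells; receiving elements record the element-averaged normal
#' stress and probe points record the pressure-like quantity
#' `-(sxx + syy)/2`.
#'
#' @param scene A `us_scene`.
#' @param duration Recorded duration (s). Default: round trip to the deepest
#'   geometry plus a 6 us margin. A warning is issued if shorter than the
#'   round trip.
#' @param waveform Optional numeric vector of source samples (one per step);
#'   default is the scene's Hann-windowed tone burst. Use `amplitude = 0` via
#'   a zero vector for quiescence checks.
#' @param snapshot_times Times (s) at which to capture a full-field snapshot.
#' @param snapshot_component One of `"pressure"`, `"sxy"`, `"vx"`, `"vy"`.
#' @param energy_every Record total discrete energy every this many steps
#'   (0 = off).
#' @param return_state Return the final field state (for invariance checks).
#' @return An object of class `"us_run"`: list with `traces` (named list of
#'   [us_trace]), `snapshots` (list of `list(time, field)`), `energy`
#'   (data.frame `time`, `energy` or `NULL`), `state` (or `NULL`), `scene_tag`,
#'   `dt`, `nt`, and a `log` with grid size, CFL and points-per-wavelength.
#' @export
run_simulation <- function(scene, duration = NULL, waveform = NULL,
                           snapshot_times = numeric(),
                           snapshot_component = c("pressure", "sxy", "vx", "vy"),
                           energy_every = 0L, return_state = FALSE) {
  stopifnot(inherits(scene, "us_scene"))
  snapshot_component <- match.arg(snapshot_component)
  dt <- scene$dt
  roundtrip <- 2 * scene$params$deepest / WATER_VL
  if (is.null(duration)) duration <- roundtrip + 6e-6
  if (duration < roundtrip)
    warning("recorded duration is shorter than the round trip to the deepest geometry")
  nt <- as.integer(ceiling(duration / dt))
  if (is.null(waveform)) {
    waveform <- tone_burst_value((seq_len(nt) - 1) * dt,
                                 f = scene$frequency, n = scene$cycles)
  }
  stopifnot(length(waveform) >= nt)
  waveform <- as.numeric(waveform[seq_len(nt)])

  tx <- Filter(function(e) isTRUE(e$transmit), scene$elements)
  if (length(tx) == 0) stop("scene has no transmitting element", call. = FALSE)
  src_cells <- do.call(rbind, lapply(tx, `[[`, "cells"))
  storage.mode(src_cells) <- "integer"

  rx <- Filter(function(e) isTRUE(e$receive), scene$elements)
  rec_cells <- lapply(rx, `[[`, "cells")
  rec_kind <- rep(0L, length(rec_cells))
  rec_labels <- vapply(rx, `[[`, "", "label")
  if (length(scene$probes)) {
    rec_cells <- c(rec_cells, scene$probes)
    rec_kind <- c(rec_kind, rep(1L, length(scene$probes)))
    rec_labels <- c(rec_labels, names(scene$probes))
  }
  rec_cells <- lapply(rec_cells, function(m) {
    storage.mode(m) <- "integer"; m
  })

  snap_steps <- sort(unique(pmin(nt - 1L, pmax(0L,
    as.integer(round(snapshot_times / dt))))))
  if (length(snapshot_times) == 0) snap_steps <- integer()
  comp <- match(snapshot_component, c("pressure", "sxy", "vx", "vy")) - 1L

  out <- .efit_core(scene$lam, scene$mu, scene$rho, scene$voidm, scene$damp,
                    dt, scene$dx, nt, waveform, src_cells,
                    rec_cells, rec_kind, snap_steps, comp,
                    as.integer(energy_every), return_state, 200L)

  traces <- stats::setNames(lapply(seq_along(rec_labels), function(r)
    us_trace(out$traces[, r], dt, rec_labels[r])), rec_labels)
  snapshots <- if (length(snap_steps))
    lapply(seq_along(snap_steps), function(s)
      list(time = snap_steps[s] * dt, field = out$snapshots[[s]]))
  else list()
  energy <- NULL
  if (energy_every > 0) {
    ne <- length(out$energy)
    keep <- seq_len(min(ne, floor((nt - 1) / energy_every) + 1))
    energy <- data.frame(time = (keep - 1) * energy_every * dt,
                         energy = out$energy[keep])
  }
  structure(list(
    traces = traces, snapshots = snapshots, energy = energy,
    state = out$state, scene_tag = scene$tag, dt = dt, nt = nt,
    log = list(nx = scene$nx, ny = scene$ny, dx = scene$dx, dt = dt, nt = nt,
               cfl = scene$resolution$cfl, ppw = scene$ppw)
  ), class = "us_run")
}

#' @export
print.us_run <- function(x, ...) {
  cat(sprintf("<us_run> %s: %d steps of %.3g ns on %d x %d cells\n",
              x$scene_tag, x$nt, x$dt * 1e9, x$log$nx, x$log$ny))
  cat(sprintf("  traces: %s; %d snapshot(s)\n",
              paste(names(x$traces), collapse = ", "), length(x$snapshots)))
  invisible(x)
}

#' Export a snapshot as a PNG image
#'
#' Signed amplitude on a symmetric grey scale (positive light, negative
#' dark), per the usual wavefield display convention.
#'
#' @param snapshot One element of a run's `snapshots` list.
#' @param path Output file path.
#' @param clip Amplitudes are clipped at `clip` times the maximum absolute
#'   value (default 0.5) to bring out weak arrivals.
#' @return `path`, invisibly.
#' @export
snapshot_to_png <- function(snapshot, path, clip = 0.5) {
  f <- snapshot$field
  m <- max(abs(f))
  if (m == 0) m <- 1
  z <- pmax(-1, pmin(1, f / (clip * m)))
  png::writePNG(t((z + 1) / 2), path)
  invisible(path)
}
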