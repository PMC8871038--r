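#' Stable time step for the explicit staggered-grid scheme
#'
#' CFL bound in two dimensions: `dt = cfl * dx / (v_max * sqrt(2))`.
#'
#' @param dx Grid spacing (m).
#' @param v_max Largest longitudinal speed present in the scene (m/s).
#' @param cfl Courant number in (0, 1]; the package default of 0.7 leaves
#'   margin for staircased free surfaces of void regions.
#' @return Time step in seconds.
#' @examples
#' stable_dt(1e-5, 5780, 0.9)  # ~1.101 ns
#' @export
stable_dt <- function(dx, v_max, cfl = 0.7) {
  stopifnot(dx > 0, v_max > 0, cfl > 0, cfl <= 1)
  cfl * dx / (v_max * sqrt(2))
}

#' Points per wavelength at a given speed and frequency
#'
#' @param dx Grid spacing (m).
#' @param c Wave speed (m/s).
#' @param f Frequency (Hz).
#' @return `c / (f * dx)`, the sampling density of that wave.
#' @export
points_per_wavelength <- function(dx, c, f) c / (f * dx)

#' Resolution policy for scene builders
#'
#' Controls the grid spacing (via points per wavelength of the water wave at
#' the source frequency), the Courant number, the sponge-layer thickness and
#' the padding between geometry and the absorbing frame.
#'
#' @param ppw Points per water wavelength used to set `dx` (default 10).
#' @param cfl Courant number (default 0.7).
#' @param sponge Absorbing-frame thickness in cells (default 32).
#' @param pad_wavelengths Water wavelengths of padding between the outermost
#'   geometry/elements and the absorbing frame (default 4).
#' @param ppw_floor Builders refuse scenes whose water wave would be sampled
#'   below this density (default 6).
#' @return A list of class `"us_resolution"`.
#' @export
resolution_policy <- function(ppw = 10, cfl = 0.7, sponge = 32,
                              pad_wavelengths = 4, ppw_floor = 6) {
  stopifnot(ppw > 0, cfl > 0, cfl <= 1, sponge >= 0, pad_wavelengths >= 0)
  if (ppw < ppw_floor)
    stop(sprintf("resolution error: ppw = %g below floor %g", ppw, ppw_floor),
         call. = FALSE)
  structure(list(ppw = ppw, cfl = cfl, sponge = as.integer(sponge),
                 pad_wavelengths = pad_wavelengths, ppw_floor = ppw_floor),
            class = "us_resolution")
}

# Cerjan-style sponge factor field for left/right/bottom frames.
# Per-step multiplicative factor exp(-(a * (L - d))^2) within L cells of an
# absorbing edge, 1 in the interior.
sponge_field <- function(nx, ny, L, a = 0.015) {
  damp <- matrix(1, nx, ny)
  if (L <= 0) return(damp)
  prof <- exp(-(a * (L - (seq_len(L) - 1)))^2)  # prof[1] at edge
  for (k in seq_len(L)) {
    damp[k, ] <- damp[k, ] * prof[k]             # left
    damp[nx - k + 1, ] <- damp[nx - k + 1, ] * prof[k]  # right
    damp[, ny - k + 1] <- damp[, ny - k + 1] * prof[k]  # bottom
  }
  damp
}
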