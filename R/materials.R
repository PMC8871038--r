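#' Define an isotropic elastic material
#'
#' Builds a material from density and wave speeds and attaches the Lame
#' parameters used by the solver: `lambda = rho * (vl^2 - 2 * vs^2)` and
#' `mu = rho * vs^2`. A fluid is the `vs = 0` limit (`mu = 0` exactly).
#'
#' @param name Material name (character scalar).
#' @param rho Density in kg/m^3 (> 0).
#' @param vl Longitudinal wave speed in m/s (> 0).
#' @param vs Shear wave speed in m/s (>= 0); 0 for a fluid.
#' @return An object of class `"us_material"`: a list with `name`, `rho`,
#'   `vl`, `vs`, `lambda`, `mu` (Pa) and the acoustic impedance `z = rho * vl`
#'   (Pa s/m).
#' @examples
#' water <- make_material("water", 1000, 1500)
#' steel <- make_material("SUS304", 7930, 5780, 3100)
#' water$mu  # exactly 0
#' @export
make_material <- function(name, rho, vl, vs = 0) {
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0)
    stop("invalid material: density must be a positive number", call. = FALSE)
  if (!is.numeric(vl) || length(vl) != 1 || !is.finite(vl) || vl <= 0)
    stop("invalid material: longitudinal speed must be positive", call. = FALSE)
  if (!is.numeric(vs) || length(vs) != 1 || !is.finite(vs) || vs < 0)
    stop("invalid material: shear speed must be >= 0", call. = FALSE)
  structure(list(
    name = as.character(name), rho = rho, vl = vl, vs = vs,
    lambda = rho * (vl^2 - 2 * vs^2), mu = rho * vs^2,
    z = rho * vl
  ), class = "us_material")
}

#' @export
print.us_material <- function(x, ...) {
  cat(sprintf("<us_material> %s\n", x$name))
  cat(sprintf("  rho = %g kg/m^3, vL = %g m/s, vS = %g m/s\n", x$rho, x$vl, x$vs))
  cat(sprintf("  lambda = %.4g GPa, mu = %.4g GPa, Z = %.3f MRayl\n",
              x$lambda / 1e9, x$mu / 1e9, x$z / 1e6))
  invisible(x)
}

#' Reference materials of the needle-tip study
#'
#' Water (1000 kg/m^3, 1500 m/s) and stainless steel SUS304
#' (7930 kg/m^3, vL 5780 m/s, vS 3100 m/s).
#' @return A `us_material`.
#' @rdname reference_materials
#' @export
material_water <- function() make_material("water", 1000, 1500, 0)

#' @rdname reference_materials
#' @export
material_sus304 <- function() make_material("SUS304", 7930, 5780, 3100)

#' Normal-incidence pressure reflection coefficient
#'
#' `(z2 - z1) / (z2 + z1)` from the acoustic impedances of the two media.
#'
#' @param m1,m2 `us_material` objects (incidence from `m1`).
#' @return Reflection coefficient in (-1, 1).
#' @export
reflection_coefficient <- function(m1, m2) {
  (m2$z - m1$z) / (m2$z + m1$z)
}
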