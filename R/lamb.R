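# Rayleigh-Lamb dispersion for a traction-free plate: the analytic oracle for
# the guided-wave mechanism. Free-plate (vacuum-loaded) roots are used; water
# loading perturbs the phase velocity only slightly at the water/steel
# impedance contrast.

# Characteristic function for the free plate, real-valued via complex
# arithmetic. fd in Hz*m, c in m/s. Returns the normalised residual (signed).
rl_char <- function(c_p, fd, vl, vs, family) {
  h <- 0.5                       # work in fd units: omega*h = pi * fd
  wh <- pi * fd                  # omega * half-thickness (m/s units)
  k <- wh / c_p
  p <- sqrt(as.complex(wh^2 / vl^2 - k^2))
  q <- sqrt(as.complex(wh^2 / vs^2 - k^2))
  t1 <- (q^2 - k^2)^2
  t2 <- 4 * k^2 * p * q
  f <- if (family == "symmetric") {
    t1 * cos(p * h * 2) * sin(q * h * 2) / (2 * h) +
      t2 * sin(p * h * 2) * cos(q * h * 2) / (2 * h)
  } else {
    t1 * sin(p * h * 2) * cos(q * h * 2) / (2 * h) +
      t2 * cos(p * h * 2) * sin(q * h * 2) / (2 * h)
  }
  scale <- (abs(t1) + abs(t2)) *
    (abs(cos(p * h * 2)) + abs(sin(p * h * 2))) *
    (abs(cos(q * h * 2)) + abs(sin(q * h * 2))) / (2 * h) + .Machine$double.xmin
  # f is purely real when q is real and purely imaginary when both p and q
  # are imaginary (c_p < vs); the sum picks the live part in either regime
  (Re(f) + Im(f)) / scale
}

#' All propagating Lamb modes at a frequency-thickness product
#'
#' Finds the real roots in phase velocity of the Rayleigh-Lamb frequency
#' equation for a traction-free plate by sign-change bracketing and bisection
#' over `c_p` in `[c_min, 1.2 * vl]`. Orders are assigned per family in
#' ascending phase velocity (0 = fundamental at that `fd`).
#'
#' @param fd Frequency-thickness product in Hz*m (e.g. `1.4e3` for
#'   1.4 MHz*mm).
#' @param material A `us_material` with non-zero shear speed.
#' @param family `"symmetric"`, `"antisymmetric"` or both (default).
#' @param c_water Water speed used for the leak angle (m/s).
#' @param n_brackets Initial bracketing grid size (default 2000).
#' @param tol Bisection tolerance on `c_p` (m/s; default 1e-3).
#' @return A data.frame with `family`, `order`, `fd`, `c_p`, `leak_angle_deg`
#'   (NA when `c_p < c_water`) and `residual` (normalised dispersion-equation
#'   residual at the root).
#' @export
lamb_modes <- function(fd, material = material_sus304(),
                       family = c("symmetric", "antisymmetric"),
                       c_water = 1500, n_brackets = 2000, tol = 1e-3) {
  stopifnot(fd > 0, material$vs > 0)
  family <- match.arg(family, several.ok = TRUE)
  vl <- material$vl; vs <- material$vs
  out <- list()
  for (fam in family) {
    grid <- seq(50, 1.2 * vl, length.out = n_brackets)
    vals <- vapply(grid, rl_char, 0, fd = fd, vl = vl, vs = vs, family = fam)
    roots <- c()
    for (i in seq_len(length(grid) - 1)) {
      if (!is.finite(vals[i]) || !is.finite(vals[i + 1])) next
      if (vals[i] == 0) roots <- c(roots, grid[i])
      if (vals[i] * vals[i + 1] < 0) {
        r <- stats::uniroot(rl_char, c(grid[i], grid[i + 1]), fd = fd, vl = vl,
                            vs = vs, family = fam, tol = tol)$root
        roots <- c(roots, r)
      }
    }
    # drop spurious sign changes at the branch points c = vl, vs (the complex
    # square roots switch branch there without a true root)
    if (length(roots)) {
      res <- vapply(roots, function(r) abs(rl_char(r, fd, vl, vs, fam)), 0)
      keep <- res < 1e-6 & !vapply(roots, function(r)
        min(abs(r - c(vl, vs))) < 0.5, TRUE)
      roots <- roots[keep]; res <- res[keep]
      if (length(roots))
        out[[fam]] <- data.frame(
          family = fam, order = seq_along(roots) - 1L, fd = fd,
          c_p = roots,
          leak_angle_deg = ifelse(roots >= c_water,
                                  asin(c_water / roots) * 180 / pi, NA_real_),
          residual = res)
    }
  }
  if (length(out) == 0)
    return(data.frame(family = character(), order = integer(), fd = numeric(),
                      c_p = numeric(), leak_angle_deg = numeric(),
                      residual = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Phase velocity of a named Lamb mode
#'
#' @param family `"symmetric"` or `"antisymmetric"`.
#' @param order Mode order (0 = fundamental).
#' @param fd Frequency-thickness product (Hz*m).
#' @param material A `us_material`.
#' @return Phase velocity in m/s.
#' @export
rayleigh_lamb_phase_velocity <- function(family, order, fd,
                                         material = material_sus304()) {
  family <- match.arg(family, c("symmetric", "antisymmetric"))
  m <- lamb_modes(fd, material, family = family)
  row <- m[m$order == order, ]
  if (nrow(row) == 0)
    stop(sprintf("mode not propagating: %s order %d at fd = %g Hz*m",
                 family, order, fd), call. = FALSE)
  row$c_p[1]
}

#' Leak angle of a guided wave into a fluid
#'
#' `asin(c_water / c_p)` in degrees; defined only for `c_p >= c_water`.
#'
#' @param c_p Phase velocity of the guided wave (m/s).
#' @param c_water Fluid speed (m/s).
#' @return Angle from the plate normal, degrees.
#' @export
leak_angle <- function(c_p, c_water = 1500) {
  stopifnot(c_p > 0)
  if (c_p < c_water)
    stop("no leak: phase velocity below the fluid speed (evanescent)",
         call. = FALSE)
  asin(c_water / c_p) * 180 / pi
}

#' Transit time across a width
#'
#' @param width Path length (m).
#' @param speed Wave speed (m/s).
#' @return `width / speed` in seconds.
#' @examples
#' transit_time(1.5e-3, 1500)  # 1 us across the 1.5 mm cylinder tip
#' @export
transit_time <- function(width, speed) {
  stopifnot(width >= 0, speed > 0)
  width / speed
}

#' Snell refraction across a speed contrast
#'
#' @param angle_in_deg Incidence angle from the normal, degrees in `[0, 90)`.
#' @param c1,c2 Speeds on the incident and transmitted sides (m/s).
#' @return List with `angle_deg` (the refracted angle, clamped at 90) and
#'   `total_reflection` (`TRUE` beyond the critical angle).
#' @export
snell_refraction <- function(angle_in_deg, c1, c2) {
  stopifnot(angle_in_deg >= 0, angle_in_deg < 90, c1 > 0, c2 > 0)
  s <- (c2 / c1) * sin(angle_in_deg * pi / 180)
  list(angle_deg = asin(min(s, 1)) * 180 / pi, total_reflection = s > 1)
}

#' Dispersion curves over a range of frequency-thickness products
#'
#' @param material A `us_material`.
#' @param fd_range `c(min, max)` in Hz*m.
#' @param n Number of fd samples.
#' @inheritParams lamb_modes
#' @return A data.frame (stacked [lamb_modes()] tables).
#' @export
dispersion_curve <- function(material = material_sus304(),
                             fd_range = c(0.1e3, 2e3), n = 40,
                             family = c("symmetric", "antisymmetric"),
                             c_water = 1500) {
  stopifnot(length(fd_range) == 2, all(fd_range > 0),
            fd_range[2] > fd_range[1])
  fds <- seq(fd_range[1], fd_range[2], length.out = n)
  do.call(rbind, lapply(fds, lamb_modes, material = material, family = family,
                        c_water = c_water))
}
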