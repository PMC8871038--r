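# Scene construction: grid + per-cell material assignment + transducer
# elements for every simulated configuration (needle, cylinder, inclined
# plate, tapered rod). Fully deterministic; geometry is rasterised onto the
# cell-centered grid (staircase boundaries, no sub-cell interface treatment).
#
# Coordinate convention: x lateral (row index i, centered on the probe axis),
# y depth (column index j, transducer face at y = 0), cell centers at
# x_i = (i - (nx+1)/2) dx, y_j = (j - 1/2) dx. nx is kept odd so the scene is
# mirror-symmetric about the center column.

WATER_RHO <- 1000
WATER_VL <- 1500

# domain skeleton filled with water
new_scene_domain <- function(frequency, resolution, half_width_geom,
                             depth_geom, sponge_sides = TRUE) {
  stopifnot(inherits(resolution, "us_resolution"))
  lambda_w <- WATER_VL / frequency
  dx <- lambda_w / resolution$ppw
  pad <- resolution$pad_wavelengths * lambda_w
  hw_cells <- ceiling((half_width_geom + pad) / dx)
  L <- resolution$sponge
  nx <- 2L * (hw_cells + if (sponge_sides) L else 0L) + 1L
  ny <- as.integer(ceiling((depth_geom + pad) / dx) + L)
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  y <- (seq_len(ny) - 0.5) * dx
  water <- material_water()
  damp <- matrix(1, nx, ny)
  if (L > 0) {
    prof <- exp(-(0.015 * (L - (seq_len(L) - 1)))^2)
    for (k in seq_len(L)) {
      if (sponge_sides) {
        damp[k, ] <- damp[k, ] * prof[k]
        damp[nx - k + 1, ] <- damp[nx - k + 1, ] * prof[k]
      }
      damp[, ny - k + 1] <- damp[, ny - k + 1] * prof[k]
    }
  }
  list(nx = nx, ny = ny, dx = dx, x = x, y = y,
       rho = matrix(water$rho, nx, ny),
       lam = matrix(water$lambda, nx, ny),
       mu = matrix(0, nx, ny),
       voidm = matrix(0L, nx, ny),
       matindex = matrix(0L, nx, ny),   # 0 water, 1 solid, 2 void
       damp = damp, frequency = frequency, resolution = resolution)
}

# paint a logical mask with a material or mark it void
paint_mask <- function(dom, mask, material) {
  if (identical(material, "void")) {
    dom$voidm[mask] <- 1L
    dom$matindex[mask] <- 2L
  } else {
    dom$rho[mask] <- material$rho
    dom$lam[mask] <- material$lambda
    dom$mu[mask] <- material$mu
    dom$matindex[mask] <- 1L
  }
  dom
}

# element cells on the transducer face from a lateral interval (m)
element_cells <- function(dom, x0, x1) {
  i <- which(dom$x > x0 + 1e-12 & dom$x < x1 - 1e-12)
  if (length(i) == 0) stop("geometry error: element interval holds no cells",
                           call. = FALSE)
  cbind(i, 1L)
}

probe_cell <- function(dom, px, py) {
  cbind(which.min(abs(dom$x - px)), which.min(abs(dom$y - py)))
}

finish_scene <- function(dom, tag, elements, probes, params, v_max, cycles = 2) {
  f <- dom$frequency
  scene <- structure(list(
    tag = tag, nx = dom$nx, ny = dom$ny, dx = dom$dx,
    frequency = f, cycles = cycles,
    rho = dom$rho, lam = dom$lam, mu = dom$mu, voidm = dom$voidm,
    matindex = dom$matindex, damp = dom$damp,
    elements = elements, probes = probes, params = params,
    resolution = dom$resolution, v_max = v_max,
    dt = stable_dt(dom$dx, v_max, dom$resolution$cfl),
    ppw = c(water = points_per_wavelength(dom$dx, WATER_VL, f),
            steel_shear = points_per_wavelength(dom$dx, material_sus304()$vs, f)),
    x = dom$x, y = dom$y
  ), class = "us_scene")
  scene
}

check_variant <- function(material_variant) {
  match.arg(material_variant, c("steel", "void"))
}

ring_elements <- function(dom, inner = 3e-3, outer = 7e-3) {
  list(
    A = list(label = "A", cells = element_cells(dom, -outer / 2, -inner / 2),
             transmit = TRUE, receive = TRUE),
    B = list(label = "B", cells = element_cells(dom, inner / 2, outer / 2),
             transmit = FALSE, receive = TRUE)
  )
}

#' Build the bevelled-needle scene
#'
#' A vertical stainless-steel (or void) needle on the probe axis, inserted
#' through a ring transducer represented in 2D cross-section by two
#' face elements: A (transmit + receive) spanning -3.5 to -1.5 mm and B
#' (receive) spanning +1.5 to +3.5 mm from the centerline (ring inner/outer
#' diameters 3 and 7 mm). The tip carries a single bevel whose slanted face
#' is oriented toward element A; the tip angle is measured between the bevel
#' face and the needle axis. Water everywhere else; absorbing frames on the
#' left, right and bottom edges.
#'
#' If the bevel face is longer than the insertion depth (shallow angles on a
#' thick needle) the needle is only partially inserted and the bevel is
#' clipped at the transducer face, with a warning.
#'
#' @param tip_angle_deg Bevel angle in degrees, in `[1, 89]`.
#' @param material_variant `"steel"` (SUS304) or `"void"`.
#' @param insertion_depth Depth of the tip below the face (m); default 15 mm.
#' @param diameter Needle diameter (m); default 1.5 mm.
#' @param frequency Source center frequency (Hz); default 7 MHz.
#' @param resolution A [resolution_policy()].
#' @param bevel `"single"` (default) or `"symmetric"` (two facets meeting on
#'   the axis).
#' @param bevel_toward Which element the slanted face is oriented to
#'   (`"A"` or `"B"`); default `"A"`.
#' @param elements `"ring"` (default) for the 3/7 mm ring cross-section, or
#'   `"compact"` for a narrow monostatic aperture close to the shaft
#'   (A = transmit/receive over 0.9-1.9 mm, B mirrored receive) used by
#'   small convergence studies where the full ring domain is unnecessarily
#'   wide.
#' @return A `us_scene`.
#' @export
build_needle_scene <- function(tip_angle_deg, material_variant = "steel",
                               insertion_depth = 15e-3, diameter = 1.5e-3,
                               frequency = 7e6,
                               resolution = resolution_policy(),
                               bevel = c("single", "symmetric"),
                               bevel_toward = c("A", "B"),
                               elements = c("ring", "compact")) {
  bevel <- match.arg(bevel)
  bevel_toward <- match.arg(bevel_toward)
  elements <- match.arg(elements)
  material_variant <- check_variant(material_variant)
  if (tip_angle_deg < 1 || tip_angle_deg > 89)
    stop("geometry error: tip angle must be in [1, 89] degrees", call. = FALSE)
  if (insertion_depth <= 0 || diameter <= 0)
    stop("geometry error: non-positive depth or diameter", call. = FALSE)
  half_w <- if (elements == "ring") 3.5e-3 else 1.9e-3
  dom <- new_scene_domain(frequency, resolution, half_width_geom = half_w,
                          depth_geom = insertion_depth)
  if (diameter < 2 * dom$dx)
    stop("resolution error: needle thinner than 2 cells at this dx",
         call. = FALSE)
  theta <- tip_angle_deg * pi / 180
  d <- diameter
  depth <- insertion_depth
  if (bevel == "single") {
    bevel_len <- d / tan(theta)
  } else {
    bevel_len <- (d / 2) / tan(theta)
  }
  if (bevel_len > depth)
    warning(sprintf(
      "bevel face (%.2f mm) longer than insertion depth (%.2f mm): needle partially inserted, bevel clipped at the face",
      bevel_len * 1e3, depth * 1e3))
  X <- matrix(dom$x, dom$nx, dom$ny)
  Y <- matrix(dom$y, dom$nx, dom$ny, byrow = TRUE)
  if (bevel == "single") {
    s <- if (bevel_toward == "A") (d / 2 - X) else (d / 2 + X)
    yface <- depth - bevel_len * s / d
  } else {
    yface <- depth - bevel_len * (d / 2 - abs(X)) / (d / 2)
  }
  mask <- abs(X) <= d / 2 & Y <= yface
  dom <- paint_mask(dom, mask,
                    if (material_variant == "steel") material_sus304() else "void")
  elems <- if (elements == "ring") ring_elements(dom) else list(
    A = list(label = "A", cells = element_cells(dom, -1.9e-3, -0.9e-3),
             transmit = TRUE, receive = TRUE),
    B = list(label = "B", cells = element_cells(dom, 0.9e-3, 1.9e-3),
             transmit = FALSE, receive = TRUE))
  params <- list(tip_angle_deg = tip_angle_deg, diameter = diameter,
                 insertion_depth = insertion_depth, bevel = bevel,
                 bevel_toward = bevel_toward, material_variant = material_variant,
                 bevel_length = bevel_len, deepest = insertion_depth)
  finish_scene(dom, paste0("needle_", material_variant), elems,
               probes = list(), params = params,
               v_max = material_sus304()$vl)
}

#' Build the flat-tipped cylinder scene
#'
#' A vertical flat-ended rod on the probe axis with the same ring-element
#' layout as the needle scene.
#'
#' @param material_variant `"steel"` or `"void"`.
#' @param width Rod width (m); default 1.5 mm.
#' @inheritParams build_needle_scene
#' @return A `us_scene`.
#' @export
build_cylinder_scene <- function(material_variant = "steel", width = 1.5e-3,
                                 insertion_depth = 15e-3, frequency = 7e6,
                                 resolution = resolution_policy()) {
  material_variant <- check_variant(material_variant)
  if (width <= 0 || insertion_depth <= 0)
    stop("geometry error: non-positive width or depth", call. = FALSE)
  dom <- new_scene_domain(frequency, resolution, half_width_geom = 3.5e-3,
                          depth_geom = insertion_depth)
  if (width < 2 * dom$dx)
    stop("resolution error: rod thinner than 2 cells at this dx", call. = FALSE)
  X <- matrix(dom$x, dom$nx, dom$ny)
  Y <- matrix(dom$y, dom$nx, dom$ny, byrow = TRUE)
  mask <- abs(X) <= width / 2 & Y <= insertion_depth
  dom <- paint_mask(dom, mask,
                    if (material_variant == "steel") material_sus304() else "void")
  params <- list(width = width, insertion_depth = insertion_depth,
                 material_variant = material_variant, deepest = insertion_depth)
  finish_scene(dom, paste0("cylinder_", material_variant),
               ring_elements(dom), probes = list(), params = params,
               v_max = material_sus304()$vl)
}

#' Build the stepped tapered-rod scene
#'
#' A steel rod whose terminal segment of length `tip_length` is narrowed to
#' `tip_width` (stepped profile); the stem defaults to the 1.5 mm cylinder.
#' With `tip_width == stem_width` or `tip_length == 0` the scene degenerates
#' to the plain cylinder.
#'
#' @param tip_width Width of the terminal segment (m).
#' @param tip_length Length of the terminal segment (m); `>= 0`.
#' @param stem_width Stem width (m); default 1.5 mm.
#' @inheritParams build_needle_scene
#' @return A `us_scene`.
#' @export
build_tapered_rod_scene <- function(tip_width, tip_length,
                                    stem_width = 1.5e-3,
                                    insertion_depth = 15e-3, frequency = 7e6,
                                    resolution = resolution_policy()) {
  if (tip_width <= 0 || tip_length < 0 || stem_width <= 0)
    stop("geometry error: non-positive tip width / stem width or negative length",
         call. = FALSE)
  if (tip_width > stem_width)
    stop("geometry error: tip width exceeds stem width", call. = FALSE)
  if (tip_length > insertion_depth)
    stop("geometry error: tip segment longer than insertion depth", call. = FALSE)
  dom <- new_scene_domain(frequency, resolution, half_width_geom = 3.5e-3,
                          depth_geom = insertion_depth)
  if (tip_width < 2 * dom$dx)
    stop("resolution error: tip thinner than 2 cells at this dx", call. = FALSE)
  X <- matrix(dom$x, dom$nx, dom$ny)
  Y <- matrix(dom$y, dom$nx, dom$ny, byrow = TRUE)
  mask <- (abs(X) <= stem_width / 2 & Y <= insertion_depth - tip_length) |
    (abs(X) <= tip_width / 2 & Y <= insertion_depth)
  dom <- paint_mask(dom, mask, material_sus304())
  params <- list(tip_width = tip_width, tip_length = tip_length,
                 stem_width = stem_width, insertion_depth = insertion_depth,
                 material_variant = "steel", deepest = insertion_depth)
  finish_scene(dom, "tapered_rod", ring_elements(dom), probes = list(),
               params = params, v_max = material_sus304()$vl)
}

#' Build the inclined-plate guided-wave scene
#'
#' A thin stainless-steel strip in water inclined at `plate_angle_deg` to the
#' transducer face, insonified by a single transmitting element of width
#' `probe_width` centered on the axis. Waveform probe points A and B sit on
#' opposite sides of the plate, displaced 1 mm along the plate normal from a
#' point 3 mm down-plate of the insonified region; an additional row of probe
#' points parallel to the plate (labels `L1..Ln`) supports measuring the
#' apparent leak angle of the guided wave.
#'
#' @param plate_thickness Plate thickness (m); default 0.2 mm; must span at
#'   least 2 cells.
#' @param plate_angle_deg Inclination to the face in degrees; default 36.
#' @param probe_width Transmitting element width (m); default 3.3 mm.
#' @param plate_depth Depth at which the plate crosses the probe axis (m).
#' @param probe_offset Normal offset of probe points A/B from the plate (m).
#' @inheritParams build_needle_scene
#' @return A `us_scene` with probes `A`, `B` and `L1..L8`.
#' @export
build_plate_scene <- function(plate_thickness = 0.2e-3, plate_angle_deg = 36,
                              probe_width = 3.3e-3, frequency = 7e6,
                              resolution = resolution_policy(),
                              plate_depth = 5e-3, probe_offset = 1e-3) {
  if (plate_thickness <= 0 || probe_width <= 0)
    stop("geometry error: non-positive thickness or probe width", call. = FALSE)
  if (plate_angle_deg < 0 || plate_angle_deg >= 90)
    stop("geometry error: plate angle must be in [0, 90)", call. = FALSE)
  dom <- new_scene_domain(frequency, resolution, half_width_geom = 6e-3,
                          depth_geom = plate_depth + 4e-3)
  if (plate_thickness < 2 * dom$dx)
    stop("resolution error: plate thinner than 2 cells at this dx",
         call. = FALSE)
  a <- plate_angle_deg * pi / 180
  nrm <- c(-sin(a), cos(a))              # plate normal (positive = deeper side)
  X <- matrix(dom$x, dom$nx, dom$ny)
  Y <- matrix(dom$y, dom$nx, dom$ny, byrow = TRUE)
  dist <- X * nrm[1] + (Y - plate_depth) * nrm[2]
  mask <- abs(dist) <= plate_thickness / 2
  dom <- paint_mask(dom, mask, material_sus304())
  elements <- list(
    T = list(label = "T", cells = element_cells(dom, -probe_width / 2,
                                                probe_width / 2),
             transmit = TRUE, receive = TRUE))
  u <- c(cos(a), sin(a))                 # down-plate direction
  pt <- function(s, off) c(s * u[1] + off * nrm[1],
                           plate_depth + s * u[2] + off * nrm[2])
  pA <- pt(3e-3, -probe_offset)          # source side
  pB <- pt(3e-3, +probe_offset)          # far side
  # the probe row starts beyond the insonified footprint (beam half-width
  # 1.65 mm around s = 0) so near-field curvature does not bias the lags
  leak_s <- seq(3.5e-3, 6.5e-3, length.out = 8)
  probes <- c(
    list(A = probe_cell(dom, pA[1], pA[2]),
         B = probe_cell(dom, pB[1], pB[2])),
    stats::setNames(lapply(leak_s, function(s) {
      p <- pt(s, 1.2e-3)
      probe_cell(dom, p[1], p[2])
    }), paste0("L", seq_along(leak_s)))
  )
  params <- list(plate_thickness = plate_thickness,
                 plate_angle_deg = plate_angle_deg, probe_width = probe_width,
                 plate_depth = plate_depth, probe_offset = probe_offset,
                 leak_s = leak_s, leak_offset = 1.2e-3,
                 fd = frequency * plate_thickness,
                 deepest = plate_depth + 4e-3)
  finish_scene(dom, "inclined_plate", elements, probes, params,
               v_max = material_sus304()$vl)
}

#' Build a homogeneous water scene (free field)
#'
#' Utility configuration for solver verification: water only, a transmitting
#' element on the face and arbitrary pressure probe points.
#'
#' @param depth,half_width Interior extent (m) excluding padding.
#' @param element_half_width Half-width of the transmitting element (m).
#' @param probes Named list of `c(x, y)` probe positions (m).
#' @param sponge_sides Absorb on the lateral edges (default `TRUE`); with
#'   `FALSE` (and `sponge = 0` in the policy) the box is rigid.
#' @inheritParams build_needle_scene
#' @return A `us_scene`.
#' @export
build_water_scene <- function(depth, half_width, frequency = 7e6,
                              resolution = resolution_policy(),
                              element_half_width = 0.25e-3,
                              probes = list(), sponge_sides = TRUE) {
  dom <- new_scene_domain(frequency, resolution, half_width_geom = half_width,
                          depth_geom = depth, sponge_sides = sponge_sides)
  elements <- list(
    T = list(label = "T",
             cells = element_cells(dom, -element_half_width, element_half_width),
             transmit = TRUE, receive = TRUE))
  pr <- lapply(probes, function(p) probe_cell(dom, p[1], p[2]))
  params <- list(depth = depth, deepest = depth)
  finish_scene(dom, "water", elements, pr, params, v_max = WATER_VL)
}

#' Build a flat water-over-solid interface scene (plane-wave test)
#'
#' Water half-space above a solid half-space with a horizontal interface;
#' the source spans the full width so the propagating field is a normally
#' incident plane wave (lateral edges rigid, no side sponge). Used to verify
#' the pressure reflection coefficient against `(Z2 - Z1)/(Z2 + Z1)`.
#'
#' @param interface_depth Depth of the interface (m).
#' @param material2 Lower half-space material (default SUS304).
#' @param probe_depth Depth of the recording point (m).
#' @inheritParams build_needle_scene
#' @return A `us_scene` with probe `P` on the centerline.
#' @export
build_interface_scene <- function(interface_depth = 4e-3,
                                  material2 = material_sus304(),
                                  probe_depth = 2e-3, frequency = 7e6,
                                  resolution = resolution_policy()) {
  dom <- new_scene_domain(frequency, resolution, half_width_geom = 0.3e-3,
                          depth_geom = interface_depth + 3e-3,
                          sponge_sides = FALSE)
  Y <- matrix(dom$y, dom$nx, dom$ny, byrow = TRUE)
  dom <- paint_mask(dom, Y >= interface_depth, material2)
  elements <- list(
    T = list(label = "T", cells = cbind(seq_len(dom$nx), 1L),
             transmit = TRUE, receive = TRUE))
  probes <- list(P = probe_cell(dom, 0, probe_depth))
  params <- list(interface_depth = interface_depth, probe_depth = probe_depth,
                 deepest = interface_depth)
  finish_scene(dom, "interface", elements, probes, params,
               v_max = max(WATER_VL, material2$vl))
}

#' Mirror a scene about the probe axis
#'
#' Flips all per-cell fields left-right and remaps element/probe columns.
#' Centered geometry is invariant; element A maps onto the mirrored interval.
#'
#' @param scene A `us_scene`.
#' @return The mirrored `us_scene`.
#' @export
mirror_scene <- function(scene) {
  stopifnot(inherits(scene, "us_scene"))
  flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  for (f in c("rho", "lam", "mu", "voidm", "matindex", "damp"))
    scene[[f]] <- flip(scene[[f]])
  remap <- function(cells) {
    cells[, 1] <- scene$nx + 1L - cells[, 1]
    cells[order(cells[, 1]), , drop = FALSE]
  }
  scene$elements <- lapply(scene$elements, function(e) {
    e$cells <- remap(e$cells); e
  })
  scene$probes <- lapply(scene$probes, remap)
  scene
}

#' Summaries of scene composition
#'
#' @param scene A `us_scene`.
#' @return Named integer vector: cells of water, solid and void.
#' @export
scene_cell_counts <- function(scene) {
  c(water = sum(scene$matindex == 0L),
    solid = sum(scene$matindex == 1L),
    void = sum(scene$matindex == 2L))
}

#' @export
print.us_scene <- function(x, ...) {
  cat(sprintf("<us_scene> %s: %d x %d cells, dx = %.3g um, dt = %.3g ns\n",
              x$tag, x$nx, x$ny, x$dx * 1e6, x$dt * 1e9))
  cat(sprintf("  f = %.2f MHz, ppw(water) = %.1f, ppw(steel shear) = %.1f\n",
              x$frequency / 1e6, x$ppw["water"], x$ppw["steel_shear"]))
  cc <- scene_cell_counts(x)
  cat(sprintf("  cells: %d water, %d solid, %d void; elements: %s\n",
              cc["water"], cc["solid"], cc["void"],
              paste(names(x$elements), collapse = ", ")))
  invisible(x)
}

#' @export
plot.us_scene <- function(x, ...) {
  graphics::image(x$x * 1e3, x$y * 1e3, x$matindex,
                  col = c("lightblue", "grey30", "white"),
                  xlab = "x (mm)", ylab = "depth (mm)",
                  ylim = rev(range(x$y * 1e3)), main = x$tag, ...)
  invisible(x)
}

#' Export a scene's material map as a PNG image
#'
#' Water is mid grey, solid dark, void white; written with no graphics
#' device.
#'
#' @param scene A `us_scene`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
scene_to_png <- function(scene, path) {
  shade <- matrix(0.6, scene$nx, scene$ny)
  shade[scene$matindex == 1L] <- 0.15
  shade[scene$matindex == 2L] <- 1.0
  png::writePNG(t(shade), path)
  invisible(path)
}
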