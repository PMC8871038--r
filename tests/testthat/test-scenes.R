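res <- resolution_policy(ppw = 8, sponge = 16)

test_that("material bookkeeping covers every cell in every builder", {
  scenes <- list(
    suppressWarnings(build_needle_scene(10, "steel", 6e-3, resolution = res)),
    suppressWarnings(build_needle_scene(10, "void", 6e-3, resolution = res)),
    build_cylinder_scene("steel", insertion_depth = 6e-3, resolution = res),
    build_tapered_rod_scene(0.5e-3, 2e-3, insertion_depth = 6e-3,
                            resolution = res),
    build_plate_scene(resolution = res)
  )
  for (sc in scenes) {
    cc <- scene_cell_counts(sc)
    expect_identical(sum(cc), as.integer(sc$nx) * as.integer(sc$ny))
  }
})

test_that("needle geometry follows the single-bevel trigonometry", {
  sc <- build_needle_scene(10, "steel", 15e-3, resolution = res)
  # bevel face length along the axis: d / tan(theta) ~ 8.51 mm
  expect_equal(sc$params$bevel_length, 1.5e-3 / tan(10 * pi / 180),
               tolerance = 1e-12)
  expect_equal(sc$params$bevel_length, 8.51e-3, tolerance = 1e-2)
  # deepest solid cell is at the insertion depth (within a cell)
  solid_y <- sc$y[col(sc$matindex)[sc$matindex == 1L]]
  expect_lt(abs(max(solid_y) - 15e-3), 2 * sc$dx)
  # void variant: identical footprint, no steel
  sv <- build_needle_scene(10, "void", 15e-3, resolution = res)
  expect_identical(sv$matindex == 2L, sc$matindex == 1L)
  expect_identical(sum(sv$matindex == 1L), 0L)
})

test_that("ring elements sit at the 3/7 mm annulus and have fixed roles", {
  sc <- build_cylinder_scene("steel", insertion_depth = 6e-3, resolution = res)
  xa <- sc$x[sc$elements$A$cells[, 1]]
  xb <- sc$x[sc$elements$B$cells[, 1]]
  expect_true(all(xa > -3.5e-3 & xa < -1.5e-3))
  expect_true(all(xb > 1.5e-3 & xb < 3.5e-3))
  # disjoint intervals, mirrored about the axis
  expect_length(intersect(sc$elements$A$cells[, 1], sc$elements$B$cells[, 1]), 0)
  expect_equal(sort(-xa), sort(xb), tolerance = 1e-12)
  expect_true(sc$elements$A$transmit && sc$elements$A$receive)
  expect_false(sc$elements$B$transmit)
  expect_true(sc$elements$B$receive)
})

test_that("degenerate geometry inputs error and sub-cell features error", {
  expect_error(build_cylinder_scene("steel", width = 0, resolution = res),
               "geometry error")
  expect_error(build_needle_scene(0.5, "steel", resolution = res),
               "geometry error")
  expect_error(build_needle_scene(10, "steel", diameter = 1e-5,
                                  resolution = res), "resolution error")
  expect_error(build_tapered_rod_scene(2e-3, 1e-3, stem_width = 1.5e-3,
                                       resolution = res), "geometry error")
  expect_error(build_tapered_rod_scene(1e-5, 1e-3, insertion_depth = 6e-3,
                                       resolution = res), "resolution error")
  expect_error(build_plate_scene(plate_thickness = 1e-5, resolution = res),
               "resolution error")
  # a bevel longer than the insertion depth is allowed but flagged
  expect_warning(build_needle_scene(5, "steel", 6e-3, resolution = res),
                 "partially inserted")
})

test_that("tapered rod degenerates to the plain cylinder", {
  cyl <- build_cylinder_scene("steel", 1.5e-3, 6e-3, resolution = res)
  full_w <- build_tapered_rod_scene(1.5e-3, 2e-3, 1.5e-3, 6e-3,
                                    resolution = res)
  zero_l <- build_tapered_rod_scene(0.2e-3, 0, 1.5e-3, 6e-3, resolution = res)
  expect_identical(full_w$matindex, cyl$matindex)
  expect_identical(zero_l$matindex, cyl$matindex)
})

test_that("mirroring preserves centered geometry and remaps elements", {
  sc <- build_cylinder_scene("steel", insertion_depth = 6e-3, resolution = res)
  ms <- mirror_scene(sc)
  expect_identical(ms$matindex, sc$matindex)  # centered rod is symmetric
  expect_equal(sort(sc$x[ms$elements$A$cells[, 1]]),
               sort(-sc$x[sc$elements$A$cells[, 1]]), tolerance = 1e-12)
})

test_that("scenes report points-per-wavelength and enforce the floor", {
  sc <- build_cylinder_scene("steel", insertion_depth = 6e-3, resolution = res)
  expect_equal(unname(sc$ppw["water"]), 8, tolerance = 1e-6)
  expect_equal(unname(sc$ppw["steel_shear"]), 8 * 3100 / 1500,
               tolerance = 1e-6)
  expect_error(resolution_policy(ppw = 4), "below floor")
})

test_that("plate scene crosses the axis at the stated depth and fd", {
  sc <- build_plate_scene(resolution = res)
  expect_equal(sc$params$fd, 7e6 * 0.2e-3)  # 1.4 MHz mm
  mid <- (sc$nx + 1) / 2
  plate_y <- sc$y[sc$matindex[mid, ] == 1L]
  expect_lt(abs(mean(plate_y) - 5e-3), 2 * sc$dx)
  expect_true(all(c("A", "B", "L1") %in% names(sc$probes)))
})
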