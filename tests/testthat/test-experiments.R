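# Pipeline behaviour on the fast "coarse" preset; quantitative ratio and
# sweep claims against the study conditions live in test-acceptance.R.

test_that("steel-vs-steel sanity: identical variants give a 100% ratio", {
  p <- simulation_preset("coarse")
  sc <- build_cylinder_scene("steel", 1.5e-3, p$depth, p$frequency,
                             p$resolution)
  r <- run_simulation(sc)
  g <- echo_gate(sc)
  m <- gated_peak(r$traces$A, g)
  expect_equal(amplitude_ratio(m, m), 100)
})

test_that("steel beats void at the receiving element in both scenes", {
  rc <- cached("cyl_coarse", compare_steel_void_cylinder("coarse"))
  expect_gt(rc$steel$metrics$B$peak, rc$void$metrics$B$peak)
  rn <- cached("needle_coarse", compare_steel_void_needle("coarse"))
  expect_gt(rn$steel$metrics$B$peak, rn$void$metrics$B$peak)
})

test_that("comparisons use identical grids and time steps across variants", {
  rc <- cached("cyl_coarse", compare_steel_void_cylinder("coarse"))
  expect_identical(rc$steel$run$log$nx, rc$void$run$log$nx)
  expect_identical(rc$steel$run$log$dt, rc$void$run$log$dt)
  expect_identical(rc$steel$run$nt, rc$void$run$nt)
})

test_that("sweeps return one ordered row per value with both elements", {
  sw <- run_length_sweep(c(2e-3, 1e-3), preset = "coarse")
  expect_s3_class(sw, "us_sweep")
  expect_identical(nrow(sw), 2L)
  expect_identical(sw$value, c(1, 2))  # sorted ascending, in mm
  expect_true(all(c("peak_A", "peak_B", "energy_A", "energy_B",
                    "phase_relation", "pair_separation") %in% names(sw)))
  expect_true(all(sw$peak_A >= 0))
  # single-value sweep returns exactly one row
  s1 <- run_width_sweep(1.5e-3, preset = "coarse")
  expect_identical(nrow(s1), 1L)
  # duplicate values are rejected
  expect_error(run_length_sweep(c(1e-3, 1e-3), preset = "coarse"))
})

test_that("sweep argmax answers come from the stored rows", {
  sw <- run_length_sweep(c(2e-3, 1e-3), preset = "coarse")
  expect_identical(sweep_argmax(sw, "A"),
                   sw$value[which.max(sw$peak_A)])
  expect_identical(sweep_argmax(sw, "B", metric = "energy"),
                   sw$value[which.max(sw$energy_B)])
})

test_that("experiments are deterministic across reruns", {
  r1 <- compare_steel_void_cylinder("coarse")
  r2 <- cached("cyl_coarse", compare_steel_void_cylinder("coarse"))
  expect_identical(r1$fold_ratio, r2$fold_ratio)
  expect_identical(r1$steel$run$traces$A$samples,
                   r2$steel$run$traces$A$samples)
})

test_that("plate demo produces snapshots, opposite-phase probes and a leak angle", {
  demo <- cached("plate_demo_ci", run_plate_demo("ci"))
  expect_gt(length(demo$run$snapshots), 0)
  expect_identical(dim(demo$run$snapshots[[1]]$field),
                   as.integer(c(demo$scene$nx, demo$scene$ny)))
  expect_identical(demo$phase_relation, "anti_phase")
  expect_true(is.finite(demo$leak_angle_deg))
  expect_gt(nrow(demo$theory), 0)
})

test_that("a plate-free water run shows no post-gate arrivals at the probes", {
  p <- simulation_preset("coarse")
  sc <- build_water_scene(9e-3, 6e-3, frequency = p$frequency,
                          resolution = p$resolution,
                          element_half_width = 1.65e-3,
                          probes = list(A = c(0.76e-3, 3.42e-3)))
  run <- suppressWarnings(run_simulation(sc, duration = 1.4e-5))
  tr <- run$traces$A
  tt <- trace_times(tr)
  direct <- max(abs(tr$samples[tt < 6e-6]))
  late <- max(abs(tr$samples[tt > 8e-6]))
  expect_lt(late, 0.02 * direct)
})
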