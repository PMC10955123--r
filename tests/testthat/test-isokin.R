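test_that("alternating repetitions segment into one run per direction", {
  sp <- trial_spec(target_speed = 30, rom_start = -60, rom_end = 90,
                   noise_sd_torque = 0, seed = 6)
  tr <- simulate_active_trial(sp, 40, 20, n_reps = 3)
  segs <- segment_repetitions(tr)
  expect_length(segs, 6)
  expect_identical(vapply(segs, function(s) s$direction, ""),
                   rep(c("external", "internal"), 3))
})

test_that("passive ten-cycle trial yields twenty directional segments", {
  ps <- trial_spec(mode = "passive", target_speed = 10, rom_start = 0,
                   rom_end = 140, noise_sd_torque = 0, seed = 7)
  tr <- simulate_passive_trial(ps, c(0.5, 0.05, 0), n_cycles = 10)
  expect_length(segment_repetitions(tr), 20)
})

test_that("monotone ramp gives a single segment with a warning", {
  tr <- structure(list(time_s = seq(0, 1, by = 0.005),
                       angle_deg = seq(0, 60, length.out = 201),
                       torque_Nm = rep(5, 201),
                       velocity_dps = rep(60, 201),
                       meta = list(sampling_rate = 200)),
                  class = "dyn_trial")
  expect_warning(segs <- segment_repetitions(tr), "single movement direction")
  expect_length(segs, 1)
})

test_that("isokinetic phase recovers the generator's plateau", {
  sp <- trial_spec(target_speed = 30, rom_start = 0, rom_end = 120,
                   accel_time = 0.25, noise_sd_torque = 0, seed = 8)
  tr <- simulate_active_trial(sp, 40, 60, n_reps = 1)
  segs <- segment_repetitions(tr)
  # with a tight band only true plateau samples qualify
  ph <- extract_isokinetic_phase(segs[[1]], tol_fraction = 1e-9)
  expect_equal(c(ph$start, ph$end), tr$ground_truth$plateau[[1]])
  # the default 10% band is a superset containing the plateau
  ph10 <- extract_isokinetic_phase(segs[[1]])
  expect_lte(ph10$start, tr$ground_truth$plateau[[1]][1])
  expect_gte(ph10$end, tr$ground_truth$plateau[[1]][2])
})

test_that("phase extraction on constant-velocity or out-of-band input behaves per contract", {
  tr <- structure(list(time_s = seq(0, 1, by = 0.005),
                       angle_deg = seq(0, 30, length.out = 201),
                       torque_Nm = rep(5, 201),
                       velocity_dps = rep(30, 201),
                       meta = list(sampling_rate = 200, target_speed = 30)),
                  class = "dyn_trial")
  seg <- suppressWarnings(segment_repetitions(tr))[[1]]
  ph <- extract_isokinetic_phase(seg)
  expect_equal(c(ph$start, ph$end), c(1L, 201L))   # whole segment
  expect_error(extract_isokinetic_phase(seg, target_speed = 60),
               "no isokinetic phase")
})

test_that("phase extraction is idempotent", {
  sp <- trial_spec(target_speed = 30, rom_start = 0, rom_end = 120,
                   accel_time = 0.25, noise_sd_torque = 0, seed = 9)
  tr <- simulate_active_trial(sp, 40, 60, n_reps = 1)
  ph <- extract_isokinetic_phase(segment_repetitions(tr)[[1]])
  # re-segment the extracted phase as a standalone trial
  sub <- structure(list(time_s = tr$time_s[ph$start:ph$end],
                        angle_deg = ph$angle_deg, torque_Nm = ph$torque_Nm,
                        velocity_dps = tr$velocity_dps[ph$start:ph$end],
                        meta = tr$meta),
                   class = "dyn_trial")
  seg2 <- suppressWarnings(segment_repetitions(sub))[[1]]
  ph2 <- extract_isokinetic_phase(seg2)
  expect_equal(ph2$torque_Nm, ph$torque_Nm)
})

test_that("normalization divides by mass and rejects bad mass", {
  expect_equal(normalize_to_body_mass(45.63, 89.2), 45.63 / 89.2)
  expect_equal(normalize_to_body_mass(45.63, 89.2), 0.5116, tolerance = 2e-4)
  expect_equal(normalize_to_body_mass(c(1, 2, 0), 1), c(1, 2, 0))
  expect_error(normalize_to_body_mass(10, 0), "> 0")
})

test_that("interpolation to 101 nodes is exact on lines and preserves endpoints", {
  phase <- list(angle_deg = seq(0, 100, by = 0.5),
                torque_Nm = 3 + 0.2 * seq(0, 100, by = 0.5))
  crv <- to_normalized_curve(phase)
  grid <- seq(0, 100, length.out = 101)
  expect_equal(crv$torque, 3 + 0.2 * grid, tolerance = 1e-12)
  expect_identical(crv$torque[1], phase$torque_Nm[1])
  expect_identical(crv$torque[101], phase$torque_Nm[length(phase$torque_Nm)])
  expect_error(to_normalized_curve(list(angle_deg = rep(5, 10),
                                        torque_Nm = 1:10)), "degenerate")
})

test_that("smooth bell survives downsample-then-resample within 1e-3 of peak", {
  ang <- seq(-60, 90, length.out = 1000)
  bell <- 40 * exp(-(ang - 20)^2 / (2 * 40^2))
  coarse_idx <- round(seq(1, 1000, length.out = 150))
  crv <- to_normalized_curve(list(angle_deg = ang[coarse_idx],
                                  torque_Nm = bell[coarse_idx]))
  grid <- seq(ang[coarse_idx[1]], ang[coarse_idx[150]], length.out = 101)
  direct <- 40 * exp(-(grid - 20)^2 / (2 * 40^2))
  expect_lt(max(abs(crv$torque - direct)), 1e-3 * 40)
})

test_that("pipeline is equivariant under torque scaling and mass normalization", {
  sp <- trial_spec(target_speed = 30, rom_start = 0, rom_end = 120,
                   noise_sd_torque = 0, seed = 10)
  tr <- simulate_active_trial(sp, 40, 60, n_reps = 1)
  ph <- extract_isokinetic_phase(segment_repetitions(tr)[[1]])
  c1 <- to_normalized_curve(ph)
  k <- 2.5
  ph_scaled <- ph
  ph_scaled$torque_Nm <- k * ph$torque_Nm
  c2 <- to_normalized_curve(ph_scaled)
  expect_equal(c2$torque, k * c1$torque, tolerance = 1e-12)
  # scaling torque and mass together leaves the normalized curve invariant
  c3 <- to_normalized_curve(ph, body_mass = 80)
  c4 <- to_normalized_curve(ph_scaled, body_mass = k * 80)
  expect_equal(c3$torque, c4$torque, tolerance = 1e-12)
})

test_that("trial CSV and curves TSV round-trip", {
  sp <- trial_spec(seed = 11)
  tr <- simulate_active_trial(sp, 40, 20, n_reps = 1, body_mass = 77)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  tr2 <- read_trial_csv(path)
  expect_equal(tr2$torque_Nm, tr$torque_Nm, tolerance = 1e-9)
  expect_equal(tr2$meta$body_mass, 77)

  set.seed(1)
  cs <- null_curve_set(3, 3, Q = 21)
  p2 <- tempfile(fileext = ".tsv")
  write_curves_tsv(cs, p2)
  cs2 <- read_curves_tsv(p2)
  expect_equal(cs2$curves, cs$curves, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(as.character(cs2$time), cs$time)
})
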