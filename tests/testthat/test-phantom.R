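test_that("phantom construction invariants hold", {
  ph <- test_phantom()
  m <- ph$masks
  # CSF nonempty and strictly inside the brain
  expect_gt(sum(m$csf), 0)
  expect_true(all(m$brain[m$csf]))
  expect_true(all(m$brain[dynqsm:::dilate_mask(m$csf, 1)]))
  # tissue classes mutually exclusive
  expect_equal(sum(m$wm & m$gm), 0)
  expect_equal(sum(m$wm & m$csf), 0)
  expect_equal(sum(m$vessel & m$csf), 0)
  expect_equal(sum(m$gm & m$vessel), 0)
  # vessel voxels carry the pure-blood CBV equivalent (blood fraction 1)
  expect_true(all(abs(ph$cbv_map[m$vessel] -
                        100 / 1.04 * 0.55 / 0.75) < 1e-9))
  # no blood volume in CSF
  expect_true(all(ph$cbv_map[m$csf] == 0))
  # deterministic given seed
  ph2 <- build_phantom(c(32, 32, 32), seed = 7)
  expect_identical(ph$chi0_map, ph2$chi0_map)
  expect_identical(ph$masks$vessel, ph2$masks$vessel)
  # different seed jitters geometry
  ph3 <- build_phantom(c(32, 32, 32), seed = 8)
  expect_false(identical(ph$chi0_map, ph3$chi0_map))
  expect_error(build_phantom(c(16, 16, 16)), "grid")
})

test_that("blood curve hits the prescribed peak and tail exactly", {
  pr <- small_params()
  for (case in list(c(5, 9), c(10, 9), c(7, 5))) {
    bl <- simulate_blood_curve(pr, peak_conc = case[1],
                               peak_to_tail_ratio = case[2])
    expect_equal(max(bl$concentration), case[1], tolerance = 0.01 * case[1])
    expect_equal(mean(utils::tail(bl$concentration, 5)), case[1] / case[2],
                 tolerance = 1e-8)
    # baseline frames exactly zero
    expect_identical(bl$concentration[1:14], rep(0, 14))
    # single dominant peak before the tail plateau
    expect_gt(which.max(bl$concentration), 14)
  }
  expect_error(simulate_blood_curve(pr, peak_conc = -1), "peak_conc")
  expect_error(simulate_blood_curve(pr, peak_to_tail_ratio = 1), "exceed")
})

test_that("tissue concentration follows the hematocrit-scaled CBV relation", {
  ph <- test_phantom()
  bl <- test_blood()
  physio <- physio_constants()
  conc <- tissue_concentration_series(ph, bl, physio)
  m <- ph$masks
  tail_t <- dim(conc)[4]
  cb_tail <- bl$concentration[tail_t]
  # white matter voxel: (cbv/100) * rho * (1-Hct_sv)/(1-Hct_lv) * blood
  wm_vox <- which(m$wm)[1]
  expected_wm <- 1.91 / 100 * 1.04 * (0.75 / 0.55) * cb_tail
  expect_equal(conc[wm_vox + (tail_t - 1) * prod(dim(conc)[1:3])],
               expected_wm, tolerance = 1e-12)
  # hand value: cbv 1.91 with blood tail 1.111 mM gives 0.0301 mM
  expect_equal(1.91 / 100 * 1.04 * (0.75 / 0.55) * (10 / 9), 0.030097,
               tolerance = 1e-4)
  # which is 0.00927 ppm at 308 ppm/M (the printed WM upper bound)
  expect_equal(dynqsm:::conc_to_ppm(0.030097, 308), 0.00927,
               tolerance = 1e-4)
  # vessel voxels carry whole-blood concentration
  ves <- which(m$vessel)[1]
  expect_equal(conc[ves + (tail_t - 1) * prod(dim(conc)[1:3])], cb_tail,
               tolerance = 1e-12)
  # CSF identically zero; zero blood curve -> zero everywhere
  csf_rows <- dynqsm:::pixel_curves(conc, which(m$csf))
  expect_true(all(csf_rows == 0))
  # linearity: doubling blood doubles tissue
  bl2 <- bl
  bl2$concentration <- 2 * bl$concentration
  conc2 <- tissue_concentration_series(ph, bl2, physio)
  expect_equal(conc2, 2 * conc, tolerance = 1e-12)
})

test_that("simulated series is deterministic and wrapped", {
  ser <- test_series()
  expect_true(all(ser$phase > -pi - 1e-12 & ser$phase <= pi + 1e-12))
  ph <- test_phantom()
  pr <- small_params()
  bl <- test_blood()
  ser2 <- simulate_series(ph, bl, pr, noise_sd = 0.02, seed = 3)
  ser3 <- simulate_series(ph, bl, pr, noise_sd = 0.02, seed = 3)
  expect_identical(ser2$magnitude, ser3$magnitude)
  expect_identical(ser2$phase, ser3$phase)
  ser4 <- simulate_series(ph, bl, pr, noise_sd = 0.02, seed = 4)
  expect_false(identical(ser2$phase, ser4$phase))
})

test_that("noiseless CSF magnitude is flat and baseline phase matches the
           forward field", {
  ph <- test_phantom()
  ser <- test_series()
  m <- ph$masks
  csf_mag <- dynqsm:::pixel_curves(ser$magnitude, which(m$csf))
  expect_lt(max(apply(csf_mag, 1, function(v) diff(range(v)))), 1e-12)
  # frame 1 (no CA, no drift at t=1): phase = wrapped scaled forward field
  pr <- ser$params
  D <- dipole_kernel(ph$grid_shape, pr$voxel_size)
  f <- forward_field(ph$chi0_map, D = D)
  shim <- dynqsm:::shim_correction(f, m$brain)
  expected <- wrap_to_pi(field_to_phase(f - shim, pr))
  expect_equal(ser$phase[, , , 1], expected, tolerance = 1e-10)
})

test_that("noiseless forward model is self-consistent for Delta-R2*", {
  ph <- test_phantom()
  ser <- test_series()
  bl <- test_blood()
  wins <- steady_state_windows()
  dr <- delta_r2star(ser, wins)
  conc <- tissue_concentration_series(ph, bl)
  nt <- dim(dr)[4]
  wm_idx <- which(ph$masks$wm)[c(1, 11, 31)]
  nvox <- prod(dim(dr)[1:3])
  for (v in wm_idx) {
    expect_equal(dr[v + (nt - 1) * nvox],
                 ph$r2s_tissue_relaxivity * conc[v + (nt - 1) * nvox],
                 tolerance = 0.01)
  }
})
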