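test_that("theory-expected values reproduce the printed steady-state table", {
  tab <- theory_expected_values(peak_conc_range = c(5, 10),
                                peak_to_tail_ratio = 9)
  blood <- tab[tab$compartment == "blood", ]
  # tail concentrations 5/9 and 10/9 mM
  expect_equal(blood$concentration, c(5, 10) / 9, tolerance = 1e-12)
  # blood delta-chi printed as 0.17-0.34 ppm
  expect_identical(blood$delta_chi_report, c(0.17, 0.34))
  wm <- tab[tab$compartment == "wm", ]
  gm <- tab[tab$compartment == "gm", ]
  # tissue delta-chi printed as 0.005-0.009 (WM) and 0.009-0.019 (GM) ppm
  expect_identical(wm$delta_chi_report, c(0.005, 0.009))
  expect_identical(gm$delta_chi_report, c(0.009, 0.019))
  # tissue concentrations round to 0.02-0.03 (WM) and 0.03-0.06 (GM) mM
  expect_identical(round_half_up(wm$concentration * 100) / 100, c(0.02, 0.03))
  expect_identical(round_half_up(gm$concentration * 100) / 100, c(0.03, 0.06))
})

test_that("concentration conversion follows chi = chi_mol * [CA]", {
  ph <- physio_constants()
  # 0.20 ppm at 308 ppm/M -> 0.65 mM; 0.0079 ppm -> 0.026 mM
  expect_equal(round_half_up(0.20 * 1000 / ph$chi_mol * 100) / 100, 0.65)
  expect_equal(round_half_up(0.0079 * 1000 / ph$chi_mol * 1000) / 1000,
               0.026)
  expect_identical(dynqsm:::ppm_to_conc(0, ph$chi_mol), 0)
  # round trip
  expect_equal(dynqsm:::conc_to_ppm(dynqsm:::ppm_to_conc(0.3, 308), 308),
               0.3, tolerance = 1e-14)
})

test_that("concentration_from_susceptibility rejects unshifted input and is
           exact on constructed series", {
  dm <- c(4L, 4L, 4L)
  nt <- 20L
  chi <- array(0, c(dm, nt))
  chi0 <- 0.05
  dchi <- 0.154   # -> 0.5 mM at 308 ppm/M
  for (t in 1:nt) chi[, , , t] <- chi0 + if (t > 14) dchi else 0
  mask <- array(TRUE, dm)
  unshifted <- susceptibility_series(chi, mask, "unshifted")
  expect_error(concentration_from_susceptibility(unshifted), "shift")
  shifted <- susceptibility_series(chi, mask, "csf_shifted")
  conc <- concentration_from_susceptibility(shifted,
                                            steady_state_windows(post_n = 4))
  expect_equal(unique(as.vector(conc[, , , 20])), 0.5, tolerance = 1e-12)
  expect_equal(unique(as.vector(conc[, , , 10])), 0, tolerance = 1e-12)
})

test_that("delta_r2star matches the log-ratio definition and flags bad voxels", {
  dm <- c(3L, 3L, 3L)
  nt <- 20L
  mag <- array(1, c(dm, nt))
  mag[, , , 16:20] <- exp(-1)          # S/S0 = e^-1
  pr <- acquisition_params(n_timepoints = nt)
  ser <- dynamic_series(mag, array(0, c(dm, nt)), pr)
  dr <- delta_r2star(ser, steady_state_windows(post_n = 4))
  expect_equal(dr[1, 1, 1, 16], 1 / 0.029, tolerance = 1e-10)
  expect_equal(dr[1, 1, 1, 10], 0, tolerance = 1e-12)
  # a voxel hitting zero signal is flagged, not propagated
  mag2 <- mag
  mag2[1, 1, 1, 18] <- 0
  ser2 <- dynamic_series(mag2, array(0, c(dm, nt)), pr)
  dr2 <- delta_r2star(ser2, steady_state_windows(post_n = 4))
  expect_true(attr(dr2, "invalid")[1, 1, 1])
  expect_true(all(is.na(dr2[1, 1, 1, ])))
  expect_false(any(is.na(dr2[2, , , ])))
})

test_that("cbv formulas match hand arithmetic and error on zero blood", {
  res <- cbv_qsm(0.0079, 0.20)
  expect_equal(res$cbv, 100 / 1.04 * (0.55 / 0.75) * 0.0079 / 0.20,
               tolerance = 1e-12)
  expect_equal(round(res$cbv, 2), 2.79)
  expect_equal(cbv_qsm(0, 0.2)$cbv, 0)
  # pure-blood voxel sanity bound
  expect_equal(cbv_qsm(0.2, 0.2)$cbv, 100 * (0.55 / 0.75) / 1.04,
               tolerance = 1e-12)
  expect_error(cbv_qsm(0.01, 0), "zero")
  # dr2s variant coincides with qsm when differences are equal
  expect_equal(cbv_dr2s(30, 100)$cbv,
               100 * 0.55 * 30 / (1.04 * 0.75 * 100), tolerance = 1e-12)
  expect_equal(cbv_dr2s(0, 50)$cbv, 0)
  expect_error(cbv_dr2s(10, 0), "zero")
})

test_that("fit_relaxivity recovers exact slope on noiseless collinear data", {
  dm <- c(2L, 2L, 2L)
  nt <- 30L
  conc <- array(0, c(dm, nt))
  for (t in 15:nt) conc[, , , t] <- 0.01 * (t - 14)
  dr2s <- 85 * conc
  mask <- array(TRUE, dm)
  fit <- fit_relaxivity(dr2s, conc, mask)
  expect_equal(fit$slope, 85, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_error(fit_relaxivity(dr2s * 0 + 1, conc * 0, mask), "degenerate")
})

test_that("blood delta-chi differencing is wrap-robust and linear in dose", {
  pr <- acquisition_params(n_timepoints = 30L)
  wins <- steady_state_windows(post_n = 7)
  theta <- 25 * pi / 180
  geom <- (3 * cos(theta)^2 - 1) / 6
  phi_t <- function(dchi) field_to_phase(dchi * geom, pr)
  mk_curves <- function(dchi_tail, wrap_err = 0) {
    base <- 1.2
    curve <- rep(base, 30)
    curve[24:30] <- base + phi_t(dchi_tail)
    curve[27] <- curve[27] + wrap_err   # residual 2*pi unwrap error
    rbind(curve, curve, curve)
  }
  clean <- dynqsm:::blood_dchi_core(mk_curves(0.17), theta, wins, pr)
  expect_equal(clean$delta_chi, 0.17, tolerance = 1e-10)
  # equal pre/post -> zero
  flat <- dynqsm:::blood_dchi_core(mk_curves(0), theta, wins, pr)
  expect_equal(flat$delta_chi, 0, tolerance = 1e-12)
  # doubling the dose doubles the difference
  dbl <- dynqsm:::blood_dchi_core(mk_curves(0.34), theta, wins, pr)
  expect_equal(dbl$delta_chi / clean$delta_chi, 2, tolerance = 1e-10)
  # a 2*pi branch error in one vessel voxel-frame does not corrupt it
  wr <- dynqsm:::blood_dchi_core(mk_curves(0.17, wrap_err = 2 * pi),
                                 theta, wins, pr)
  expect_equal(wr$delta_chi, 0.17, tolerance = 1e-10)
})
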