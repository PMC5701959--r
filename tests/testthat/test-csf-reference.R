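# synthetic curve-level fixtures exercise the selection rules exactly
mk_chi_series <- function(curves, dm = NULL) {
  # curves: matrix voxels x time laid over a small grid
  nv <- nrow(curves); nt <- ncol(curves)
  n <- ceiling(nv^(1 / 3))
  if (is.null(dm)) dm <- c(n, n, max(2L, ceiling(nv / n^2)))
  chi <- array(0, c(dm, nt))
  for (t in seq_len(nt)) {
    fr <- numeric(prod(dm))
    fr[seq_len(nv)] <- curves[, t]
    chi[, , , t] <- array(fr, dm)
  }
  susceptibility_series(chi, array(TRUE, dm), "unshifted")
}

test_that("candidate ROI is the ventricular CSF mask, disjoint from tissue", {
  ph <- test_phantom()
  roi <- candidate_roi(ph$masks)
  expect_identical(roi, which(ph$masks$csf))
  expect_true(all(ph$masks$brain[roi]))
  expect_false(any(ph$masks$wm[roi]))
  expect_false(any(ph$masks$gm[roi]))
  expect_error(candidate_roi(list(csf = array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("signal-range criterion keeps the prescribed count, smallest first", {
  dm <- c(5L, 5L, 2L)
  nt <- 20L
  mag <- array(1, c(dm, nt))
  roi <- 1:10
  # give pixel i a range of i/100
  for (i in roi) mag[i + (nt - 1) * prod(dm) * 0] <- 1  # keep baseline
  for (i in roi) mag[arrayInd(i, dm)[1], arrayInd(i, dm)[2],
                     arrayInd(i, dm)[3], nt] <- 1 + i / 100
  ser <- dynamic_series(mag, array(0, c(dm, nt)),
                        acquisition_params(n_timepoints = nt))
  # thresh 10% of 10 pixels -> exactly the single smallest-range pixel
  out <- filter_by_signal_range(ser, roi, reference_config(thresh_range = 10))
  expect_identical(out$pixels, 1L)
  # thresh 100% -> the whole ROI
  out2 <- filter_by_signal_range(ser, roi,
                                 reference_config(thresh_range = 100))
  expect_identical(out2$pixels, sort(roi))
  # 25% of 10 -> round-half-up(2.5) = 3 pixels
  out3 <- filter_by_signal_range(ser, roi,
                                 reference_config(thresh_range = 25))
  expect_identical(out3$pixels, 1:3)
})

test_that("CSF pixels beat grey-matter decoys on signal range", {
  ph <- test_phantom()
  ser <- test_series()
  csf_px <- which(ph$masks$csf)[1:10]
  gm_px <- which(ph$masks$gm)[1:10]
  out <- filter_by_signal_range(ser, c(csf_px, gm_px),
                                reference_config(thresh_range = 50))
  expect_true(all(out$pixels %in% csf_px))
})

test_that("tail-to-peak trimming discards the extremes symmetrically", {
  nt <- 30L
  n_cand <- 20L
  # brain mean curve with a clear bolus dip in magnitude and hump in chi
  brain_chi <- c(rep(0, 14), 0.05 * exp(-((15:nt) - 18)^2 / 8) + 0.01)
  set.seed(5)
  curves <- matrix(rnorm(n_cand * nt, 0, 1e-4), n_cand, nt)
  # two corrupted candidates: large spikes at the tail, opposite signs
  curves[1, 28:30] <- curves[1, 28:30] + 0.05
  curves[2, 28:30] <- curves[2, 28:30] - 0.05
  chi <- mk_chi_series(sweep(curves, 2L, brain_chi, "+"))
  dm <- dim(chi$chi)[1:3]
  mag <- array(1, c(dm, nt))
  mag_curve <- c(rep(1, 14), 1 - 0.5 * exp(-((15:nt) - 18)^2 / 8))
  for (t in seq_len(nt)) mag[, , , t] <- mag_curve[t]
  ser <- dynamic_series(mag, array(0, c(dm, nt)),
                        acquisition_params(n_timepoints = nt))
  brain_mask <- array(TRUE, dm)
  # thresh 0: everything retained
  sel0 <- filter_by_tailpeak(chi, ser, 1:n_cand, brain_mask,
                             reference_config(thresh_tailpeak = 0))
  expect_identical(sel0$pixels, 1:n_cand)
  # 30% of 20 -> 3 from each end discarded, 14 retained
  sel <- filter_by_tailpeak(chi, ser, 1:n_cand, brain_mask,
                            reference_config(thresh_tailpeak = 30))
  expect_length(sel$pixels, 14L)
  # the spiked candidates are among the discarded
  expect_false(1L %in% sel$pixels)
  expect_false(2L %in% sel$pixels)
  # discarding everything raises a helpful error
  expect_error(filter_by_tailpeak(chi, ser, 1:4, brain_mask,
                                  reference_config(thresh_tailpeak = 99)),
               "thresh_tailpeak")
})

test_that("selection size is monotone in the thresholds", {
  ph <- test_phantom()
  ser <- test_series()
  rec_chi <- susceptibility_series(
    array(rnorm(prod(dim(ser$phase))) * 1e-3, dim(ser$phase)),
    ph$masks$brain, "unshifted")
  sizes_r <- vapply(c(10, 30, 60, 100), function(tr)
    length(select_csf_reference(rec_chi, ser, ph$masks,
                                reference_config(thresh_range = tr))$pixels),
    numeric(1))
  expect_true(all(diff(sizes_r) >= 0))
  sizes_t <- vapply(c(0, 20, 40), function(tp)
    length(select_csf_reference(rec_chi, ser, ph$masks,
                                reference_config(thresh_tailpeak = tp))$pixels),
    numeric(1))
  expect_true(all(diff(sizes_t) <= 0))
})

test_that("shifting flattens the reference at its baseline and is idempotent", {
  nt <- 25L
  set.seed(9)
  curves <- matrix(rnorm(8 * nt, 1, 0.2), 8, nt)
  chi <- mk_chi_series(curves)
  sel <- structure(list(pixels = 1:4), class = "reference_selection")
  wins <- steady_state_windows(post_n = 5)
  sh <- shift_susceptibility(chi, sel, wins)
  expect_identical(sh$reference_state, "csf_shifted")
  ref_curve <- colMeans(dynqsm:::pixel_curves(sh$chi, 1:4))
  base <- mean(ref_curve[5:14])
  expect_lt(max(abs(ref_curve - base)), 1e-12)
  # idempotent
  sh2 <- shift_susceptibility(sh, sel, wins)
  expect_equal(sh2$chi, sh$chi, tolerance = 1e-12)
  # spatial differences preserved at every frame
  d_before <- chi$chi[1, 1, 1, ] - chi$chi[2, 2, 1, ]
  d_after <- sh$chi[1, 1, 1, ] - sh$chi[2, 2, 1, ]
  expect_equal(d_before, d_after, tolerance = 1e-12)
})

test_that("phase drift correction removes an injected linear drift", {
  dm <- c(4L, 4L, 4L)
  nt <- 25L
  drift <- 0.03 * (seq_len(nt) - 1)
  ph4 <- array(0, c(dm, nt))
  for (t in seq_len(nt)) ph4[, , , t] <- 0.4 + drift[t]
  fs <- field_series(ph4, array(TRUE, dm), "unwrapped", "rad",
                     acquisition_params(n_timepoints = nt))
  sel <- structure(list(pixels = 1:6), class = "reference_selection")
  corr <- shift_phase(fs, sel, steady_state_windows(post_n = 5))
  csf_curve <- colMeans(dynqsm:::pixel_curves(corr$values, 1:6))
  expect_lt(max(abs(csf_curve - csf_curve[1])), 1e-12)
  # the applied correction is the same scalar for every voxel per frame
  delta <- ph4 - corr$values
  for (t in seq_len(nt))
    expect_lt(diff(range(delta[, , , t])), 1e-12)
  # with zero drift the correction is ~0
  ph0 <- array(0.4, c(dm, nt))
  fs0 <- field_series(ph0, array(TRUE, dm), "unwrapped", "rad")
  corr0 <- shift_phase(fs0, sel, steady_state_windows(post_n = 5))
  expect_lt(max(abs(corr0$diagnostics$reference_shift)), 1e-12)
})
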