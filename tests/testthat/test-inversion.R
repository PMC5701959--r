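inv_setup <- function(dm = c(32L, 32L, 32L)) {
  ph <- build_phantom(dm, seed = 7)
  m <- ph$masks
  D <- dipole_kernel(dm)
  chi_in <- ph$chi0_map
  chi_in[!m$brain] <- 0
  list(ph = ph, m = m, D = D, chi_in = chi_in)
}

fs_of <- function(f3_list, mask) {
  dm <- dim(f3_list[[1]])
  field_series(array(unlist(f3_list), c(dm, length(f3_list))), mask,
               stage = "background-removed", unit = "ppm",
               params = acquisition_params())
}

test_that("tkd recovers piecewise-constant region means from a clean field", {
  dm <- c(48L, 48L, 48L)
  g <- dynqsm:::index_grids(dm)
  ell <- function(cx, a) ((g$x - cx[1]) / a[1])^2 +
    ((g$y - cx[2]) / a[2])^2 + ((g$z - cx[3]) / a[3])^2 <= 1
  mask <- ell(c(24.5, 24.5, 24.5), c(18, 19, 16))
  blob1 <- ell(c(18, 20, 22), c(5, 6, 5))
  blob2 <- ell(c(31, 29, 27), c(6, 5, 5))
  ref <- ell(c(24.5, 24.5, 24.5), c(3, 3, 3)) & !blob1 & !blob2
  chi_true <- array(0, dm)
  chi_true[blob1] <- 0.05
  chi_true[blob2] <- -0.03
  f <- forward_field(chi_true)
  s0 <- array(0.1, dm); s0[mask] <- 1
  chi <- invert_dipole(fs_of(list(f), mask), s0, mask, inversion_config())
  x <- chi$chi[, , , 1]
  expect_lt(abs((mean(x[blob1]) - mean(x[ref])) / 0.05 - 1), 0.10)
  expect_lt(abs((mean(x[blob2]) - mean(x[ref])) / (-0.03) - 1), 0.10)
  expect_identical(chi$reference_state, "unshifted")
})

test_that("tkd is linear and insensitive to constant field offsets", {
  s <- inv_setup()
  set.seed(3)
  f1 <- forward_field(s$chi_in, D = s$D)
  f2 <- forward_field(array(rnorm(prod(dim(f1)), 0, 0.01), dim(f1)),
                      D = s$D)
  cfg <- inversion_config()
  inv1 <- invert_dipole(fs_of(list(f1), s$m$brain), s$ph$s0_map,
                        s$m$brain, cfg)$chi[, , , 1]
  inv2 <- invert_dipole(fs_of(list(f2), s$m$brain), s$ph$s0_map,
                        s$m$brain, cfg)$chi[, , , 1]
  inv12 <- invert_dipole(fs_of(list(f1 + f2), s$m$brain), s$ph$s0_map,
                         s$m$brain, cfg)$chi[, , , 1]
  expect_equal(inv12, inv1 + inv2, tolerance = 1e-10)
  # absolute level is not recoverable: offsets vanish (D(0) = 0)
  invoff <- invert_dipole(fs_of(list(f1 + 0.25), s$m$brain), s$ph$s0_map,
                          s$m$brain, cfg)$chi[, , , 1]
  expect_equal(invoff, inv1, tolerance = 1e-10)
})

test_that("non-finite field values inside the mask are rejected", {
  s <- inv_setup()
  f <- forward_field(s$chi_in, D = s$D)
  f[which(s$m$brain)[1]] <- NaN
  expect_error(invert_dipole(fs_of(list(f), s$m$brain), s$ph$s0_map,
                             s$m$brain), "finite")
})

test_that("regularized inversion contrast is non-decreasing in lambda", {
  s <- inv_setup()
  set.seed(11)
  dyn <- array(0, dim(s$chi_in))
  dyn[s$m$gm] <- 0.012
  dyn[s$m$wm] <- 0.006
  noise <- function() array(rnorm(prod(dim(dyn)), 0, 8.6e-4), dim(dyn))
  f1 <- forward_field(s$chi_in, D = s$D) + noise()
  f2 <- forward_field(s$chi_in + dyn, D = s$D) + noise()
  fs <- fs_of(list(f1, f2), s$m$brain)
  contrasts <- vapply(c(100, 1000, 5000), function(lam) {
    chi <- invert_dipole(fs, s$ph$s0_map, s$m$brain,
                         inversion_config(method = "medi_like", lam = lam))
    d <- chi$chi[, , , 2] - chi$chi[, , , 1]
    mean(d[s$m$gm]) - mean(d[s$m$wm])
  }, numeric(1))
  expect_true(all(diff(contrasts) >= 0))
})

test_that("cross-talk calibration matrix deconvolves region means", {
  s <- inv_setup(c(40L, 40L, 40L))
  m <- s$m
  xt <- region_crosstalk_matrix(m, valid = array(TRUE, dim(s$chi_in)),
                                cfg = inversion_config())
  # diagonal dominance: each compartment responds mostly to itself
  expect_true(all(diag(xt$M[c("wm", "gm"), c("wm", "gm")]) > 0.5))
  expect_true(all(abs(xt$M["wm", "gm"]) < xt$M["wm", "wm"]))
  # synthetic truth: known compartment amplitudes recovered through M
  a_true <- c(wm = 0.004, gm = 0.009)
  D <- dipole_kernel(dim(s$chi_in))
  src <- array(0, dim(s$chi_in))
  src[m$wm] <- a_true["wm"]; src[m$gm] <- a_true["gm"]
  f <- forward_field(src, D = D)
  chi <- invert_dipole(fs_of(list(f), m$brain), s$ph$s0_map, m$brain,
                       inversion_config())$chi[, , , 1]
  y <- c(wm = mean(chi[m$wm]) - mean(chi[m$csf]),
         gm = mean(chi[m$gm]) - mean(chi[m$csf]))
  a_hat <- solve(xt$M[c("wm", "gm"), c("wm", "gm")], y)
  expect_equal(unname(a_hat), unname(a_true), tolerance = 0.05)
})
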