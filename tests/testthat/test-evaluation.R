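# hand-computed two-way ANOVA oracle for the absolute-agreement ICC
icc_oracle <- function(x, y) {
  m <- cbind(x, y)
  n <- nrow(m); k <- 2
  gm <- mean(m)
  msr <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - gm)^2) / (k - 1)
  mse <- (sum((m - gm)^2) - k * sum((rowMeans(m) - gm)^2) -
            n * sum((colMeans(m) - gm)^2)) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

test_that("ICC matches a hand-computed 3x2 ANOVA table", {
  x <- c(2, 4, 6)
  y <- c(3, 5, 8)
  # mean squares by hand: grand mean 4.6667; row means 2.5, 4.5, 7;
  # column means 4, 5.3333
  expect_equal(icc_absolute_agreement(x, y), icc_oracle(x, y),
               tolerance = 1e-10)
  # against aov mean squares as an independent route
  d <- data.frame(v = c(x, y), subj = factor(rep(1:3, 2)),
                  visit = factor(rep(1:2, each = 3)))
  ms <- summary(stats::aov(v ~ subj + visit, data = d))[[1]][["Mean Sq"]]
  icc_aov <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 / 3 * (ms[2] - ms[3]))
  expect_equal(icc_absolute_agreement(x, y), icc_aov, tolerance = 1e-10)
})

test_that("ICC properties: identity, offset penalty, bounds", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(icc_absolute_agreement(x, x), 1, tolerance = 1e-12)
  # a large constant offset drives ICC well below the Pearson r
  y <- x + 10
  expect_lt(icc_absolute_agreement(x, y), 0.2)
  expect_equal(stats::cor(x, y), 1, tolerance = 1e-12)
  # equal means and variances: the consistency form of the ICC equals the
  # Pearson r exactly, and absolute agreement differs only by the
  # finite-n column-variance term
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 5) # same mean/variance as a
  m <- cbind(a, b)
  gm <- mean(m)
  msr <- 2 * sum((rowMeans(m) - gm)^2) / 4
  mse <- (sum((m - gm)^2) - 2 * sum((rowMeans(m) - gm)^2)) / 4
  expect_equal((msr - mse) / (msr + mse), stats::cor(a, b),
               tolerance = 1e-12)
  expect_equal(icc_absolute_agreement(a, b), stats::cor(a, b),
               tolerance = 0.05)
  set.seed(11)
  for (i in 1:20) {
    u <- rnorm(8); v <- rnorm(8)
    expect_lte(icc_absolute_agreement(u, v), 1)
  }
  expect_error(icc_absolute_agreement(c(1, 1, 1), c(1, 1, 1)), "variance")
})

test_that("bland_altman matches hand arithmetic", {
  z <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(z$mean_diff, 0)
  expect_equal(z$upper, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(z$lower, -1.96 * sqrt(2), tolerance = 1e-12)
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$upper, 0)
  # constant offset shifts the mean, not the width
  x <- c(1.5, 2.5, 4)
  b1 <- bland_altman(x, x + c(0.1, -0.2, 0.3))
  b2 <- bland_altman(x, x + c(0.1, -0.2, 0.3) + 5)
  expect_equal(b2$mean_diff - b1$mean_diff, 5, tolerance = 1e-12)
  expect_equal(b2$upper - b2$lower, b1$upper - b1$lower, tolerance = 1e-12)
})

test_that("age regression recovers an exact linear cohort and ignores row order", {
  coh <- data.frame(subject = 1:6, visit = 1L,
                    age = c(30, 40, 50, 60, 70, 80), region = "gm")
  coh$cbv <- 4.9 - 0.025 * coh$age
  fit <- age_regression(coh, "gm")
  expect_equal(fit$slope, -0.025, tolerance = 1e-12)
  expect_equal(fit$intercept, 4.9, tolerance = 1e-12)
  expect_equal(fit$r, -1, tolerance = 1e-12)
  perm <- coh[sample(nrow(coh)), ]
  fit2 <- age_regression(perm, "gm")
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-14)
  coh$age <- 50
  expect_error(age_regression(coh, "gm"), "degenerate")
})

test_that("age-slope recovery from the simulated cohort design", {
  # generator uses slope -0.025 (GM); with the design noise the fitted
  # slope distribution should centre on the truth
  slopes <- vapply(1:12, function(s) {
    coh <- simulate_cohort_table(n_subjects = 20, seed = s)
    age_regression(coh, "gm")$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-0.025)), 0.01)
  # correlation magnitude in the design ballpark (weak negative trend)
  coh <- simulate_cohort_table(n_subjects = 20, seed = 3)
  r <- age_regression(coh, "gm")$r
  expect_true(r < 0 && r > -0.9)
})

test_that("simulated cohort table respects the design invariants", {
  coh <- simulate_cohort_table(n_subjects = 20, seed = 2, drop_one = TRUE)
  # one measurement discarded: 2 regions x (2*20 - 1) rows
  expect_equal(nrow(coh), 2 * (2 * 20 - 1))
  expect_true(all(coh$age >= 25 & coh$age <= 84))
  # at most one row per (subject, visit, region)
  expect_false(any(duplicated(coh[c("subject", "visit", "region")])))
})
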