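#' Intraclass correlation, two-way random, single measure, absolute agreement
#'
#' ICC(A,1) from the standard two-way ANOVA mean-squares decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`, with rows =
#' subjects and columns = visits.  Absolute agreement penalizes systematic
#' offsets between visits, unlike the Pearson correlation.
#'
#' @param x,y paired measurements (visit 1, visit 2), equal length n >= 3.
#' @return ICC value (dimensionless, <= 1).
#' @export
icc_absolute_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  m <- cbind(x, y)
  k <- 2L
  gm <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  sst <- sum((m - gm)^2)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- sst - ssr - ssc
  if (sst < .Machine$double.eps) stop("zero total variance: ICC undefined")
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Bland-Altman limits of agreement
#'
#' @param x,y paired measurements.
#' @return list with `mean_diff`, `lower`, `upper`
#'   (mean difference +/- 1.96 sample SD of the differences) and the
#'   differences themselves.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  md <- mean(d)
  s <- sd(d)
  list(mean_diff = md, lower = md - 1.96 * s, upper = md + 1.96 * s,
       sd_diff = s, differences = d)
}

#' Ordinary least-squares regression of CBV on age
#'
#' @param cohort a cohort table (data.frame with columns subject, visit,
#'   age, region, cbv).
#' @param region which region to analyse.
#' @return list with slope (mL/100 g per year), intercept, r and n.
#' @export
age_regression <- function(cohort, region) {
  d <- cohort[cohort$region == region, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 observations")
  if (sd(d$age) < .Machine$double.eps^0.5)
    stop("degenerate ages: regression undefined")
  fit <- lm(cbv ~ age, data = d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = suppressWarnings(stats::cor(d$age, d$cbv)), n = nrow(d))
}

#' Simulate a cohort result table
#'
#' Emulates the test-retest study design: `n_subjects` volunteers with ages
#' uniform on [25, 84], two visits each, true regional CBV decreasing
#' linearly with age plus between-subject and between-visit variation, and
#' optionally one discarded measurement (as happens when header information
#' is lost for one scan).
#'
#' @param n_subjects number of volunteers.
#' @param regions region labels.
#' @param intercept,slope age model of true CBV per region (recycled).
#' @param between_sd between-subject SD (mL/100 g).
#' @param within_sd between-visit (measurement) SD.
#' @param drop_one discard one random measurement (n = 2*n_subjects - 1).
#' @param seed RNG seed.
#' @return data.frame with subject, visit, age, region, cbv.
#' @export
simulate_cohort_table <- function(n_subjects = 20L, regions = c("gm", "wm"),
                                  intercept = c(4.9, 5.6),
                                  slope = c(-0.025, -0.029),
                                  between_sd = 1.1, within_sd = 0.4,
                                  drop_one = TRUE, seed = 1L) {
  with_seed(seed, {
    ages <- runif(n_subjects, 25, 84)
    subj_dev <- rnorm(n_subjects, 0, between_sd)
    rows <- list()
    for (ri in seq_along(regions)) {
      mu <- intercept[(ri - 1) %% length(intercept) + 1] +
        slope[(ri - 1) %% length(slope) + 1] * ages + subj_dev
      for (v in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = seq_len(n_subjects), visit = v, age = ages,
          region = regions[ri],
          cbv = pmax(0.2, mu + rnorm(n_subjects, 0, within_sd)),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (drop_one) {
      drop_subj <- sample.int(n_subjects, 1)
      drop_visit <- sample(1:2, 1)
      out <- out[!(out$subject == drop_subj & out$visit == drop_visit), ]
    }
    rownames(out) <- NULL
    out
  })
}

#' Sweep the CSF reference thresholds on a synthetic test-retest cohort
#'
#' Re-runs reference selection, shifting and whole-brain CBV estimation for
#' every grid value of `thresh_range` and `thresh_tailpeak` (varied
#' separately, one at a time, the other held at its default), and reports
#' the test-retest ICC across subjects and the cohort-mean CBV.  The
#' expensive reconstruction (unwrap/background/inversion) is reused; only
#' the selection stage is recomputed, so each grid point equals an
#' independent single run with identical seeds.
#'
#' @param cohort a retest cohort from [simulate_retest_cohort()] (list of
#'   subjects, each with reconstructed `visit1`/`visit2` bundles).
#' @param range_grid grid of `thresh_range` values (percent).
#' @param tailpeak_grid grid of `thresh_tailpeak` values (percent).
#' @param windows a [steady_state_windows()].
#' @param physio a [physio_constants()].
#' @param region region whose CBV is tracked (default whole brain mask).
#' @return data.frame with parameter, value, icc, mean_cbv.
#' @export
threshold_sweep <- function(cohort, range_grid = c(5, 10, 25, 50, 100),
                            tailpeak_grid = c(0, 15, 30, 45),
                            windows = steady_state_windows(),
                            physio = physio_constants(),
                            region = "brain") {
  if (!is.null(cohort$subjects)) cohort <- cohort$subjects
  default_cfg <- reference_config()
  eval_point <- function(cfg) {
    per_visit <- vapply(cohort, function(subj) {
      vapply(list(subj$visit1, subj$visit2), function(rec) {
        tab <- quantify_cbv(rec, cfg, windows, physio,
                            regions = region)$cbv
        tab$cbv[tab$region == region]
      }, numeric(1))
    }, numeric(2))
    v1 <- per_visit[1, ]; v2 <- per_visit[2, ]
    c(icc = icc_absolute_agreement(v1, v2), mean_cbv = mean(c(v1, v2)))
  }
  rows <- list()
  for (v in range_grid) {
    cfg <- reference_config(thresh_range = v,
                            thresh_tailpeak = default_cfg$thresh_tailpeak)
    r <- eval_point(cfg)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "thresh_range",
                                            value = v, icc = r["icc"],
                                            mean_cbv = r["mean_cbv"])
  }
  for (v in tailpeak_grid) {
    cfg <- reference_config(thresh_range = default_cfg$thresh_range,
                            thresh_tailpeak = v)
    r <- eval_point(cfg)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "thresh_tailpeak",
                                            value = v, icc = r["icc"],
                                            mean_cbv = r["mean_cbv"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the inversion regularization parameter lambda
#'
#' For each lambda, both steady-state window-mean local fields (baseline
#' and tail) are inverted with the regularized method and the GM-minus-WM
#' CBV difference is computed.  The difference (rather than the ratio) is
#' reported because it does not depend on the CSF reference shift.
#'
#' @param recon a reconstructed bundle from [reconstruct_series()].
#' @param lambda_grid lambda values.
#' @param cfg base [inversion_config()]; must have `method = "medi_like"`
#'   (lambda is undefined for thresholded k-space division).
#' @param ref_cfg a [reference_config()] for the CSF reference used in the
#'   blood measurement.
#' @param windows a [steady_state_windows()].
#' @param physio a [physio_constants()].
#' @return data.frame with lambda and cbv_gm_minus_wm (mL/100 g).
#' @export
lambda_sweep <- function(recon, lambda_grid = c(100, 300, 1000, 3000, 5000),
                         cfg = inversion_config(method = "medi_like"),
                         ref_cfg = reference_config(),
                         windows = steady_state_windows(),
                         physio = physio_constants()) {
  if (cfg$method != "medi_like")
    stop("lambda is undefined for the tkd method; use method = 'medi_like'")
  loc <- recon$local_field
  nt <- n_frames(loc$values)
  idx <- window_indices(windows, nt)
  f_pre <- apply(loc$values[, , , idx$pre, drop = FALSE], 1:3, mean)
  f_post <- apply(loc$values[, , , idx$post, drop = FALSE], 1:3, mean)
  two <- array(c(f_pre, f_post), c(dim(f_pre), 2L))
  fs <- field_series(two, loc$mask, stage = "background-removed",
                     unit = "ppm", params = loc$params)
  blood <- quantify_cbv(recon, ref_cfg, windows, physio)$blood
  rows <- lapply(lambda_grid, function(lam) {
    cfg_l <- cfg
    cfg_l$lam <- lam
    chi2 <- invert_dipole(fs, recon$magnitude_ref, recon$masks$brain, cfg_l)
    dgm <- mean(chi2$chi[, , , 2][recon$masks$gm]) -
      mean(chi2$chi[, , , 1][recon$masks$gm])
    dwm <- mean(chi2$chi[, , , 2][recon$masks$wm]) -
      mean(chi2$chi[, , , 1][recon$masks$wm])
    cbv_g <- cbv_qsm(dgm, blood$delta_chi, physio, "gm")$cbv
    cbv_w <- cbv_qsm(dwm, blood$delta_chi, physio, "wm")$cbv
    data.frame(lambda = lam, cbv_gm_minus_wm = cbv_g - cbv_w)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
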