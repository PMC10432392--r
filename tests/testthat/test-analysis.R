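test_that("ROI time courses are mask means with the expected algebra", {
  ph <- fix_phantom(field = FALSE)
  vols <- array(3, dim = c(48, 36, 5))
  ds <- structure(list(volumes = vols, volume_interval_s = 2,
                       paradigm = fix_paradigm(), phantom = ph),
                  class = "timeseries_dataset")
  ob <- ph$masks$ob_left | ph$masks$ob_right
  expect_equal(roi_timecourse(ds, ob), rep(3, 5))
  # single-pixel mask returns that pixel's trace
  one <- matrix(FALSE, 48, 36); one[24, 18] <- TRUE
  ds$volumes[24, 18, ] <- 1:5
  expect_equal(roi_timecourse(ds, one), as.numeric(1:5))
  # combined-mask series is the size-weighted average of hemisphere series
  set.seed(1); ds$volumes[] <- stats::rnorm(length(ds$volumes))
  l <- roi_timecourse(ds, ph$masks$ob_left)
  r <- roi_timecourse(ds, ph$masks$ob_right)
  b <- roi_timecourse(ds, ob)
  nl <- sum(ph$masks$ob_left); nr <- sum(ph$masks$ob_right)
  expect_equal(b, (nl * l + nr * r) / (nl + nr))
  expect_error(roi_timecourse(ds, matrix(FALSE, 48, 36)), "empty")
})

test_that("percent change is zero on flat series and recovers a known response", {
  par <- fix_paradigm()
  flat <- rep(100, par$n_volumes)
  expect_equal(percent_change(flat, par)$peak_pct, 0)

  # closed-form construction: baseline 100 with a 5% HRF-convolved block
  reg <- task_regressor(par)
  series <- 100 * (1 + 0.05 * reg)
  pc <- percent_change(series, par)
  expect_gt(pc$peak_pct, 4.5); expect_lt(pc$peak_pct, 5.5)
})

test_that("pure linear drift cancels in the epoch average", {
  par <- build_paradigm(air_s = 40, odor_s = 20, n_events = 10,
                        volume_interval_s = 2, n_volumes = 300)
  tt <- par$volume_times_s
  drift <- 100 * (1 + 0.02 * (tt / max(tt) - 0.5))   # 2% over the run
  pc <- percent_change(drift, par)
  expect_lt(abs(pc$peak_pct), 0.5)
})

test_that("Gaussian smoothing has the requested FWHM and conserves mass", {
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  pm <- c(0.1, 0.1)
  expect_identical(smooth_gaussian(img, 0, pm), img)
  sm <- smooth_gaussian(img, 0.5, pm)
  # fit the measured FWHM of the impulse response along each axis
  prof <- sm[, 21] / max(sm[, 21])
  above <- which(prof >= 0.5)
  fwhm_px <- max(above) - min(above) + 1 -
    2 * (0.5 - (0.5 - prof[min(above) - 1]) /
           (prof[min(above)] - prof[min(above) - 1]))
  expect_lt(abs(fwhm_px - 5), 0.5)            # 0.5 mm / 0.1 mm = 5 px
  expect_equal(sum(sm), sum(img), tolerance = 1e-3)
  expect_error(smooth_gaussian(img, -1, pm), "nonnegative")
  expect_warning(smooth_gaussian(img, 2.5, pm), "25%")
})

test_that("design matrix has the documented structure and full rank", {
  par <- fix_paradigm()
  X <- design_matrix(par)
  expect_true(all(c("intercept", "task", "task_t", "task_t2") %in%
                    colnames(X$X)))
  expect_true(any(grepl("^drift", colnames(X$X))))
  expect_equal(max(X$X[, "task"]), 1)
  expect_equal(qr(X$X)$rank, ncol(X$X))
  # modulation columns are centered relative to the task epochs
  expect_lt(abs(mean(X$X[, "task_t"])), 0.1 * max(abs(X$X[, "task_t"])))
})

test_that("first-level GLM controls the type-I error at nominal alpha", {
  par <- build_paradigm(air_s = 40, odor_s = 20, n_events = 2,
                        volume_interval_s = 2, n_volumes = 120)
  X <- design_matrix(par)
  set.seed(11)
  vols <- array(stats::rnorm(100 * 100 * 120), dim = c(100, 100, 120))
  map <- glm_first_level(vols, X, p_threshold = 0.001)
  n <- length(map$stat)
  expect_gte(n, 1e4)
  hits <- sum(map$mask_supra)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.001)
  expect_gte(hits, ci[1]); expect_lte(hits, ci[2])
  # and at alpha = 0.05
  m2 <- threshold_map(map, 0.05)
  ci2 <- stats::qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(sum(m2$mask_supra), ci2[1])
  expect_lte(sum(m2$mask_supra), ci2[2])
})

test_that("first-level GLM recovers an injected activation mask", {
  ph <- fix_phantom(texture = 0)
  par <- fix_paradigm()
  p <- fix_params("PR_SPEN", noise_sigma = fix_sigma30())
  bm <- bold_model("neutral", concentration_ppm = 450)
  ds <- simulate_run(ph, p, par, bm, seed = 21)
  X <- design_matrix(par)
  map <- glm_first_level(smooth_gaussian(ds, 0.4), X, p_threshold = 0.001)
  expect_gte(dice_coef(map$mask_supra, active_roi(ph, bm)), 0.6)
})

test_that("zero-residual pixels give a flagged infinite t, not a crash", {
  par <- build_paradigm(air_s = 40, odor_s = 20, n_events = 2,
                        volume_interval_s = 2, n_volumes = 120)
  X <- design_matrix(par)
  vols <- array(rep(X$X[, "task"], each = 16), dim = c(4, 4, 120))
  map <- glm_first_level(vols, X)
  expect_true(all(is.infinite(map$stat)))
  expect_true(all(map$degenerate))
  expect_true(all(map$mask_supra))
})

test_that("contrast and dimension errors are reported", {
  par <- fix_paradigm()
  X <- design_matrix(par)
  vols <- array(1, dim = c(4, 4, 10))
  expect_error(glm_first_level(vols, X), "design matrix rows")
  vols2 <- array(stats::rnorm(4 * 4 * par$n_volumes),
                 dim = c(4, 4, par$n_volumes))
  expect_error(glm_first_level(vols2, X, contrast = c(1, 0)),
               "contrast length")
})
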