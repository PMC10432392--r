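test_that("default block paradigm reproduces the protocol arithmetic", {
  par <- build_paradigm()
  expect_equal(par$n_events * par$odor_s, 260)          # total odor-on time
  expect_equal(par$onsets_s[1] / par$volume_interval_s, 60)
  run_s <- par$n_volumes * par$volume_interval_s
  expect_equal(run_s, 1400)                             # ~23 min
  expect_equal(round(run_s / 60), 23)
  expect_error(build_paradigm(n_volumes = 10), "too small")
})

test_that("single immediate block: boxcar mass equals odor_s/volume_interval", {
  par <- build_paradigm(air_s = 0, odor_s = 26, n_events = 1,
                        volume_interval_s = 2, n_volumes = 30,
                        onset_ramp_s = 0)
  expect_equal(sum(stimulus_waveform(par)), 26 / 2)
})

test_that("canonical HRF has the double-gamma shape", {
  expect_equal(hrf(0), 0)
  t <- seq(0, 40, by = 0.01)
  h <- hrf(t)
  expect_gt(sum(h) * 0.01, 0)                 # positive integral
  expect_equal(sum(diff(sign(h[h != 0])) != 0), 1)   # one sign change
  pk <- t[which.max(h)]
  expect_gt(pk, 3); expect_lt(pk, 8)
  expect_error(hrf(-1), "t_s >= 0")
  expect_error(hrf(1, list(a1 = -6, a2 = 16, b = 1, ratio = 6)), "invalid")
  # response to a 26 s block peaks after onset and before the undershoot end
  par <- build_paradigm(air_s = 60, odor_s = 26, n_events = 1,
                        volume_interval_s = 1, n_volumes = 150,
                        onset_ramp_s = 0)
  reg <- task_regressor(par)
  t_peak <- par$volume_times_s[which.max(reg)] - 60
  expect_gt(t_peak, 0); expect_lt(t_peak, 26 + 30)
})

test_that("concentration response is a saturating Hill function", {
  expect_equal(concentration_amplitude(0), 0)
  expect_equal(concentration_amplitude(60), 0.5)       # c = c50 -> max/2
  grid <- c(60, 300, 500, 700)
  v <- concentration_amplitude(grid)
  expect_true(all(diff(v) > 0))                        # nondecreasing
  expect_lt(v[4] / v[2], 1.25)                         # saturated regime
  expect_error(concentration_amplitude(-5), ">= 0")
})

test_that("nostril occlusion lateralizes the activation model", {
  bm <- bold_model("neutral")
  ph <- fix_phantom(field = FALSE)
  left_plug <- nostril_scenario(bm, "left")
  expect_equal(left_plug$lateralization, "right_only")
  roi <- active_roi(ph, left_plug)
  expect_false(any(roi & ph$masks$ob_left))
  expect_true(any(roi & ph$masks$ob_right))
  expect_identical(nostril_scenario(bm, "none"), bm)
  expect_error(nostril_scenario(left_plug, "right"), "contradictory")
})

test_that("BOLD contrast ordering: GE-EPI >= PR-SPEN >= FR-SPEN", {
  ph <- fix_phantom(texture = 0)
  par <- fix_paradigm(n_events = 2L, n_volumes = 80L)
  bm <- bold_model("neutral", concentration_ppm = 450)
  act <- active_roi(ph, bm)
  peak <- sapply(c("GE_EPI", "PR_SPEN", "FR_SPEN"), function(kind) {
    ds <- simulate_run(ph, fix_params(kind), par, bm,
                       nuisance = nuisance_defaults(0, 0, 0), seed = 1)
    percent_change(roi_timecourse(ds, act), par)$peak_pct
  })
  expect_gte(peak[["GE_EPI"]], peak[["PR_SPEN"]])
  expect_gte(peak[["PR_SPEN"]], peak[["FR_SPEN"]])
  expect_gt(peak[["FR_SPEN"]], 0)
})

test_that("an injected 5% change is recovered by the run's own readout", {
  # choose Delta-R2* so the instantaneous peak signal change is exactly 5%
  ph <- fix_phantom(field = FALSE, texture = 0)
  par <- fix_paradigm()
  g <- concentration_amplitude(450)
  p <- fix_params("PR_SPEN")
  dr2 <- log(1.05) / (g * (p$te_s * 0.4 + p$delta_s * 0.6))
  bm <- bold_model("neutral", delta_r2star_hz = dr2,
                   concentration_ppm = 450)
  ds <- simulate_run(ph, p, par, bm,
                     nuisance = nuisance_defaults(0, 0, 0), seed = 1)
  pc <- percent_change(roi_timecourse(ds, active_roi(ph, bm)), par)
  expect_equal(pc$peak_pct, 5, tolerance = 0.2 / 5)
})

test_that("zero activation produces a null epoch response", {
  ph <- fix_phantom(texture = 0)
  par <- fix_paradigm()
  bm <- bold_model("neutral", delta_r2star_hz = 0, concentration_ppm = 450)
  p <- fix_params("PR_SPEN", noise_sigma = fix_sigma30())
  ds <- simulate_run(ph, p, par, bm, seed = 3)
  act <- ph$masks$epl | ph$masks$glomerular_lateral
  pc <- percent_change(roi_timecourse(ds, act), par)
  # epoch-averaged response statistically indistinguishable from zero
  expect_lt(abs(pc$peak_pct), 0.5)
})

test_that("measured response is monotone and saturating in concentration", {
  ph <- fix_phantom(texture = 0)
  par <- fix_paradigm()
  p <- fix_params("PR_SPEN", noise_sigma = fix_sigma30())
  bm0 <- bold_model("neutral")
  act <- active_roi(ph, bm0)
  peaks <- sapply(c(60, 300, 500, 700), function(cc) {
    bm <- bold_model("neutral", concentration_ppm = cc)
    ds <- simulate_run(ph, p, par, bm, seed = 7)
    percent_change(roi_timecourse(ds, act), par)$peak_pct
  })
  expect_true(all(diff(peaks) > -0.1))        # nondecreasing up to noise
  expect_lt(peaks[4] - peaks[2], peaks[1])    # 300->700 gain < 0->60 gain
})

test_that("whole runs are reproducible from their seed", {
  ph <- fix_phantom()
  par <- fix_paradigm(n_events = 2L, n_volumes = 80L)
  p <- fix_params("PR_SPEN", noise_sigma = 0.1)
  a <- simulate_run(ph, p, par, bold_model(), seed = 9)
  b <- simulate_run(ph, p, par, bold_model(), seed = 9)
  expect_identical(a$volumes, b$volumes)
  c <- simulate_run(ph, p, par, bold_model(), seed = 10)
  expect_false(identical(a$volumes, c$volumes))
})
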