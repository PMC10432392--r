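test_that("noiseless EPI sampling equals the 2D DFT of the object", {
  ph <- fix_nodecay()
  p <- fix_params("SE_EPI", n_averages = 1L)
  raw <- acquire(ph, p)

  # independent oracle: direct double sum with the package's stated
  # conventions (pixel centers at ((i+0.5)-N/2)*delta, exp(-i k y) forward)
  d <- dim(ph$pd_map)
  y <- (seq_len(d[2]) - 0.5 - d[2] / 2) * ph$pixel_mm[2]
  k <- 2 * pi * (seq_len(d[2]) - 1 - d[2] / 2) / (d[2] * ph$pixel_mm[2])
  Ey <- exp(-1i * outer(y, k)) * ph$pixel_mm[2]
  Sy <- ph$pd_map %*% Ey                        # y-encoded, x still spatial
  oracle <- stats::mvfft(Sy)                    # Fourier along readout
  expect_lt(max(Mod(raw$samples - oracle)) / max(Mod(oracle)), 1e-6)
})

test_that("zero-PD phantom yields pure noise with the stated variance", {
  ph <- fix_phantom(field = FALSE)
  ph$pd_map[] <- 0
  p <- fix_params("SE_EPI", noise_sigma = 0.5, n_averages = 2L)
  raw <- acquire(ph, p, seed = 3)
  re <- Re(raw$samples); im <- Im(raw$samples)
  expect_lt(abs(mean(re)), 0.05)
  # coherent averaging sums n_averages noise draws: variance n_avg * sigma^2
  expect_equal(stats::var(as.vector(re)), 2 * 0.25, tolerance = 0.1)
  expect_equal(stats::var(as.vector(im)), 2 * 0.25, tolerance = 0.1)
})

test_that("noiseless acquisition is linear in the object", {
  ph1 <- fix_nodecay()
  ph2 <- ph1
  set.seed(42)
  ph2$pd_map <- matrix(stats::runif(prod(dim(ph1$pd_map))), nrow(ph1$pd_map))
  p <- fix_params("FR_SPEN")
  ra <- acquire(ph1, p)$samples
  rb <- acquire(ph2, p)$samples
  ph3 <- ph1
  ph3$pd_map <- 2 * ph1$pd_map + 0.5 * ph2$pd_map
  rc <- acquire(ph3, p)$samples
  expect_lt(max(Mod(rc - 2 * ra - 0.5 * rb)) / max(Mod(rc)), 1e-10)
})

test_that("acquisition is deterministic per seed", {
  ph <- fix_phantom()
  p <- fix_params("PR_SPEN", noise_sigma = 0.2)
  expect_identical(acquire(ph, p, seed = 5)$samples,
                   acquire(ph, p, seed = 5)$samples)
  expect_false(identical(acquire(ph, p, seed = 5)$samples,
                         acquire(ph, p, seed = 6)$samples))
})

test_that("noiseless EPI sample energy satisfies Parseval's relation", {
  ph <- fix_phantom(field = FALSE, texture = 0)
  p <- fix_params("SE_EPI", n_averages = 1L)
  raw <- acquire(ph, p)
  # decayed object as encoded (T2 decay at each sample time is position
  # independent only through tau; use the echo-time decayed object and a
  # generous tolerance for the decay variation across the echo train)
  op_energy <- sum(Mod(raw$samples)^2)
  d <- dim(ph$pd_map)
  rho <- fix_truth(ph, p$te_s)
  expected <- d[1] * d[2] * ph$pixel_mm[2]^2 * sum(rho^2)
  expect_equal(op_energy, expected, tolerance = 0.05)
})

test_that("full refocusing makes the image magnitude insensitive to a uniform field", {
  ph0 <- fix_nodecay()
  p <- fix_params("FR_SPEN")
  m0 <- recon_spen_magnitude(acquire(ph0, p))
  ph1 <- ph0; ph1$b0_map[] <- 100
  m1 <- recon_spen_magnitude(acquire(ph1, p))
  ob <- ph0$masks$ob_left | ph0$masks$ob_right
  # no attenuation/broadening: the OB-mean magnitude moves by far less
  # than the off-resonance would attenuate an unrefocused acquisition
  expect_lt(abs(mean(m1[ob]) - mean(m0[ob])) / mean(m0[ob]), 0.02)
  # the residual displacement is the EPI shift reduced by the chirp factor
  shift_spen <- abs(centroid_shift(m1, m0, ph0$pixel_mm)[2]) / ph0$pixel_mm[2]
  expect_lt(shift_spen, 1.2 * 100 * p$tacq_s / p$chirp_factor)
  e <- fix_params("SE_EPI")
  i0 <- recon_epi(acquire(ph0, e)); i1 <- recon_epi(acquire(ph1, e))
  shift_epi <- abs(centroid_shift(i1, i0, ph0$pixel_mm)[2]) / ph0$pixel_mm[2]
  expect_lt(shift_spen, shift_epi / 2)
})

test_that("noise calibration reaches the target SNR and scales as 1/sigma", {
  ph <- fix_phantom()
  p <- fix_params("FR_SPEN")
  sig <- calibrate_noise(ph, p, target_snr = 30, n_trials = 6, seed = 1)
  # SNR ~ 1/sigma: doubling the target halves the noise level (checked on
  # the clean-field phantom, far from the reconstruction leakage floor)
  ph0 <- fix_phantom(field = FALSE)
  sA <- calibrate_noise(ph0, p, target_snr = 30, n_trials = 6, seed = 1)
  sB <- calibrate_noise(ph0, p, target_snr = 60, n_trials = 6, seed = 1)
  expect_equal(as.numeric(sB) / as.numeric(sA), 0.5, tolerance = 0.1)
  # verify on independent noise realizations
  p$noise_sigma <- as.numeric(sig)
  A <- encoding_matrix(p)
  ob <- ph$masks$ob_left | ph$masks$ob_right
  snrs <- vapply(1:20, function(s)
    snr(recon_spen_sr(acquire(ph, p, seed = 200 + s), A, 1e-3),
        ob, ph$masks$noise_roi), numeric(1))
  expect_gt(mean(snrs), 27); expect_lt(mean(snrs), 33)
  # zero noise: SNR is reported as the sentinel Inf on a flat background
  flat <- matrix(1, 10, 10); flat[6:10, ] <- 2
  sm <- matrix(FALSE, 10, 10); sm[6:10, ] <- TRUE
  expect_identical(snr(flat, sm, !sm), Inf)
})
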