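# Shared fixtures: small phantoms and sequence settings used across tests.
# Grids are reduced (48 x 36 or 32 x 24) relative to the nominal 96 x 70
# acquisition matrix to keep the suite fast; the geometry (10.4 x 7.5 mm
# FOV) and timing parameters are the nominal ones.

pm48 <- c(10.4 / 48, 7.5 / 36)

fix_phantom <- function(field = TRUE, texture = 0.02) {
  ph <- make_ob_phantom(48, 36, pixel_mm = pm48, texture_sd = texture)
  if (field) ph <- default_field(ph)
  ph
}

# relaxation switched off: pure encoding tests
fix_nodecay <- function(ph = fix_phantom(field = FALSE, texture = 0)) {
  ph$t2_map[] <- 1e9
  ph$t2prime_map[] <- 1e9
  ph
}

fix_params <- function(kind, nx = 48L, ny = 36L,
                       delta_s = if (kind == "PR_SPEN") 0.004 else 0, ...) {
  seq_params(kind, fov_mm = c(10.4, 7.5), matrix_size = c(nx, ny),
             delta_s = delta_s, ...)
}

fix_paradigm <- function(n_events = 5L, n_volumes = 190L)
  build_paradigm(air_s = 50, odor_s = 26, n_events = n_events,
                 volume_interval_s = 2, n_volumes = n_volumes)

# raw-noise level giving image SNR ~30 on the 48 x 36 default-field phantom
# (computed once per test run via the calibration routine)
sigma30_cache <- new.env()
fix_sigma30 <- function() {
  if (is.null(sigma30_cache$value)) {
    sigma30_cache$value <- as.numeric(
      calibrate_noise(fix_phantom(), fix_params("FR_SPEN"),
                      target_snr = 30, n_trials = 6, seed = 1))
  }
  sigma30_cache$value
}

# decayed ground truth at the echo time, the reference for distortion metrics
fix_truth <- function(ph, te_s = 0.026) ph$pd_map * exp(-te_s * 1000 / ph$t2_map)

expect_rel_rms <- function(x, ref, tol) {
  expect_lt(sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2)), tol)
}
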