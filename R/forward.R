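# Forward simulation: single-shot raw data from a phantom under a sequence.
#
# The readout (x) axis is an ideal Fourier axis; every inhomogeneity effect
# acts along the low-bandwidth (y) axis. For each low-bandwidth sample m the
# noiseless signal from readout position x is
#   s(x, t_m) = sum_n rho(x, y_n) * exp(i[phi_e(y_n) + k(t_m) y_n])
#               * exp(i 2 pi Df(x, y_n) tau(y_n, t_m))
#               * exp(-Tel(y_n, t_m)/T2(x, y_n))
#               * exp(-|tau(y_n, t_m)|/T2'(x, y_n)) * dy
# and the stored raw samples are the FFT of s over x. phi_e is the SPEN
# quadratic phase (absent for EPI, where k alone encodes y).

#' Encoding phase profile along the low-bandwidth axis
#'
#' Complex encoding factors `exp(i[phi_e(y) + k(t_m) y]) * dy` evaluated at
#' arbitrary object positions `y_mm` for every sample of the timing table.
#' For EPI variants `phi_e = 0` and `k(t_m)` are the usual Fourier moments
#' `2*pi*(m - 1 - Ny/2)/Ly`.
#'
#' @param timing A `timing_table`.
#' @param y_mm Object positions (mm).
#' @param dy_mm Object pixel height (mm), the integration measure.
#' @return Complex matrix (length(y_mm) x n samples).
#' @keywords internal
encoding_profile <- function(timing, y_mm, dy_mm) {
  p <- timing$params
  m <- nrow(timing$samples)
  if (is_spen(p)) {
    qc <- quadratic_phase_coeffs(p)
    k_m <- qc$k_rate * timing$samples$t_s
    phase <- outer(y_mm, k_m) + (qc$alpha * y_mm^2 + qc$beta * y_mm)
    # finite-voxel integration: first-order phase across a voxel of height dy
    # gives a sinc envelope sin(u)/u, u = phi'(y) dy / 2. This is what
    # localizes the SPEN signal around the stationary point y*(t).
    u <- (outer(y_mm, k_m, function(y, k) 2 * qc$alpha * y + qc$beta + k)) *
      dy_mm / 2
    env <- ifelse(abs(u) < 1e-8, 1, sin(u) / ifelse(u == 0, 1, u))
    exp(1i * phase) * env * dy_mm
  } else {
    Ly <- p$fov_mm[2]
    k_m <- 2 * pi * (seq_len(m) - 1 - m / 2) / Ly
    phase <- outer(y_mm, -k_m)   # exp(-i k y): forward Fourier convention
    exp(1i * phase) * dy_mm
  }
}

# Precompute everything static about (phantom, sequence): the complex static
# signal cube S[x, y, m] (encoding x off-resonance x baseline decay x PD) and
# the per-(y, m) evolution-time matrices used to modulate decay dynamically.
forward_operator <- function(phantom, params, timing = NULL) {
  validate_phantom(phantom); validate_seq_params(params)
  if (is.null(timing)) timing <- build_timing(params)
  d <- phantom_dim(phantom)
  nx <- d[1]; ny <- d[2]
  if (nx != params$matrix_size[1])
    stop("phantom x-dimension (", nx, ") must match the sequence matrix (",
         params$matrix_size[1], ")")
  y_obj <- pixel_coords(ny, phantom$pixel_mm[2])
  dy <- phantom$pixel_mm[2]
  p <- params
  nm <- nrow(timing$samples)

  E <- encoding_profile(timing, y_obj, dy)              # ny x nm
  # evolution times at the *object* positions (timing positions are the
  # reconstruction grid; extrapolate the stationary-time map linearly)
  if (is_spen(p)) {
    t_star <- p$tacq_s * ((y_obj - p$zoom_center_mm) / p$fov_mm[2] + 0.5)
    tau <- outer(p$delta_s - t_star, timing$samples$t_s, `+`)
    tel <- outer(p$te_s - t_star, timing$samples$t_s, `+`)
  } else {
    tau0 <- if (p$kind == "GE_EPI") 0 else p$te_s
    tau <- matrix(timing$samples$t_s - tau0, ny, nm, byrow = TRUE)
    tel <- matrix(timing$samples$t_s, ny, nm, byrow = TRUE)
  }

  r2 <- 1000 / phantom$t2_map            # 1/s (maps are ms)
  r2p <- 1000 / phantom$t2prime_map
  b0 <- phantom$b0_map

  static <- array(0i, dim = c(nx, ny, nm))
  for (m in seq_len(nm)) {
    ph <- b0 * rep(2 * pi * tau[, m], each = nx)        # column-wise broadcast
    dec <- r2 * rep(tel[, m], each = nx) + r2p * rep(abs(tau[, m]), each = nx)
    w <- phantom$pd_map * exp(1i * ph - dec)
    static[, , m] <- w * rep(E[, m], each = nx)
  }
  list(static = static, tau = tau, tel = tel, timing = timing,
       params = params, dims = c(nx = nx, ny = ny, nm = nm))
}

# Noiseless signal s[x, m] given an optional dynamic decay exponent cube
# B[x, y, m] scaled by g (signal = sum_y static * exp(-g * B)).
forward_signal <- function(op, B = NULL, g = 0) {
  A <- op$static
  if (!is.null(B) && g != 0) A <- A * exp(-g * B)
  colSums(aperm(A, c(2L, 1L, 3L)))     # sum over y -> [x, m]
}

#' Simulate single-shot raw data
#'
#' Runs the forward model for one image: encodes the phantom along the
#' low-bandwidth axis according to the sequence (quadratic phase + gradient
#' moment for SPEN, Fourier moments for EPI), applies per-pixel off-resonance
#' evolution, T2 and T2' decay, Fourier-encodes the readout axis, sums
#' `n_averages` coherent averages, and adds i.i.d. complex Gaussian noise of
#' standard deviation `noise_sigma` per sample per average.
#'
#' @param phantom An `ob_phantom` whose x-dimension matches the sequence
#'   matrix.
#' @param params A `seq_params`.
#' @param timing Optional precomputed `timing_table` (built from `params` if
#'   omitted).
#' @param seed Integer seed for the noise.
#' @return A `"raw_data"` object: list with complex matrix `samples`
#'   (readout index x low-bandwidth sample index), `params`, `timing`,
#'   `seed`.
#' @examples
#' ph <- make_ob_phantom(32, 24, pixel_mm = c(0.3, 0.3))
#' rd <- acquire(ph, seq_params("FR_SPEN", matrix_size = c(32L, 24L),
#'                              fov_mm = c(9.6, 7.2)))
#' dim(rd$samples)
#' @export
acquire <- function(phantom, params, timing = NULL, seed = 1L) {
  op <- forward_operator(phantom, params, timing)
  s <- forward_signal(op)
  raw_from_signal(s, op, seed)
}

# shared tail of acquire()/simulate_run(): x-FFT, averaging, noise
raw_from_signal <- function(s, op, seed, rng_ready = FALSE) {
  p <- op$params
  raw <- stats::mvfft(s) * p$n_averages
  if (p$noise_sigma > 0) {
    if (!rng_ready) set.seed(as.integer(seed))
    n <- length(raw)
    eps <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
    raw <- raw + p$noise_sigma * sqrt(p$n_averages) * matrix(eps, nrow(raw))
  }
  structure(list(samples = raw, params = p, timing = op$timing,
                 seed = as.integer(seed)),
            class = "raw_data")
}

#' @export
print.raw_data <- function(x, ...) {
  cat(sprintf("<raw_data> %s, %d x %d complex samples, sigma = %g\n",
              x$params$kind, nrow(x$samples), ncol(x$samples),
              x$params$noise_sigma))
  invisible(x)
}

#' Calibrate the raw-sample noise level to a target image SNR
#'
#' Finds the complex-noise standard deviation such that the reconstructed
#' image SNR (mean over the OB mask divided by the standard deviation over
#' the background noise ROI) averaged over `n_trials` noise realizations
#' matches `target_snr`. Uses the proportionality SNR ~ 1/sigma with two
#' fixed-point refinements.
#'
#' @param phantom An `ob_phantom` (its `ob_left`/`ob_right`/`noise_roi` masks
#'   are used).
#' @param params A `seq_params`; its `noise_sigma` field is ignored.
#' @param target_snr Desired image-domain SNR (> 0).
#' @param n_trials Number of noise realizations averaged per evaluation.
#' @param seed Integer seed.
#' @param lambda Regularization used for the SPEN super-resolution
#'   reconstruction during calibration.
#' @return The calibrated `noise_sigma` (scalar), with attribute
#'   `"achieved_snr"`.
#' @export
calibrate_noise <- function(phantom, params, target_snr = 30,
                            n_trials = 10L, seed = 1L, lambda = NULL) {
  if (!is.finite(target_snr) || target_snr <= 0)
    stop("target_snr must be positive")
  params$noise_sigma <- 0              # calibration ignores the stored level
  op <- forward_operator(phantom, params)
  s0 <- forward_signal(op)
  ob <- phantom$masks$ob_left | phantom$masks$ob_right
  A <- if (is_spen(params)) encoding_matrix(params, op$timing) else NULL

  recon_img <- function(raw) {
    if (is_spen(params)) {
      recon_spen_sr(raw, A, lambda = if (is.null(lambda)) 1e-3 else lambda)
    } else recon_epi(raw)
  }
  # mean image SNR over n_trials; common random numbers across sigma values
  # make the function smooth and strictly decreasing in sigma, so a plain
  # bisection converges
  measure <- function(sigma, seed0) {
    mean(vapply(seq_len(n_trials), function(i) {
      opi <- op; opi$params$noise_sigma <- sigma
      img <- recon_img(raw_from_signal(s0, opi, seed0 + i))
      snr(img, ob, phantom$masks$noise_roi)
    }, numeric(1)))
  }
  seed0 <- as.integer(seed) + 1000L
  img0 <- recon_img(raw_from_signal(s0, op, seed))
  floor_snr <- snr(img0, ob, phantom$masks$noise_roi)
  if (is.finite(floor_snr) && floor_snr <= target_snr)
    stop("noise calibration infeasible: reconstruction leakage floor alone ",
         "limits SNR to ", signif(floor_snr, 4), " <= target ", target_snr)
  lo <- 0
  hi <- mean(img0[ob]) / target_snr * 0.02
  it <- 0
  while (measure(hi, seed0) > target_snr) {
    hi <- hi * 2; it <- it + 1
    if (it > 40) stop("noise calibration failed to bracket the target SNR")
  }
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (measure(mid, seed0) > target_snr) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-4 * hi) break
  }
  sigma <- (lo + hi) / 2
  achieved <- measure(sigma, as.integer(seed) + 5000L)   # fresh realizations
  structure(sigma, achieved_snr = achieved)
}
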