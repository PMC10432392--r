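SEQ_KINDS <- c("GE_EPI", "SE_EPI", "FR_SPEN", "PR_SPEN")

#' Acquisition parameters for single-shot sequences
#'
#' Container and validator for the four single-shot variants simulated by the
#' package: gradient-echo EPI, spin-echo EPI, and fully- (FR) or partially-
#' refocused (PR) spatiotemporally encoded (SPEN) acquisitions.
#'
#' Full refocusing ties the echo time to the acquisition time
#' (`te_s == tacq_s`) and unwinds each position's off-resonance/T2* phase at
#' the moment that position is acquired; partial refocusing leaves a uniform
#' residual T2* evolution time `delta_s` per voxel, restoring BOLD
#' sensitivity.
#'
#' @param kind One of `"GE_EPI"`, `"SE_EPI"`, `"FR_SPEN"`, `"PR_SPEN"`.
#' @param fov_mm Length-2 field of view (Lx, Ly) in mm.
#' @param matrix_size Length-2 integer (Nx, Ny): readout and low-bandwidth
#'   matrix.
#' @param tr_s Repetition time (s).
#' @param te_s Echo time (s). For FR SPEN this must equal `tacq_s`.
#' @param tacq_s Acquisition duration along the low-bandwidth axis (s); the
#'   EPI bandwidth per pixel along that axis is `1/tacq_s`.
#' @param chirp_duration_s Duration of the encoding chirp pulse (SPEN only,
#'   used for timing feasibility).
#' @param delta_s Residual T2* weighting delay Delta (s); must be 0 for
#'   FR SPEN and > 0 for PR SPEN.
#' @param chirp_factor Encoding time-bandwidth product expressed as a
#'   multiple of the matrix size (SPEN only). Larger values increase the
#'   quadratic-phase strength and proportionally reduce the residual
#'   off-resonance displacement relative to EPI.
#' @param n_averages Number of coherently summed averages (>= 1).
#' @param noise_sigma Complex-noise standard deviation per sample per average
#'   (raw-sample units).
#' @param zoom_center_mm Center of the SPEN zoom window along y (mm); with
#'   `fov_mm[2]` smaller than the object, the stationary-point sweep is
#'   restricted to the window and no foldover occurs.
#' @return An object of class `"seq_params"`.
#' @examples
#' sp <- seq_params("PR_SPEN", delta_s = 0.004)
#' sp$delta_s
#' @export
seq_params <- function(kind = c("FR_SPEN", "PR_SPEN", "GE_EPI", "SE_EPI"),
                       fov_mm = c(10.4, 7.5), matrix_size = c(96L, 70L),
                       tr_s = 1, te_s = 0.026, tacq_s = 0.026,
                       chirp_duration_s = 0.005,
                       delta_s = if (match.arg(kind) == "PR_SPEN") 0.004 else 0,
                       chirp_factor = 3, n_averages = 2L,
                       noise_sigma = 0, zoom_center_mm = 0) {
  kind <- match.arg(kind, SEQ_KINDS)
  if (kind == "FR_SPEN") te_s <- tacq_s  # full-refocusing constraint
  p <- structure(list(
    kind = kind, fov_mm = as.numeric(fov_mm),
    matrix_size = as.integer(matrix_size),
    tr_s = tr_s, te_s = te_s, tacq_s = tacq_s,
    chirp_duration_s = chirp_duration_s, delta_s = delta_s,
    chirp_factor = chirp_factor, n_averages = as.integer(n_averages),
    noise_sigma = noise_sigma, zoom_center_mm = zoom_center_mm
  ), class = "seq_params")
  validate_seq_params(p)
  p
}

validate_seq_params <- function(p) {
  stopifnot(inherits(p, "seq_params"))
  if (!p$kind %in% SEQ_KINDS) stop("unknown sequence kind: ", p$kind)
  if (length(p$fov_mm) != 2 || any(p$fov_mm <= 0)) stop("fov_mm must be 2 positive values")
  if (length(p$matrix_size) != 2 || any(p$matrix_size < 8)) stop("matrix_size too small")
  dur <- c(tr_s = p$tr_s, te_s = p$te_s, tacq_s = p$tacq_s)
  if (any(!is.finite(dur)) || any(dur <= 0)) stop("all durations must be positive")
  if (p$tr_s < p$tacq_s) stop("tr_s must be >= tacq_s")
  if (p$kind == "FR_SPEN" && p$delta_s != 0)
    stop("FR_SPEN requires delta_s = 0")
  if (p$kind == "PR_SPEN" && p$delta_s <= 0)
    stop("PR_SPEN requires delta_s > 0")
  if (p$kind == "FR_SPEN" && abs(p$te_s - p$tacq_s) > 1e-12)
    stop("FR_SPEN requires te_s = tacq_s (full-refocusing constraint)")
  if (is_spen(p) && p$te_s < p$chirp_duration_s)
    stop("infeasible timing: te_s (", p$te_s, " s) < chirp_duration_s (",
         p$chirp_duration_s, " s)")
  if (p$n_averages < 1) stop("n_averages must be >= 1")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is_spen(p) && p$chirp_factor < 1) stop("chirp_factor must be >= 1")
  invisible(p)
}

#' @rdname seq_params
#' @param p An object to test.
#' @export
is_spen <- function(p) p$kind %in% c("FR_SPEN", "PR_SPEN")

#' Quadratic-phase coefficients of the SPEN encoding
#'
#' The chirp pulse applied under a gradient imparts a quadratic phase
#' `phi_e(y) = alpha*y^2 + beta*y` along the low-bandwidth axis. During
#' acquisition a readout moment `k(t)` (rad/mm, linear in t) is added, and the
#' signal at time t is dominated by the stationary-phase point
#' `y*(t) = -(beta + k(t)) / (2*alpha)`, which sweeps linearly from `-Ly/2` at
#' `t = 0` to `+Ly/2` at `t = tacq_s`; the total moment swept is
#' `k(tacq_s) - k(0) = 2*|alpha|*Ly`.
#'
#' The magnitude of `alpha` is `chirp_factor * pi * Ny / Ly^2`, i.e. an
#' encoding time-bandwidth product of `chirp_factor * Ny`.
#'
#' @param params A SPEN `seq_params`.
#' @return List with `alpha` (rad/mm^2, negative), `beta` (rad/mm), the sweep
#'   rate `k_rate` (rad/mm/s) with `k(t) = k_rate * t`, and the window center
#'   `y0_mm`.
#' @examples
#' qc <- quadratic_phase_coeffs(seq_params("FR_SPEN"))
#' -(qc$beta + 0) / (2 * qc$alpha)  # y*(0) = -Ly/2 (about the window center)
#' @export
quadratic_phase_coeffs <- function(params) {
  validate_seq_params(params)
  if (!is_spen(params)) stop("quadratic_phase_coeffs: kind must be a SPEN variant")
  Ly <- params$fov_mm[2]; Ny <- params$matrix_size[2]
  y0 <- params$zoom_center_mm
  alpha <- -params$chirp_factor * pi * Ny / Ly^2
  # y*(0) = y0 - Ly/2 with k(0) = 0  =>  beta = -2*alpha*(y0 - Ly/2)... solve:
  # y*(t) = -(beta + k t)/(2 alpha); want y*(0) = y0 - Ly/2, y*(tacq) = y0 + Ly/2
  beta <- -2 * alpha * (y0 - Ly / 2)
  k_rate <- -2 * alpha * Ly / params$tacq_s   # k(tacq) - k(0) = 2|alpha|Ly
  list(alpha = alpha, beta = beta, k_rate = k_rate, y0_mm = y0)
}

#' Stationary-point position at time t
#' @param params A SPEN `seq_params`.
#' @param t_s Time(s) within the acquisition, in s.
#' @return Position(s) in mm.
#' @export
spen_ystar <- function(params, t_s) {
  qc <- quadratic_phase_coeffs(params)
  -(qc$beta + qc$k_rate * t_s) / (2 * qc$alpha)
}

#' Per-position refocusing timing table
#'
#' Computes the sample times and, for every nominal position along the
#' low-bandwidth axis, the time at which that position is acquired (the
#' stationary-point time for SPEN; the echo time for EPI) and the residual
#' off-resonance evolution time at that moment. For FR SPEN the
#' pre-acquisition delay exactly unwinds each position's accrued
#' off-resonance phase (`tau_resid = 0` for all y); for PR SPEN a uniform
#' residual `tau_resid = delta_s` remains. For EPI, the evolution time of the
#' line acquired at time t is t measured from excitation (GE) or `t - TE`
#' (SE).
#'
#' @param params A `seq_params`.
#' @return A `"timing_table"`: list with `params`, `samples` (tibble: `m`,
#'   `t_s`) and `positions` (tibble: `n`, `y_mm`, `t_star_s`, `tau_resid_s`).
#' @examples
#' tt <- build_timing(seq_params("PR_SPEN", delta_s = 0.004))
#' unique(tt$positions$tau_resid_s)
#' @export
build_timing <- function(params) {
  validate_seq_params(params)
  Ny <- params$matrix_size[2]; Ly <- params$fov_mm[2]
  dy <- Ly / Ny
  y <- pixel_coords(Ny, dy) + params$zoom_center_mm

  if (is_spen(params)) {
    # the chirp encodes a time-bandwidth product of chirp_factor * Ny, so the
    # acquisition samples chirp_factor * Ny points over tacq; the stationary
    # point then crosses each reconstruction pixel in chirp_factor samples
    My <- as.integer(round(params$chirp_factor * Ny))
    t_m <- (seq_len(My) - 0.5) / My * params$tacq_s
    t_star <- params$tacq_s * ((y - params$zoom_center_mm) / Ly + 0.5)
    tau <- rep(params$delta_s, Ny)
  } else {
    # EPI: samples centered on the echo, t measured from excitation
    t_m <- params$te_s + (seq_len(Ny) - 0.5 - Ny / 2) / Ny * params$tacq_s
    t_star <- rep(params$te_s, Ny)
    tau <- if (params$kind == "GE_EPI") t_star else t_star - params$te_s
  }
  structure(list(
    params = params,
    samples = tibble::tibble(m = seq_along(t_m), t_s = t_m),
    positions = tibble::tibble(n = seq_len(Ny), y_mm = y,
                               t_star_s = t_star, tau_resid_s = tau)
  ), class = "timing_table")
}

#' Off-resonance evolution time tau(y, t)
#'
#' Matrix of net off-resonance/T2' evolution times (s) for every
#' (position, sample) pair: `tau_resid(y) + (t - t*(y))` for SPEN, `t` from
#' excitation for GE EPI, `t - TE` for SE EPI.
#'
#' @param timing A `timing_table`.
#' @return Ny x Nsamples matrix (positions by samples), seconds.
#' @export
tau_matrix <- function(timing) {
  p <- timing$params
  t_m <- timing$samples$t_s
  if (is_spen(p)) {
    outer(timing$positions$tau_resid_s - timing$positions$t_star_s,
          t_m, `+`)
  } else {
    off <- if (p$kind == "GE_EPI") 0 else p$te_s
    matrix(t_m - off, nrow = nrow(timing$positions),
           ncol = length(t_m), byrow = TRUE)
  }
}

#' Total transverse-decay time per (position, sample)
#'
#' Elapsed T2-decay time: for SPEN each position behaves like a spin echo
#' centered at its stationary moment, `te_s + (t - t*(y))`; for EPI it is the
#' time from excitation (`t`, with the sample train centered on `te_s`).
#'
#' @param timing A `timing_table`.
#' @return Ny x Nsamples matrix, seconds.
#' @export
t2_elapsed_matrix <- function(timing) {
  p <- timing$params
  t_m <- timing$samples$t_s
  if (is_spen(p)) {
    outer(p$te_s - timing$positions$t_star_s, t_m, `+`)
  } else {
    matrix(t_m, nrow = nrow(timing$positions), ncol = length(t_m),
           byrow = TRUE)
  }
}

#' Export a timing table as a plain data frame
#' @param timing A `timing_table`.
#' @return Tibble with one row per position.
#' @export
timing_as_table <- function(timing) timing$positions

#' @export
print.timing_table <- function(x, ...) {
  cat(sprintf("<timing_table> %s, %d samples over %.1f ms\n",
              x$params$kind, nrow(x$samples), 1000 * x$params$tacq_s))
  print(utils::head(x$positions, 3))
  invisible(x)
}
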