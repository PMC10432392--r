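# Block-design stimulation paradigm and hemodynamic response model.

#' Build a block-design odor paradigm
#'
#' Alternating air/odor blocks: event k delivers odor during
#' `[air_s + k*(air_s + odor_s), air_s + k*(air_s + odor_s) + odor_s)`
#' (the run starts with an air block). Volumes are acquired every
#' `volume_interval_s`; the run may be shorter than the full paradigm span
#' (the trailing blocks are truncated), as in a 700-volume, 2 s-spaced run of
#' 10 events of 120 s air + 26 s odor.
#'
#' @param air_s Air (baseline) block duration, s.
#' @param odor_s Odor (stimulation) block duration, s.
#' @param n_events Number of odor events (>= 1).
#' @param volume_interval_s Time between volumes, s.
#' @param n_volumes Number of volumes in the run.
#' @param onset_ramp_s Linear ramp to odor steady state after each onset, s
#'   (odor lines reach steady concentration in about 10 s).
#' @return A `"paradigm"` object: list with the arguments plus `onsets_s`,
#'   `total_span_s` and `volume_times_s`.
#' @examples
#' par <- build_paradigm()
#' par$onsets_s[1] / par$volume_interval_s  # first onset at volume index 60
#' @export
build_paradigm <- function(air_s = 120, odor_s = 26, n_events = 10L,
                           volume_interval_s = 2, n_volumes = 700L,
                           onset_ramp_s = 10) {
  if (odor_s <= 0 || volume_interval_s <= 0 || n_volumes < 1 || n_events < 1)
    stop("paradigm durations and counts must be positive")
  if (air_s < 0 || onset_ramp_s < 0) stop("air_s and onset_ramp_s must be >= 0")
  if (n_volumes * volume_interval_s < air_s + odor_s)
    stop("n_volumes too small to contain one full air+odor event")
  onsets <- air_s + (seq_len(n_events) - 1) * (air_s + odor_s)
  structure(list(
    air_s = air_s, odor_s = odor_s, n_events = as.integer(n_events),
    volume_interval_s = volume_interval_s, n_volumes = as.integer(n_volumes),
    onset_ramp_s = onset_ramp_s,
    onsets_s = onsets,
    total_span_s = n_events * (air_s + odor_s),
    volume_times_s = (seq_len(n_volumes) - 1) * volume_interval_s
  ), class = "paradigm")
}

#' Stimulus waveform of a paradigm
#'
#' Boxcar with a linear ramp of `onset_ramp_s` at each odor onset, evaluated
#' at arbitrary times.
#'
#' @param paradigm A `paradigm`.
#' @param t_s Times (s).
#' @return Numeric vector in `[0, 1]`.
#' @export
stimulus_waveform <- function(paradigm, t_s = paradigm$volume_times_s) {
  out <- numeric(length(t_s))
  ramp <- paradigm$onset_ramp_s
  for (on in paradigm$onsets_s) {
    rel <- t_s - on
    inblk <- rel >= 0 & rel < paradigm$odor_s
    v <- if (ramp > 0) pmin(rel / ramp, 1) else rep(1, length(rel))
    out[inblk] <- pmax(out[inblk], v[inblk])
  }
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; a1, b) - g(t; a2, b)/ratio` with gamma-density kernels: the
#' canonical HRF used by statistical parametric mapping (response delay 6 s,
#' undershoot delay 16 s, undershoot ratio 1/6), without derivative terms.
#' A faster rodent preset is available via [hrf_params_rodent()].
#'
#' @param t_s Times since stimulus (s, >= 0).
#' @param params Named list `a1`, `a2`, `b`, `ratio`; see
#'   [hrf_params_canonical()].
#' @return Dimensionless amplitudes; `hrf(0) = 0`, single positive peak
#'   followed by an undershoot.
#' @examples
#' hrf(0)                 # 0
#' which.max(hrf(0:30))   # peak near 5-6 s
#' @export
hrf <- function(t_s, params = hrf_params_canonical()) {
  if (any(t_s < 0)) stop("hrf is defined for t_s >= 0")
  p <- params
  if (any(!is.finite(unlist(p))) || p$a1 <= 0 || p$a2 <= 0 || p$b <= 0 ||
      p$ratio <= 0)
    stop("invalid HRF shape parameters")
  stats::dgamma(t_s, shape = p$a1, rate = p$b) -
    stats::dgamma(t_s, shape = p$a2, rate = p$b) / p$ratio
}

#' @rdname hrf
#' @export
hrf_params_canonical <- function() list(a1 = 6, a2 = 16, b = 1, ratio = 6)

#' @rdname hrf
#' @export
hrf_params_rodent <- function() list(a1 = 4, a2 = 11, b = 1.4, ratio = 6)

#' HRF-convolved task regressor at volume times
#'
#' Convolves the paradigm's stimulus waveform with the HRF on a fine time
#' grid and samples the result at the volume times, max-normalized to 1.
#'
#' @param paradigm A `paradigm`.
#' @param hrf_params HRF parameters.
#' @param dt_s Fine grid step for the convolution.
#' @return Numeric vector of length `n_volumes` with maximum 1.
#' @export
task_regressor <- function(paradigm, hrf_params = hrf_params_canonical(),
                           dt_s = 0.1) {
  t_fine <- seq(0, max(paradigm$volume_times_s) + 1, by = dt_s)
  stim <- stimulus_waveform(paradigm, t_fine)
  kern <- hrf(seq(0, 40, by = dt_s), hrf_params)
  conv <- stats::convolve(stim, rev(kern), type = "open")[seq_along(t_fine)] * dt_s
  reg <- stats::approx(t_fine, conv, xout = paradigm$volume_times_s,
                       rule = 2)$y
  m <- max(reg)
  if (m > 0) reg / m else reg
}

#' Paradigm events table
#'
#' @param paradigm A `paradigm`.
#' @return Tibble with `onset`, `duration`, `condition` (BIDS-style events).
#' @export
paradigm_events <- function(paradigm) {
  tibble::tibble(onset = paradigm$onsets_s,
                 duration = paradigm$odor_s,
                 condition = "odor")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf(paste0("<paradigm> %d events of %g s air + %g s odor; %d volumes ",
                     "every %g s (run %.0f s, paradigm span %.0f s)\n"),
              x$n_events, x$air_s, x$odor_s, x$n_volumes,
              x$volume_interval_s, x$n_volumes * x$volume_interval_s,
              x$total_span_s))
  invisible(x)
}
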