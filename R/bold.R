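# Block-design olfactory BOLD simulation: activation model and full runs.

#' Activation (BOLD) model
#'
#' Describes how odor stimulation modulates transverse relaxation in the
#' phantom: a peak activation-induced change in R2* (`delta_r2star_hz`, 1/s)
#' distributed over named region masks with relative amplitudes, a
#' hemisphere lateralization, a saturating concentration response (Hill
#' function), and an optional adaptation time constant. A fraction
#' `t2_fraction` of the R2* change behaves as irreversible (T2-like)
#' relaxation from microscopic vessels, which survives full refocusing; the
#' remainder is reversible (T2'-like) and is only seen through residual T2*
#' evolution time.
#'
#' @param odor One of `"neutral"`, `"appetitive"`, `"aversive"`, or
#'   `"control"` (no activation): selects the active masks (lateral
#'   glomerular sectors for appetitive, external plexiform ring for aversive,
#'   both for neutral).
#' @param delta_r2star_hz Peak activation-induced R2* change (1/s).
#' @param concentration_ppm Odorant concentration at the mask outlet (ppm).
#' @param conc_model List `c50` (ppm), `h` (Hill exponent), `max` (scale).
#' @param lateralization `"both"`, `"left_only"`, or `"right_only"`.
#' @param t2_fraction Fraction of `delta_r2star_hz` acting as T2-like change
#'   (survives full refocusing).
#' @param hrf_params HRF shape parameters.
#' @param active_masks Optional named numeric vector of mask weights
#'   overriding the odor preset, e.g. `c(epl = 1, glomerular_lateral = 0.5)`.
#' @param adaptation_tau_s Optional exponential adaptation time constant (s);
#'   `Inf` disables adaptation (default: stimuli of 26 s show none).
#' @return A `"bold_model"` object.
#' @examples
#' bm <- bold_model("aversive", concentration_ppm = 60)
#' bm$active_masks
#' @export
bold_model <- function(odor = c("neutral", "appetitive", "aversive", "control"),
                       delta_r2star_hz = 5,
                       concentration_ppm = 450,
                       conc_model = list(c50 = 60, h = 1.5, max = 1),
                       lateralization = c("both", "left_only", "right_only"),
                       t2_fraction = 0.4,
                       hrf_params = hrf_params_canonical(),
                       active_masks = NULL,
                       adaptation_tau_s = Inf) {
  odor <- match.arg(odor)
  lateralization <- match.arg(lateralization)
  if (delta_r2star_hz < 0) stop("delta_r2star_hz must be >= 0")
  if (t2_fraction < 0 || t2_fraction > 1) stop("t2_fraction must be in [0, 1]")
  if (is.null(active_masks))
    active_masks <- switch(odor,
      neutral    = c(epl = 1, glomerular_lateral = 1),
      appetitive = c(glomerular_lateral = 1),
      aversive   = c(epl = 1),
      control    = c(epl = 0, glomerular_lateral = 0))
  structure(list(
    odor = odor, delta_r2star_hz = delta_r2star_hz,
    concentration_ppm = concentration_ppm, conc_model = conc_model,
    lateralization = lateralization, t2_fraction = t2_fraction,
    hrf_params = hrf_params, active_masks = active_masks,
    adaptation_tau_s = adaptation_tau_s,
    plugged = "none"
  ), class = "bold_model")
}

#' Saturating concentration response
#'
#' Hill function `c^h / (c^h + c50^h) * max`: nonnegative, nondecreasing in
#' concentration and bounded, reflecting the saturation of the olfactory
#' response beyond physiological concentrations (on the order of 100 ppm).
#'
#' @param c_ppm Concentration(s), ppm (>= 0).
#' @param conc_model List with `c50`, `h`, `max`.
#' @return Amplitude scale(s) in `[0, max]`.
#' @examples
#' concentration_amplitude(60)   # = max/2 at c50
#' @export
concentration_amplitude <- function(c_ppm,
                                    conc_model = list(c50 = 60, h = 1.5,
                                                      max = 1)) {
  if (any(c_ppm < 0)) stop("concentration must be >= 0")
  m <- conc_model
  ifelse(c_ppm == 0, 0, c_ppm^m$h / (c_ppm^m$h + m$c50^m$h) * m$max)
}

#' Single-nostril scenario
#'
#' Each OB hemisphere receives input from the ipsilateral nostril, so
#' plugging one nostril silences the ipsilateral hemisphere: activation is
#' confined to the side of the open nostril.
#'
#' @param bold A `bold_model`.
#' @param plugged `"left"`, `"right"`, or `"none"`.
#' @return The modified `bold_model`.
#' @examples
#' bm <- nostril_scenario(bold_model(), "left")
#' bm$lateralization  # "right_only"
#' @export
nostril_scenario <- function(bold, plugged = c("none", "left", "right")) {
  plugged <- match.arg(plugged)
  if (plugged == "none") return(bold)
  if (bold$plugged != "none" && bold$plugged != plugged)
    stop("contradictory nostril occlusion: already plugged ", bold$plugged)
  bold$plugged <- plugged
  bold$lateralization <- if (plugged == "left") "right_only" else "left_only"
  bold
}

#' Active ROI of a bold model on a phantom
#'
#' Logical mask of the pixels whose relaxation is modulated by the model
#' (the union of its weighted masks, after lateralization).
#'
#' @param phantom An `ob_phantom`.
#' @param bold A `bold_model`.
#' @return Logical matrix.
#' @export
active_roi <- function(phantom, bold) activation_map_r2star(phantom, bold) > 0

# peak Delta-R2* map (1/s) over the phantom grid for a bold model
activation_map_r2star <- function(phantom, bold) {
  d <- phantom_dim(phantom)
  M <- matrix(0, d[1], d[2])
  for (nm in names(bold$active_masks)) {
    if (is.null(phantom$masks[[nm]]))
      stop("phantom is missing required mask '", nm, "'")
    M <- M + bold$active_masks[[nm]] * phantom$masks[[nm]]
  }
  if (bold$lateralization == "left_only")  M[!phantom$masks$ob_left] <- 0
  if (bold$lateralization == "right_only") M[!phantom$masks$ob_right] <- 0
  M * bold$delta_r2star_hz
}

#' Default nuisance settings for simulated runs
#'
#' Multiplicative slow drift (linear plus one low-frequency cosine, percent
#' of baseline per run), and randomly timed in-plane translation spikes
#' (per-volume probability and amplitude in pixels).
#'
#' @param drift_pct Peak-to-peak linear drift over the run, percent.
#' @param spike_rate Per-volume probability of a motion spike.
#' @param spike_px Motion spike amplitude (pixels, integer shifts).
#' @return Named list.
#' @export
nuisance_defaults <- function(drift_pct = 1, spike_rate = 0.002,
                              spike_px = 1) {
  list(drift_pct = drift_pct, spike_rate = spike_rate, spike_px = spike_px)
}

#' Simulate a complete block-design fMRI run
#'
#' For every volume, the activation regressor (HRF-convolved stimulus, scaled
#' by the concentration response) modulates the relaxation rates of the
#' active regions (activation lowers R2*, raising the signal): a fraction
#' `t2_fraction` of the peak Delta-R2* acts on
#' 1/T2 (seen by every sequence through its echo time) and the remainder on
#' 1/T2' (seen through each sequence's residual T2* evolution time, so a
#' fully refocused SPEN run responds only through the T2-like component,
#' a partially refocused run adds `exp(-Delta * Delta-R2*')` modulation, and
#' EPI responds through its full evolution time). Each volume is acquired
#' with the forward model and reconstructed with the sequence's matched
#' reconstruction; multiplicative slow drift and randomly timed in-plane
#' translation spikes are then applied. Deterministic for a fixed seed.
#'
#' @param phantom An `ob_phantom`.
#' @param params A `seq_params` (any of the four kinds). Its `noise_sigma`
#'   is the raw noise level per average.
#' @param paradigm A `paradigm`; its `volume_interval_s` should equal
#'   `tr_s * n_averages`.
#' @param bold A `bold_model`.
#' @param nuisance See [nuisance_defaults()].
#' @param seed Integer seed for noise and motion.
#' @param lambda Regularization for the SPEN reconstruction.
#' @return A `"timeseries_dataset"`: list with `volumes` (nx x ny x T array),
#'   `volume_interval_s`, `paradigm`, `phantom` and `provenance` (params,
#'   bold, nuisance, seed, motion table).
#' @export
simulate_run <- function(phantom, params, paradigm = build_paradigm(),
                         bold = bold_model(), nuisance = nuisance_defaults(),
                         seed = 1L, lambda = 1e-3) {
  op <- forward_operator(phantom, params)
  d <- phantom_dim(phantom)
  nvol <- paradigm$n_volumes

  # task amplitude per volume: HRF-convolved stimulus x concentration scale
  reg <- task_regressor(paradigm, bold$hrf_params)
  if (is.finite(bold$adaptation_tau_s)) {
    # optional adaptation: exponential down-weighting within each odor block
    tvol <- paradigm$volume_times_s
    w <- rep(1, nvol)
    for (on in paradigm$onsets_s) {
      rel <- tvol - on
      idx <- rel >= 0
      w[idx] <- pmin(w[idx], exp(-pmax(rel[idx], 0) / bold$adaptation_tau_s))
    }
    reg <- reg * w
  }
  g_t <- reg * concentration_amplitude(bold$concentration_ppm, bold$conc_model)

  # dynamic decay exponent cube: Tel * dR2 + |tau| * dR2'
  dr2star <- activation_map_r2star(phantom, bold)
  dr2  <- bold$t2_fraction * dr2star
  dr2p <- (1 - bold$t2_fraction) * dr2star
  nm <- op$dims[["nm"]]
  B <- array(0, dim = c(d[1], d[2], nm))
  for (m in seq_len(nm)) {
    B[, , m] <- dr2 * rep(op$tel[, m], each = d[1]) +
      dr2p * rep(abs(op$tau[, m]), each = d[1])
  }

  # drift: linear + one low-frequency cosine, percent of baseline
  tt <- paradigm$volume_times_s
  Tn <- max(tt) + paradigm$volume_interval_s
  a <- nuisance$drift_pct / 100
  drift <- 1 + a * (tt / Tn - 0.5) + 0.3 * a * cos(2 * pi * tt * 1.5 / Tn)

  set.seed(as.integer(seed))
  spike <- stats::runif(nvol) < nuisance$spike_rate
  shifts <- matrix(0L, nvol, 2)
  if (any(spike)) {
    amp <- max(1L, round(nuisance$spike_px))
    shifts[spike, ] <- cbind(sample(c(-amp, amp), sum(spike), TRUE),
                             sample(c(-amp, amp), sum(spike), TRUE))
  }

  A <- if (is_spen(params)) encoding_matrix(params, op$timing) else NULL
  Rsolver <- if (is_spen(params)) sr_solver(A, lambda, "identity") else NULL

  vols <- array(0, dim = c(d[1], d[2], nvol))
  for (v in seq_len(nvol)) {
    # activation lowers R2*/R2' (BOLD), raising the signal: exponent -(-g)B
    s <- forward_signal(op, B, -g_t[v]) * drift[v]
    raw <- raw_from_signal(s, op, seed, rng_ready = TRUE)
    img <- if (is_spen(params)) {
      sx <- stats::mvfft(raw$samples, inverse = TRUE) / d[1]
      t(Mod(Rsolver %*% t(sx))) / params$n_averages
    } else recon_epi(raw)
    if (spike[v]) img <- shift_image(img, shifts[v, 1], shifts[v, 2])
    vols[, , v] <- img
  }
  structure(list(
    volumes = vols, volume_interval_s = paradigm$volume_interval_s,
    paradigm = paradigm, phantom = phantom,
    provenance = list(params = params, bold = bold, nuisance = nuisance,
                      seed = as.integer(seed), lambda = lambda,
                      regressor = reg, g_t = g_t, drift = drift,
                      motion = tibble::tibble(volume = which(spike),
                                              dx = shifts[spike, 1],
                                              dy = shifts[spike, 2]))
  ), class = "timeseries_dataset")
}

# integer in-plane translation with zero fill
shift_image <- function(img, dx, dy) {
  d <- dim(img)
  out <- matrix(0, d[1], d[2])
  xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  out[okx, oky] <- img[xs[okx], ys[oky]]
  out
}

#' @export
print.timeseries_dataset <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<timeseries_dataset> %d x %d px, %d volumes every %g s (%s)\n",
              d[1], d[2], d[3], x$volume_interval_s,
              x$provenance$params$kind))
  invisible(x)
}
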