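# Quality-control screening of simulated runs, mirroring the plain-inspection
# discard criteria applied to raw OB time courses: evident motion, severe
# baseline drift, uncertain (inconsistent) activation.

#' Default QC thresholds
#' @param motion_z Frame-to-frame z-score above which a volume counts as a
#'   motion spike.
#' @param motion_max_volumes Maximum tolerated number of spike volumes.
#' @param drift_pct Maximum tolerated absolute linear drift, percent per run.
#' @param consistency_min Minimum split-half correlation of the
#'   epoch-averaged response.
#' @param require_consistency Whether an inconsistent (or absent) response is
#'   grounds for discarding.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(motion_z = 4, motion_max_volumes = 3,
                          drift_pct = 3, consistency_min = 0.3,
                          require_consistency = TRUE) {
  list(motion_z = motion_z, motion_max_volumes = motion_max_volumes,
       drift_pct = drift_pct, consistency_min = consistency_min,
       require_consistency = require_consistency)
}

#' Quality-control screen of a run
#'
#' Computes (a) motion indicators: robust z-scores of the frame-to-frame
#' global-intensity change and of the frame-to-frame center-of-mass
#' displacement (in pixels), counting volumes where either exceeds
#' `motion_z`; (b) the fitted linear drift of the OB-mean time course, in
#' percent per run; (c) response consistency: the correlation between the
#' epoch-averaged response curves of the odd and even epochs. The run is
#' kept only if all metrics pass their thresholds. All metrics are returned
#' regardless of the verdict; with fewer than 2 complete epochs the
#' consistency metric is reported as missing.
#'
#' @param ds A `timeseries_dataset`.
#' @param thresholds See [qc_thresholds()].
#' @param mask ROI for the drift/consistency time course; defaults to the
#'   whole OB.
#' @return List with `keep` (logical), `metrics` (tibble: one row), and
#'   `spike_volumes`.
#' @export
qc_screen <- function(ds, thresholds = qc_thresholds(), mask = NULL) {
  d <- dim(ds$volumes)
  if (is.null(mask)) {
    msk <- ds$phantom$masks
    mask <- msk$ob_left | msk$ob_right
  }
  series <- roi_timecourse(ds, mask)

  # (a) motion: per-volume center-of-mass displacement from the run median,
  # plus detrended global-intensity deviations. Absolute floors (half a
  # pixel, 1% of intensity) keep the task-related micro-fluctuations of very
  # clean runs from registering as motion.
  gint <- apply(ds$volumes, 3, mean)
  gint_resid <- gint - stats::runmed(gint, 15)
  z_int <- robust_z(gint_resid)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  com <- t(apply(ds$volumes, 3, function(v) {
    s <- sum(v)
    c(sum(v * xs) / s, sum(v * rep(ys, each = d[1])) / s)
  }))
  disp <- sqrt((com[, 1] - stats::median(com[, 1]))^2 +
                 (com[, 2] - stats::median(com[, 2]))^2)
  z_com <- robust_z(disp)
  spike <- which((abs(z_int) > thresholds$motion_z &
                    abs(gint_resid) > 0.01 * stats::median(gint)) |
                   (abs(z_com) > thresholds$motion_z & disp > 0.5))
  motion_ok <- length(spike) <= thresholds$motion_max_volumes

  # (b) linear drift in percent of mean per run
  tt <- seq_along(series)
  fit <- stats::lm.fit(cbind(1, tt), series)
  drift_pct <- 100 * fit$coefficients[2] * length(series) / mean(series)
  drift_ok <- abs(drift_pct) <= thresholds$drift_pct

  # (c) split-half epoch consistency
  consistency <- NA_real_
  pc_all <- tryCatch(percent_change(series, ds$paradigm), error = function(e) NULL)
  if (!is.null(pc_all) && pc_all$n_epochs >= 2) {
    halves <- epoch_halves(series, ds$paradigm)
    if (!is.null(halves)) consistency <- stats::cor(halves[[1]], halves[[2]])
  }
  cons_ok <- if (!thresholds$require_consistency) TRUE else
    (!is.na(consistency) && consistency >= thresholds$consistency_min)

  keep <- motion_ok && drift_ok && cons_ok
  list(
    keep = keep,
    metrics = tibble::tibble(
      n_spike_volumes = length(spike), motion_ok = motion_ok,
      drift_pct_per_run = unname(drift_pct), drift_ok = drift_ok,
      epoch_consistency = consistency, consistency_ok = cons_ok
    ),
    spike_volumes = spike
  )
}

robust_z <- function(v) {
  s <- stats::mad(v)
  if (s == 0) s <- stats::sd(v)
  if (is.na(s) || s == 0) return(rep(0, length(v)))
  (v - stats::median(v)) / s
}

# epoch-averaged percent-change curves of the odd and the even epochs
epoch_halves <- function(series, paradigm) {
  vi <- paradigm$volume_interval_s
  nvol <- length(series)
  nb <- max(1L, round(30 / vi))
  npre <- round(20 / vi); npost <- round((paradigm$odor_s + 40) / vi)
  rel <- seq(-npre, npost)
  curves <- list()
  for (on in paradigm$onsets_s) {
    i_on <- round(on / vi) + 1L
    idx <- i_on + rel; i_base <- (i_on - nb):(i_on - 1L)
    if (min(i_base) < 1 || max(idx) > nvol || min(idx) < 1) next
    base <- mean(series[i_base])
    curves[[length(curves) + 1L]] <- 100 * (series[idx] - base) / base
  }
  if (length(curves) < 2) return(NULL)
  odd <- curves[seq(1, length(curves), by = 2)]
  even <- curves[seq(2, length(curves), by = 2)]
  list(colMeans(do.call(rbind, odd)), colMeans(do.call(rbind, even)))
}
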