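# First-level analysis: ROI time courses, epoch averaging, smoothing, GLM.

#' ROI mean time course
#'
#' Per-volume mean intensity over a mask: the raw, statistics-free readout of
#' a run (mean OB signal against the paradigm).
#'
#' @param ds A `timeseries_dataset`.
#' @param mask Logical matrix on the dataset grid.
#' @return Numeric vector of length `n_volumes`.
#' @export
roi_timecourse <- function(ds, mask) {
  d <- dim(ds$volumes)
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), d[1:2])) stop("mask grid does not match dataset")
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask)
  apply(ds$volumes, 3, function(v) mean(v[idx]))
}

#' Epoch-averaged percent signal change
#'
#' For every complete odor event, the baseline is the mean of the last
#' `baseline_s` of the preceding air block; the percent-change curves of all
#' complete epochs, aligned at odor onset, are averaged; and the peak percent
#' change after onset is reported. Staggered-epoch averaging cancels slow
#' drift to first order.
#'
#' @param series ROI time course (per volume), aligned to `paradigm`.
#' @param paradigm The `paradigm` of the run.
#' @param baseline_s Pre-onset baseline window (s).
#' @param pre_s,post_s Epoch window before onset and after odor offset (s).
#' @return An `"epoch_response"`: list with `curve` (tibble `rel_s`, `pct`),
#'   `peak_pct`, `peak_time_s`, `n_epochs`.
#' @export
percent_change <- function(series, paradigm, baseline_s = 30,
                           pre_s = 20, post_s = 40) {
  vi <- paradigm$volume_interval_s
  nvol <- length(series)
  if (nvol != paradigm$n_volumes)
    stop("series length does not match the paradigm")
  nb <- max(1L, round(baseline_s / vi))
  npre <- round(pre_s / vi)
  npost <- round((paradigm$odor_s + post_s) / vi)
  rel <- seq(-npre, npost)
  curves <- list()
  for (on in paradigm$onsets_s) {
    i_on <- round(on / vi) + 1L
    i_base <- (i_on - nb):(i_on - 1L)
    idx <- i_on + rel
    if (min(i_base) < 1 || max(idx) > nvol || min(idx) < 1) next
    base <- mean(series[i_base])
    if (base == 0) stop("zero baseline in percent_change")
    curves[[length(curves) + 1L]] <- 100 * (series[idx] - base) / base
  }
  if (!length(curves)) stop("no complete epoch (baseline window empty)")
  avg <- colMeans(do.call(rbind, curves))
  post_onset <- rel > 0
  structure(list(
    curve = tibble::tibble(rel_s = rel * vi, pct = avg),
    peak_pct = max(avg[post_onset]),
    peak_time_s = rel[post_onset][which.max(avg[post_onset])] * vi,
    n_epochs = length(curves)
  ), class = "epoch_response")
}

#' @export
print.epoch_response <- function(x, ...) {
  cat(sprintf("<epoch_response> %d epochs; peak %.2f%% at %.0f s after onset\n",
              x$n_epochs, x$peak_pct, x$peak_time_s))
  invisible(x)
}

#' Gaussian spatial smoothing
#'
#' Separable 2D Gaussian convolution with the kernel width given as FWHM in
#' mm (converted per axis by the pixel size). Applied per volume for a
#' dataset. Zero padding at the edges: total intensity is conserved for
#' interior-supported images. A warning is emitted when the FWHM exceeds 25%
#' of the image extent, where smoothing is large relative to the object.
#'
#' @param x A matrix image or a `timeseries_dataset`.
#' @param fwhm_mm Kernel full width at half maximum, mm (>= 0; 0 is the
#'   identity).
#' @param pixel_mm Pixel size; taken from the dataset when `x` is one.
#' @return Smoothed object of the same type.
#' @export
smooth_gaussian <- function(x, fwhm_mm, pixel_mm = NULL) {
  if (length(fwhm_mm) != 1 || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a single nonnegative number")
  if (inherits(x, "timeseries_dataset")) {
    pm <- x$phantom$pixel_mm
    for (v in seq_len(dim(x$volumes)[3]))
      x$volumes[, , v] <- smooth_gaussian(x$volumes[, , v], fwhm_mm, pm)
    return(x)
  }
  if (fwhm_mm == 0) return(x)
  if (is.null(pixel_mm)) stop("pixel_mm required for matrix input")
  ext <- dim(x) * pixel_mm
  if (fwhm_mm > 0.25 * max(ext))
    warning("smoothing FWHM (", fwhm_mm, " mm) exceeds 25% of the image extent")
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / pixel_mm
  kx <- gauss_kernel(sig[1]); ky <- gauss_kernel(sig[2])
  out <- apply(x, 2, function(col) conv_same(col, kx))
  t(apply(out, 1, function(row) conv_same(row, ky)))
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

conv_same <- function(v, k) {
  if (length(k) == 1L) return(v * k)
  r <- (length(k) - 1L) / 2L
  padded <- c(rep(0, r), v, rep(0, r))
  stats::convolve(padded, k, type = "filter")
}

#' First-level design matrix
#'
#' Columns: intercept; HRF-convolved task regressor (max-normalized to 1);
#' optional second-order time modulation of the task (task multiplied by
#' mean-centered linear and quadratic time covariates, accounting for
#' non-stationary response amplitude); and a low-frequency cosine drift
#' basis (periods longer than `drift_cutoff_s`).
#'
#' @param paradigm A `paradigm`.
#' @param hrf_params HRF parameters.
#' @param time_modulation Order of task time-modulation (0, 1 or 2).
#' @param drift_cutoff_s Drift basis cutoff: cosines with period >=
#'   `drift_cutoff_s` are included (0 disables the basis).
#' @return A `"design_matrix"`: list with `X` (volumes x regressors, named
#'   columns), `times_s`, and `task_col`.
#' @export
design_matrix <- function(paradigm, hrf_params = hrf_params_canonical(),
                          time_modulation = 2L, drift_cutoff_s = 256) {
  tt <- paradigm$volume_times_s
  task <- task_regressor(paradigm, hrf_params)
  X <- cbind(intercept = 1, task = task)
  if (time_modulation >= 1) {
    tc <- scale(tt, center = TRUE, scale = max(tt) / 2)[, 1]
    X <- cbind(X, task_t = task * tc)
    if (time_modulation >= 2) {
      tc2 <- tc^2 - mean(tc^2)
      X <- cbind(X, task_t2 = task * tc2)
    }
  }
  if (drift_cutoff_s > 0) {
    Tn <- max(tt) + paradigm$volume_interval_s
    K <- floor(2 * Tn / drift_cutoff_s)
    if (K >= 1) {
      dr <- sapply(seq_len(K), function(k) cos(pi * k * (tt + 0.5) / Tn))
      colnames(dr) <- paste0("drift", seq_len(K))
      X <- cbind(X, dr)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, times_s = tt, task_col = "task"),
            class = "design_matrix")
}

#' First-level GLM t-map
#'
#' Pixelwise ordinary least squares fit of the design matrix, with the
#' t-statistic of a contrast: `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)`,
#' `df = T - rank(X)`. Pixels with exactly zero residual variance and a
#' nonzero contrast estimate are flagged and reported as infinite t.
#'
#' @param ds A `timeseries_dataset` (or a volumes array with attribute
#'   handling left to the caller).
#' @param X A `design_matrix` whose row count equals the number of volumes.
#' @param contrast Contrast vector (length = number of regressors) or the
#'   name of a single column (default the task column).
#' @param p_threshold Significance threshold applied to the two-sided p.
#' @param correction `"none"` (uncorrected, as in threshold-level activation
#'   maps) or `"fdr"` (Benjamini-Hochberg).
#' @param mask Optional analysis mask (logical matrix): statistics are
#'   computed everywhere but only pixels inside the mask can be
#'   suprathreshold, as in a standard brain-masked analysis.
#' @return An `"activation_map"`: list with `stat` (matrix of t), `df`,
#'   `p` (two-sided), `p_threshold`, `correction`, `mask_supra`,
#'   `degenerate` (logical matrix of zero-variance pixels), `beta_task`.
#' @export
glm_first_level <- function(ds, X = NULL, contrast = NULL,
                            p_threshold = 0.001,
                            correction = c("none", "fdr"), mask = NULL) {
  correction <- match.arg(correction)
  vols <- if (inherits(ds, "timeseries_dataset")) ds$volumes else ds
  d <- dim(vols)
  if (is.null(X)) X <- design_matrix(ds$paradigm)
  Xm <- X$X
  if (nrow(Xm) != d[3])
    stop("design matrix rows (", nrow(Xm), ") != volumes (", d[3], ")")
  if (is.null(contrast)) contrast <- X$task_col
  cvec <- if (is.character(contrast)) {
    v <- numeric(ncol(Xm)); v[match(contrast, colnames(Xm))] <- 1; v
  } else {
    if (length(contrast) != ncol(Xm))
      stop("contrast length != number of regressors")
    as.numeric(contrast)
  }
  Y <- matrix(vols, nrow = d[1] * d[2], ncol = d[3])   # pixels x time
  XtX <- crossprod(Xm)
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% crossprod(Xm, t(Y))               # k x pixels
  resid <- t(Y) - Xm %*% beta
  dfree <- d[3] - qr(Xm)$rank
  sigma2 <- colSums(resid^2) / dfree
  # numerically-zero residual variance (exact fit) is a degenerate case:
  # flag it and report an infinite t rather than dividing rounding noise
  tss <- rowSums(Y^2)
  zero_var <- sigma2 * dfree <= 1e-16 * pmax(tss, .Machine$double.xmin)
  cb <- drop(crossprod(cvec, beta))
  varc <- drop(crossprod(cvec, XtXinv %*% cvec))
  se <- sqrt(sigma2 * varc)
  tval <- ifelse(se > 0 & !zero_var, cb / se,
                 ifelse(cb == 0, 0, Inf * sign(cb)))
  degen <- zero_var & cb != 0
  pval <- 2 * stats::pt(abs(tval), dfree, lower.tail = FALSE)
  pval[degen] <- 0
  map <- new_activation_map(matrix(tval, d[1], d[2]), df = dfree,
                            p = matrix(pval, d[1], d[2]),
                            p_threshold = p_threshold,
                            correction = correction, stat_type = "t",
                            degenerate = matrix(degen, d[1], d[2]),
                            beta_task = matrix(drop(beta[which(cvec != 0)[1], ]),
                                               d[1], d[2]))
  if (!is.null(mask)) {
    map$mask_supra <- map$mask_supra & mask
    map$analysis_mask <- mask
  }
  map
}

new_activation_map <- function(stat, df, p, p_threshold, correction,
                               stat_type, ...) {
  padj <- switch(correction,
                 none = p,
                 fdr = matrix(stats::p.adjust(p, method = "BH"), nrow(p)),
                 permutation = p)   # permutation p is already FWE-corrected
  structure(list(stat = stat, df = df, p = p, p_adj = padj,
                 p_threshold = p_threshold, correction = correction,
                 stat_type = stat_type,
                 mask_supra = padj < p_threshold, ...),
            class = "activation_map")
}

#' Re-threshold an activation map
#' @param map An `activation_map`.
#' @param p_threshold New threshold.
#' @param correction `"none"` or `"fdr"` (permutation maps keep their
#'   correction).
#' @return The re-thresholded map.
#' @export
threshold_map <- function(map, p_threshold = map$p_threshold,
                          correction = map$correction) {
  new_activation_map(map$stat, map$df, map$p, p_threshold, correction,
                     map$stat_type)
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %s map (df %s), %d/%d suprathreshold at p < %g (%s)\n",
              x$stat_type, paste(x$df, collapse = ","),
              sum(x$mask_supra), length(x$mask_supra),
              x$p_threshold, x$correction))
  invisible(x)
}
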