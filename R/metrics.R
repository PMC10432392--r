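# Image- and map-level metrics.

#' Image signal-to-noise ratio
#'
#' Mean intensity over the signal mask divided by the standard deviation
#' over the noise mask. For magnitude images the background noise is
#' Rayleigh-distributed; with `rayleigh_correction = TRUE` the background SD
#' is divided by 0.655 to estimate the underlying Gaussian sigma.
#'
#' @param image Nonnegative matrix.
#' @param signal_mask,noise_mask Disjoint nonempty logical masks.
#' @param rayleigh_correction Apply the 0.655 magnitude-background factor.
#' @return SNR (>= 0); infinite when the noise SD is zero.
#' @export
snr <- function(image, signal_mask, noise_mask, rayleigh_correction = FALSE) {
  if (!any(signal_mask) || !any(noise_mask)) stop("masks must be nonempty")
  if (any(signal_mask & noise_mask)) stop("masks must be disjoint")
  s <- mean(image[signal_mask])
  n <- stats::sd(image[noise_mask])
  if (rayleigh_correction) n <- n / 0.655
  if (n == 0) return(Inf)
  s / n
}

#' Intensity-centroid displacement between two images
#'
#' Difference of the intensity centroids (reconstruction minus truth), in
#' mm per axis: the package's scalar summary of geometric distortion.
#'
#' @param recon_image,truth_image Nonnegative matrices on the same grid with
#'   positive total intensity.
#' @param pixel_mm Pixel size (dx, dy) in mm.
#' @return Named numeric `c(dx_mm, dy_mm)`.
#' @export
centroid_shift <- function(recon_image, truth_image, pixel_mm) {
  if (!identical(dim(recon_image), dim(truth_image)))
    stop("images must share one grid")
  if (any(recon_image < 0) || any(truth_image < 0))
    stop("images must be nonnegative")
  if (sum(recon_image) <= 0 || sum(truth_image) <= 0)
    stop("zero-mass image")
  c1 <- centroid_px(recon_image); c0 <- centroid_px(truth_image)
  out <- (c1 - c0) * pixel_mm
  names(out) <- c("dx_mm", "dy_mm")
  out
}

centroid_px <- function(img) {
  d <- dim(img); s <- sum(img)
  c(sum(img * seq_len(d[1])) / s,
    sum(img * rep(seq_len(d[2]), each = d[1])) / s)
}

#' Dice overlap of two binary masks
#'
#' `2|A and B| / (|A| + |B|)`, in `[0, 1]`.
#'
#' @param maskA,maskB Logical matrices on the same grid; both empty is
#'   rejected.
#' @return Dice coefficient.
#' @export
dice_coef <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("masks must share one grid")
  a <- sum(maskA); b <- sum(maskB)
  if (a + b == 0) stop("both masks are empty")
  2 * sum(maskA & maskB) / (a + b)
}

#' Object-support mask of an image
#'
#' Threshold at a fraction of the robust maximum (99th percentile), the
#' package's convention for comparing reconstructed support against ground
#' truth.
#'
#' @param image Nonnegative matrix.
#' @param frac Fraction of the robust maximum.
#' @return Logical matrix.
#' @export
support_mask <- function(image, frac = 0.25) {
  image > frac * stats::quantile(image, 0.99)
}
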