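#' Digital olfactory-bulb phantom
#'
#' Builds a 2D two-hemisphere olfactory-bulb (OB) phantom on a regular pixel
#' grid: two elliptical hemispheres with concentric layers (outer glomerular
#' rim, external plexiform ring, granule-cell core), per-layer proton density
#' and relaxation values, and a set of anatomical region masks used throughout
#' the simulator (hemispheres, EPL ring, lateral glomerular sectors,
#' background air, and a background noise ROI).
#'
#' Pixel centers sit at `((i + 0.5) - N/2) * delta` mm with 0-based `i`;
#' `x` is the readout axis, `y` the low-bandwidth (phase/SPEN) axis.
#' The transverse-relaxation maps satisfy `1/T2* = 1/T2 + 1/T2'` by
#' construction wherever `t2prime_map` is finite.
#'
#' @param nx,ny Grid size in pixels along x (readout) and y (low-bandwidth
#'   axis). Both must be at least 16.
#' @param pixel_mm Length-2 numeric, pixel size (dx, dy) in mm. The defaults
#'   realize a 10.4 x 7.5 mm^2 field of view at 96 x 70 pixels
#'   (108 x 107 um^2 nominal resolution).
#' @param seed Integer seed controlling the small multiplicative proton
#'   density texture; the geometry is deterministic.
#' @param texture_sd Standard deviation of the log-normal PD texture inside
#'   the object (0 disables it).
#' @param tissue Optional named list overriding per-layer tissue values; see
#'   [ob_tissue_defaults()].
#'
#' @return An object of class `"ob_phantom"`: a list with matrices `pd_map`
#'   (relative proton density, 0 outside the object), `t2_map`, `t2prime_map`
#'   (ms), `b0_map` (off-resonance, Hz; zero until a field is applied),
#'   `pixel_mm`, and `masks`, a named list of logical matrices
#'   (`ob_left`, `ob_right`, `epl`, `glomerular_lateral`, `core`,
#'   `background`, `noise_roi`).
#' @examples
#' ph <- make_ob_phantom(48, 36)
#' range(ph$pd_map)
#' @export
make_ob_phantom <- function(nx = 96L, ny = 70L,
                            pixel_mm = c(10.4 / 96, 7.5 / 70),
                            seed = 1L, texture_sd = 0.02,
                            tissue = NULL) {
  if (length(nx) != 1L || length(ny) != 1L || nx < 16 || ny < 16)
    stop("phantom grid must be at least 16 x 16 pixels (got ",
         nx, " x ", ny, ")")
  pixel_mm <- as.numeric(pixel_mm)
  if (length(pixel_mm) != 2L || any(!is.finite(pixel_mm)) || any(pixel_mm <= 0))
    stop("pixel_mm must be two positive numbers (dx, dy) in mm")
  nx <- as.integer(nx); ny <- as.integer(ny)

  tis <- ob_tissue_defaults()
  if (!is.null(tissue)) tis[names(tissue)] <- tissue

  x <- pixel_coords(nx, pixel_mm[1])
  y <- pixel_coords(ny, pixel_mm[2])
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)

  fov <- c(nx, ny) * pixel_mm
  # two hemisphere ellipses, side by side along x, separated by a thin midline
  a <- 0.23 * fov[1]          # semi-axis along x of each hemisphere
  b <- 0.38 * fov[2]          # semi-axis along y
  cx <- 0.25 * fov[1]         # hemisphere center offset from midline

  r_left  <- sqrt(((X + cx) / a)^2 + (Y / b)^2)
  r_right <- sqrt(((X - cx) / a)^2 + (Y / b)^2)
  ob_left  <- r_left  <= 1
  ob_right <- r_right <= 1 & !ob_left   # midline gap keeps them disjoint

  # concentric layers by normalized elliptical radius: glomerular rim
  # (outermost), EPL ring, core
  r <- pmin(r_left, r_right)
  inside <- ob_left | ob_right
  glom <- inside & r > 0.85
  epl  <- inside & r > 0.62 & r <= 0.85
  core <- inside & r <= 0.62

  pd <- matrix(0, nx, ny)
  pd[glom] <- tis$pd["glomerular"]
  pd[epl]  <- tis$pd["epl"]
  pd[core] <- tis$pd["core"]

  if (texture_sd > 0) {
    set.seed(as.integer(seed))
    tex <- matrix(exp(stats::rnorm(nx * ny, 0, texture_sd)), nx, ny)
    pd <- pd * tex
  }
  pd[!inside] <- 0

  t2 <- matrix(tis$t2_background, nx, ny)
  t2[glom] <- tis$t2["glomerular"]; t2[epl] <- tis$t2["epl"]
  t2[core] <- tis$t2["core"]
  t2p <- matrix(tis$t2prime_background, nx, ny)
  t2p[glom] <- tis$t2prime["glomerular"]; t2p[epl] <- tis$t2prime["epl"]
  t2p[core] <- tis$t2prime["core"]

  # lateral glomerular sectors: outward-facing (away from midline) part of the
  # glomerular rim of each hemisphere
  lat_left  <- glom & ob_left  & (X + cx) < -0.35 * a
  lat_right <- glom & ob_right & (X - cx) >  0.35 * a
  glomerular_lateral <- lat_left | lat_right

  background <- !inside
  noise_roi <- matrix(FALSE, nx, ny)
  m <- max(3L, round(0.1 * min(nx, ny)))
  noise_roi[1:m, 1:m] <- TRUE
  noise_roi[(nx - m + 1):nx, 1:m] <- TRUE
  noise_roi[1:m, (ny - m + 1):ny] <- TRUE
  noise_roi[(nx - m + 1):nx, (ny - m + 1):ny] <- TRUE
  noise_roi <- noise_roi & background

  ph <- structure(list(
    pd_map = pd, t2_map = t2, t2prime_map = t2p,
    b0_map = matrix(0, nx, ny),
    pixel_mm = pixel_mm,
    masks = list(ob_left = ob_left, ob_right = ob_right,
                 epl = epl, glomerular_lateral = glomerular_lateral,
                 core = core, background = background,
                 noise_roi = noise_roi),
    seed = as.integer(seed)
  ), class = "ob_phantom")
  validate_phantom(ph)
  ph
}

#' Default tissue parameters for the OB phantom
#'
#' Relative proton density, T2 and T2' (ms) per layer. These are package
#' defaults chosen to give plausible contrast and visible T2* dropout near
#' field perturbers; they are not literature relaxometry values.
#'
#' @return Named list with vectors `pd`, `t2`, `t2prime` (per layer) and
#'   scalars `t2_background`, `t2prime_background`.
#' @export
ob_tissue_defaults <- function() {
  list(
    pd = c(glomerular = 0.9, epl = 1.0, core = 0.8),
    t2 = c(glomerular = 30, epl = 40, core = 35),          # ms
    t2prime = c(glomerular = 40, epl = 50, core = 50),     # ms
    t2_background = 1000, t2prime_background = 1e6
  )
}

pixel_coords <- function(n, delta) (seq_len(n) - 0.5 - n / 2) * delta

validate_phantom <- function(ph) {
  stopifnot(inherits(ph, "ob_phantom"))
  d <- dim(ph$pd_map)
  for (nm in c("t2_map", "t2prime_map", "b0_map"))
    if (!identical(dim(ph[[nm]]), d)) stop("phantom map '", nm, "' shape mismatch")
  if (any(ph$pd_map < 0)) stop("pd_map must be nonnegative")
  if (any(ph$t2_map <= 0) || any(ph$t2prime_map <= 0))
    stop("relaxation times must be positive")
  msk <- ph$masks
  if (any(msk$ob_left & msk$ob_right)) stop("hemisphere masks overlap")
  ob <- msk$ob_left | msk$ob_right
  if (any((msk$epl | msk$glomerular_lateral) & !ob))
    stop("layer masks must lie inside the OB")
  if (any(msk$background & ob)) stop("background overlaps the OB")
  invisible(ph)
}

#' Phantom grid dimensions
#' @param ph An `ob_phantom`.
#' @return Integer vector (nx, ny).
#' @export
phantom_dim <- function(ph) dim(ph$pd_map)

#' Combined T2* map of a phantom
#'
#' `1/T2* = 1/T2 + 1/T2'` pixelwise (ms).
#' @param ph An `ob_phantom`.
#' @return Matrix of T2* values in ms.
#' @export
t2star_map <- function(ph) 1 / (1 / ph$t2_map + 1 / ph$t2prime_map)

#' Air-interface off-resonance field
#'
#' Superimposes 2D dipole-like off-resonance fields onto the phantom's
#' `b0_map`, emulating the field distortion produced by air cavities (nasal
#' cavity, eyes) adjacent to the olfactory bulb. Each perturber is a disk of
#' radius `a` centered at `(cx, cy)` mm whose external field is
#' `peak * (a/r)^2 * cos(2*theta)` (Hz), the in-plane cross-section of a
#' magnetized cylinder; inside the disk the field is set to `peak`.
#'
#' @param phantom An `ob_phantom`.
#' @param perturbers A list of numeric vectors `c(cx, cy, radius, peak)`
#'   (mm, mm, mm, Hz), or a data frame with those four columns.
#' @param b0_scale Dimensionless multiplier applied to the summed field.
#' @param replace If `TRUE` (default) the field replaces `b0_map`; otherwise
#'   it is added to the existing map.
#' @return The phantom with `b0_map` set.
#' @examples
#' ph <- make_ob_phantom(48, 36)
#' ph <- air_interface_field(ph, list(c(0, -4, 0.8, 120)))
#' max(abs(ph$b0_map))
#' @export
air_interface_field <- function(phantom, perturbers, b0_scale = 1,
                                replace = TRUE) {
  validate_phantom(phantom)
  if (is.data.frame(perturbers))
    perturbers <- lapply(seq_len(nrow(perturbers)),
                         function(i) as.numeric(perturbers[i, 1:4]))
  d <- phantom_dim(phantom)
  fov <- d * phantom$pixel_mm
  x <- pixel_coords(d[1], phantom$pixel_mm[1])
  y <- pixel_coords(d[2], phantom$pixel_mm[2])
  X <- matrix(x, d[1], d[2]); Y <- matrix(y, d[1], d[2], byrow = TRUE)

  field <- matrix(0, d[1], d[2])
  for (p in perturbers) {
    p <- as.numeric(p)
    if (length(p) != 4) stop("each perturber is c(cx, cy, radius, peak)")
    a <- p[3]; peak <- p[4]
    if (!is.finite(a) || a <= 0) stop("perturber radius must be positive")
    dx <- X - p[1]; dy <- Y - p[2]
    r2 <- dx^2 + dy^2
    if (all(r2 < a^2)) stop("perturber covers the entire grid")
    # cos(2 theta) = (dx^2 - dy^2) / r^2
    f <- ifelse(r2 >= a^2,
                peak * a^2 * (dx^2 - dy^2) / pmax(r2^2, 1e-12) * 1,
                peak)
    field <- field + f
  }
  field <- field * b0_scale
  phantom$b0_map <- if (replace) field else phantom$b0_map + field
  phantom
}

#' Default air-interface field for the OB phantom
#'
#' Places three air perturbers where the nasal cavity and the two eyes sit
#' relative to the bulbs: a large cavity below the bulbs on the midline and
#' a smaller one beside each hemisphere, slightly posterior. The default
#' peak (1 kHz at the cavity surface, a modest value for air/tissue
#' susceptibility at 15.2 T) produces off-resonance of order 100-300 Hz over
#' the bulbs -- several EPI pixel-bandwidths, i.e. visibly distorted EPI
#' while SPEN remains usable.
#'
#' @param phantom An `ob_phantom`.
#' @param peak_hz Peak off-resonance of the main (nasal) perturber in Hz.
#' @param b0_scale Overall field scale.
#' @return The phantom with `b0_map` populated.
#' @export
default_field <- function(phantom, peak_hz = 1000, b0_scale = 1) {
  fov <- phantom_dim(phantom) * phantom$pixel_mm
  air_interface_field(phantom, list(
    c(0, -0.85 * fov[2], 0.40 * fov[2], peak_hz),
    c(-0.46 * fov[1],  0.30 * fov[2], 0.12 * fov[2], 0.6 * peak_hz),
    c( 0.46 * fov[1],  0.30 * fov[2], 0.12 * fov[2], 0.6 * peak_hz)
  ), b0_scale = b0_scale)
}

#' @export
print.ob_phantom <- function(x, ...) {
  d <- phantom_dim(x)
  cat(sprintf("<ob_phantom> %d x %d px, %.3f x %.3f mm/px (FOV %.1f x %.1f mm)\n",
              d[1], d[2], x$pixel_mm[1], x$pixel_mm[2],
              d[1] * x$pixel_mm[1], d[2] * x$pixel_mm[2]))
  cat(sprintf("  PD in [%.2f, %.2f]; |B0| max %.1f Hz; masks: %s\n",
              min(x$pd_map), max(x$pd_map), max(abs(x$b0_map)),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}
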