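# NIfTI / TSV / YAML input-output for phantoms, runs, and configurations.

#' Write a phantom to NIfTI volumes plus a YAML sidecar
#'
#' One NIfTI volume per map (`pd`, `t2`, `t2prime`, `b0`) and per mask, with
#' a YAML sidecar recording the pixel geometry and the mask names.
#'
#' @param phantom An `ob_phantom`.
#' @param prefix Output path prefix (files `<prefix>_pd.nii.gz`, ...,
#'   `<prefix>.yaml`).
#' @return The sidecar path, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  validate_phantom(phantom)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  pd3 <- c(phantom$pixel_mm, 1)
  maps <- list(pd = phantom$pd_map, t2 = phantom$t2_map,
               t2prime = phantom$t2prime_map, b0 = phantom$b0_map)
  for (nm in names(maps))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]], pixdim = pd3),
                       paste0(prefix, "_", nm, ".nii.gz"))
  for (nm in names(phantom$masks))
    RNifti::writeNifti(RNifti::asNifti(phantom$masks[[nm]] * 1L, pixdim = pd3),
                       paste0(prefix, "_mask_", nm, ".nii.gz"))
  side <- list(pixel_mm = as.numeric(phantom$pixel_mm),
               dim = as.integer(phantom_dim(phantom)),
               maps = names(maps), masks = names(phantom$masks),
               seed = phantom$seed)
  path <- paste0(prefix, ".yaml")
  yaml::write_yaml(side, path)
  invisible(path)
}

#' Read a phantom written by [write_phantom()]
#' @param prefix The path prefix used when writing.
#' @return An `ob_phantom`.
#' @export
read_phantom <- function(prefix) {
  side <- yaml::read_yaml(paste0(prefix, ".yaml"))
  rd <- function(nm) {
    m <- RNifti::readNifti(paste0(prefix, "_", nm, ".nii.gz"))
    matrix(as.numeric(m), side$dim[1], side$dim[2])
  }
  masks <- lapply(side$masks, function(nm) {
    m <- RNifti::readNifti(paste0(prefix, "_mask_", nm, ".nii.gz"))
    matrix(as.numeric(m) > 0, side$dim[1], side$dim[2])
  })
  names(masks) <- side$masks
  ph <- structure(list(
    pd_map = rd("pd"), t2_map = rd("t2"), t2prime_map = rd("t2prime"),
    b0_map = rd("b0"), pixel_mm = as.numeric(side$pixel_mm),
    masks = masks, seed = side$seed %||% 1L
  ), class = "ob_phantom")
  validate_phantom(ph)
  ph
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated run: 4D NIfTI + events TSV + provenance YAML
#'
#' @param ds A `timeseries_dataset`.
#' @param dir Output directory (created if needed). Files: `bold.nii.gz`,
#'   `events.tsv`, `provenance.yaml`, and the phantom under `phantom_*`.
#' @return `dir`, invisibly.
#' @export
write_run <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pm <- ds$phantom$pixel_mm
  nii <- RNifti::asNifti(ds$volumes,
                         pixdim = c(pm, 1, ds$volume_interval_s))
  RNifti::writeNifti(nii, file.path(dir, "bold.nii.gz"))
  ev <- paradigm_events(ds$paradigm)
  utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  prov <- list(
    paradigm = unclass(ds$paradigm)[c("air_s", "odor_s", "n_events",
                                      "volume_interval_s", "n_volumes",
                                      "onset_ramp_s")],
    params = unclass(ds$provenance$params),
    bold = unclass(ds$provenance$bold)[c("odor", "delta_r2star_hz",
                                         "concentration_ppm",
                                         "lateralization", "t2_fraction")],
    nuisance = ds$provenance$nuisance,
    seed = ds$provenance$seed, lambda = ds$provenance$lambda
  )
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  write_phantom(ds$phantom, file.path(dir, "phantom"))
  invisible(dir)
}

#' Read a run written by [write_run()]
#' @param dir The run directory.
#' @return A `timeseries_dataset`.
#' @export
read_run <- function(dir) {
  prov <- yaml::read_yaml(file.path(dir, "provenance.yaml"))
  if (!file.exists(file.path(dir, "events.tsv")))
    stop("missing paradigm events file in ", dir)
  vols <- RNifti::readNifti(file.path(dir, "bold.nii.gz"))
  vols <- array(as.numeric(vols), dim = dim(vols))
  par <- do.call(build_paradigm, prov$paradigm)
  ph <- read_phantom(file.path(dir, "phantom"))
  sq <- prov$params
  params <- seq_params(kind = sq$kind, fov_mm = as.numeric(sq$fov_mm),
                       matrix_size = as.integer(sq$matrix_size),
                       tr_s = sq$tr_s, te_s = sq$te_s, tacq_s = sq$tacq_s,
                       chirp_duration_s = sq$chirp_duration_s,
                       delta_s = sq$delta_s, chirp_factor = sq$chirp_factor,
                       n_averages = sq$n_averages,
                       noise_sigma = sq$noise_sigma,
                       zoom_center_mm = sq$zoom_center_mm)
  structure(list(volumes = vols, volume_interval_s = par$volume_interval_s,
                 paradigm = par, phantom = ph,
                 provenance = list(params = params, bold = prov$bold,
                                   nuisance = prov$nuisance,
                                   seed = prov$seed, lambda = prov$lambda)),
            class = "timeseries_dataset")
}

#' Write an activation map as NIfTI plus a YAML report
#' @param map An `activation_map`.
#' @param prefix Output prefix.
#' @param pixel_mm Pixel geometry.
#' @return The prefix, invisibly.
#' @export
write_map <- function(map, prefix, pixel_mm = c(1, 1)) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  pd3 <- c(pixel_mm, 1)
  RNifti::writeNifti(RNifti::asNifti(map$stat, pixdim = pd3),
                     paste0(prefix, "_stat.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$mask_supra * 1L, pixdim = pd3),
                     paste0(prefix, "_supra.nii.gz"))
  yaml::write_yaml(list(stat_type = map$stat_type, df = map$df,
                        p_threshold = map$p_threshold,
                        correction = map$correction,
                        n_supra = sum(map$mask_supra)),
                   paste0(prefix, "_report.yaml"))
  invisible(prefix)
}
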