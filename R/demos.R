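# Figure-style demonstrations: each writes the plotted data as CSV (and the
# figure as PNG when `png = TRUE`) so every demo is reproducible from its
# configuration and seed alone.

#' Reproduce a figure-style demonstration
#'
#' * `"timecourse"`: raw whole-OB time course of a default run and its
#'   first-level t-map.
#' * `"sequences"`: image-quality comparison of the four sequence variants
#'   under the default inhomogeneity field (metric table).
#' * `"nostril"`: left/right/both hemisphere time courses with the left
#'   nostril plugged.
#' * `"concentration"`: epoch-averaged responses at 60/300/500/700 ppm.
#' * `"odors"`: mean responses and maps for aversive/appetitive/neutral
#'   odors.
#'
#' @param which One of `"timecourse"`, `"sequences"`, `"nostril"`,
#'   `"concentration"`, `"odors"`.
#' @param out_dir Output directory.
#' @param config Base configuration; the demos shrink the paradigm relative
#'   to the full 700-volume protocol to stay interactive.
#' @param png Also write PNG figures.
#' @return List of computed objects, invisibly; artifacts on disk.
#' @export
demo_figure <- function(which = c("timecourse", "sequences", "nostril",
                                  "concentration", "odors"),
                        out_dir, config = demo_config(), png = FALSE) {
  which <- match.arg(which)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(config)
  out <- switch(which,
    timecourse = demo_timecourse(obj, config, out_dir, png),
    sequences = {
      tab <- run_compare_sequences(config)
      utils::write.csv(tab, file.path(out_dir, "sequence_metrics.csv"),
                       row.names = FALSE)
      list(table = tab)
    },
    nostril = demo_nostril(obj, config, out_dir, png),
    concentration = demo_concentration(obj, config, out_dir, png),
    odors = demo_odors(obj, config, out_dir, png))
  invisible(out)
}

#' Reduced configuration for interactive demonstrations
#' @param seed Master seed.
#' @return A run configuration with a 5-event, 190-volume paradigm on a
#'   48 x 36 grid.
#' @export
demo_config <- function(seed = 1L) {
  modifyList(default_run_config(seed), list(
    phantom = list(nx = 48L, ny = 36L, pixel_mm = c(10.4 / 48, 7.5 / 36)),
    paradigm = list(air_s = 50, odor_s = 26, n_events = 5L,
                    volume_interval_s = 2, n_volumes = 190L,
                    onset_ramp_s = 10)))
}

demo_timecourse <- function(obj, config, out_dir, png) {
  ds <- simulate_run(obj$phantom, obj$params, obj$paradigm, obj$bold,
                     nuisance = obj$nuisance,
                     seed = split_seed(config$seed, "run"))
  ob <- obj$phantom$masks$ob_left | obj$phantom$masks$ob_right
  series <- roi_timecourse(ds, ob)
  resp <- percent_change(series, obj$paradigm)
  map <- glm_first_level(smooth_gaussian(ds, config$analysis$fwhm_mm),
                         design_matrix(obj$paradigm),
                         p_threshold = config$analysis$p_threshold)
  utils::write.csv(tibble::tibble(time_s = obj$paradigm$volume_times_s,
                                  ob = series),
                   file.path(out_dir, "timecourse.csv"), row.names = FALSE)
  utils::write.csv(resp$curve, file.path(out_dir, "epoch_response.csv"),
                   row.names = FALSE)
  if (png) {
    save_png(plot_timecourse(series, obj$paradigm),
             file.path(out_dir, "timecourse.png"))
    save_png(autoplot(map), file.path(out_dir, "tmap.png"))
  }
  list(response = resp, map = map)
}

demo_nostril <- function(obj, config, out_dir, png) {
  rows <- list()
  for (side in c("left")) {
    bm <- nostril_scenario(obj$bold, side)
    ds <- simulate_run(obj$phantom, obj$params, obj$paradigm, bm,
                       nuisance = obj$nuisance,
                       seed = split_seed(config$seed, paste0("plug_", side)))
    msk <- obj$phantom$masks
    rows[[side]] <- tibble::tibble(
      plugged = side,
      time_s = obj$paradigm$volume_times_s,
      left = roi_timecourse(ds, msk$ob_left),
      right = roi_timecourse(ds, msk$ob_right),
      both = roi_timecourse(ds, msk$ob_left | msk$ob_right))
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "nostril_timecourses.csv"),
                   row.names = FALSE)
  list(table = tab)
}

demo_concentration <- function(obj, config, out_dir, png) {
  concs <- c(60, 300, 500, 700)
  rows <- lapply(concs, function(cc) {
    bm <- obj$bold; bm$concentration_ppm <- cc
    ds <- simulate_run(obj$phantom, obj$params, obj$paradigm, bm,
                       nuisance = obj$nuisance,
                       seed = split_seed(config$seed, paste0("conc", cc)))
    act <- activation_map_r2star(obj$phantom, bm) > 0
    resp <- percent_change(roi_timecourse(ds, act), obj$paradigm)
    tibble::tibble(concentration_ppm = cc, peak_pct = resp$peak_pct)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "concentration_response.csv"),
                   row.names = FALSE)
  list(table = tab)
}

demo_odors <- function(obj, config, out_dir, png) {
  odors <- c("aversive", "appetitive", "neutral")
  rows <- list(); maps <- list()
  for (od in odors) {
    bm <- bold_model(odor = od,
                     delta_r2star_hz = config$bold$delta_r2star_hz,
                     concentration_ppm = 60)
    ds <- simulate_run(obj$phantom, obj$params, obj$paradigm, bm,
                       nuisance = obj$nuisance,
                       seed = split_seed(config$seed, paste0("odor_", od)))
    act <- activation_map_r2star(obj$phantom, bm) > 0
    resp <- percent_change(roi_timecourse(ds, act), obj$paradigm)
    maps[[od]] <- glm_first_level(smooth_gaussian(ds, config$analysis$fwhm_mm),
                                  design_matrix(obj$paradigm),
                                  p_threshold = config$analysis$p_threshold)
    rows[[od]] <- tibble::tibble(odor = od, peak_pct = resp$peak_pct,
                                 n_supra = sum(maps[[od]]$mask_supra))
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "odor_responses.csv"),
                   row.names = FALSE)
  list(table = tab, maps = maps)
}

save_png <- function(p, path, width = 6, height = 4) {
  grDevices::png(path, width = width * 100, height = height * 100)
  print(p)
  grDevices::dev.off()
}
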