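# End-to-end orchestration: simulate -> (gate/moco) -> localize -> track ->
# maps -> quantify, with a reproducible run manifest.

stage_log <- function(manifest, stage, t0, ...) {
  entry <- list(stage = stage, seconds = round(as.numeric(Sys.time()) - t0, 3),
                ...)
  manifest$stages[[stage]] <- entry
  message(sprintf("[srulm] %-10s %6.1fs %s", stage, entry$seconds,
                  paste(names(list(...)), unlist(list(...)),
                        sep = "=", collapse = " ")))
  manifest
}

#' Run the full pipeline from a config
#'
#' Executes the requested stages in order on a simulated acquisition:
#' ground-truth generation and stack rendering, cardiac gating plus
#' two-level motion correction (`no_gating = TRUE` reproduces the ex vivo
#' pathway: no gating, no inter-cycle stage), localization, tracking, map
#' rendering and quantification. All artifacts are written under the run
#' directory; no stage mutates its inputs. A manifest sufficient to
#' reproduce the run is written at the end.
#'
#' @param config path to a YAML config or a config list
#'   (see [default_pipeline_config()]).
#' @param out_dir run directory (overrides the config's `output$dir`).
#' @param no_gating disable gating and inter-cycle correction (ex vivo).
#' @param moco run tissue motion correction at all? (FALSE when the
#'   simulation has no tissue motion).
#' @return invisible manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         no_gating = FALSE, moco = NULL) {
  cfg <- read_pipeline_config(config)
  out_dir <- out_dir %||% cfg$output$dir %||% "srulm_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("srulm")),
                   stages = list(), seeds = list())
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(cfg, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  g <- cfg$geometry
  geom <- acq_geometry(n_elements = g$n_elements, pitch_um = g$pitch_um,
                       virtual_source_depth_mm = g$virtual_source_depth_mm,
                       sound_speed = g$sound_speed, f_tx_mhz = g$f_tx_mhz,
                       f_center_mhz = g$f_center_mhz, prf = g$prf,
                       steering_angles_deg = unlist(g$steering_angles_deg),
                       n_am_pulses = g$n_am_pulses,
                       imaging_depth_mm = g$imaging_depth_mm)
  fr <- compounded_frame_rate(geom$prf, length(geom$steering_angles_deg),
                              geom$n_am_pulses)

  # ---- simulate ----
  t0 <- as.numeric(Sys.time())
  sim <- cfg$simulation
  seed <- sim$seed %||% 1L
  manifest$seeds$simulation <- seed
  tree <- vessel_phantom(sim$phantom %||% "branching",
                         centre_mm = unlist(sim$centre_mm %||% c(0, 70)),
                         separation_um = sim$separation_um %||% 300,
                         length_mm = sim$length_mm %||% 14,
                         diameter_um = sim$diameter_um %||% 300,
                         seed = seed)
  gt <- simulate_transit(tree, duration_s = sim$duration_s %||% 5,
                         frame_rate = fr,
                         bubble_rate = sim$bubble_rate %||% 20, seed = seed)
  mot <- sim$motion %||% list(enabled = FALSE)
  with_motion <- isTRUE(mot$enabled)
  if (with_motion) {
    xr <- range(vapply(tree$segments, function(s) range(s$points_um[, 1]),
                       numeric(2))) / 1e3 + c(-8, 8)
    zr <- range(vapply(tree$segments, function(s) range(s$points_um[, 2]),
                       numeric(2))) / 1e3 + c(-8, 8)
    mm <- motion_model(period_s = mot$period_s %||% 0.8,
                       peak_um = mot$peak_um %||% 1500,
                       domain = list(x_mm = xr, z_mm = zr), seed = seed)
    gt <- apply_tissue_motion(gt, mm)
  }
  span_x <- range(vapply(tree$segments,
                         function(s) range(s$points_um[, 1]), numeric(2)))
  span_z <- range(vapply(tree$segments,
                         function(s) range(s$points_um[, 2]), numeric(2)))
  grid <- cart_grid((span_z + c(-6e3, 6e3)) / 1e3,
                    (span_x + c(-6e3, 6e3)) / 1e3)
  psf <- psf_model()
  sim_out <- render_ceus_stack(gt, psf, grid, snr_db = sim$snr_db %||% 30,
                               seed = seed)
  write_stack_tiff(sim_out$ceus, file.path(out_dir, "ceus.tif"),
                   meta = list(frame_rate = fr, seed = seed,
                               dz_um = grid$dz_um, dx_um = grid$dx_um))
  write_stack_tiff(sim_out$bmode, file.path(out_dir, "bmode.tif"),
                   meta = list(frame_rate = fr, seed = seed))
  write_table_full(as.data.frame(gt), file.path(out_dir, "ground_truth.csv"))
  manifest <- stage_log(manifest, "simulate", t0,
                        frames = dim(sim_out$ceus)[3],
                        bubbles = length(unique(gt$id)))

  # ---- gating + motion correction ----
  t0 <- as.numeric(Sys.time())
  proc <- cfg$processing %||% list()
  ceus <- sim_out$ceus
  do_moco <- moco %||% with_motion
  if (do_moco) {
    if (!no_gating && isTRUE(proc$gating %||% TRUE)) {
      ci <- gate_diastole(sim_out$bmode, fr)
      runs <- ci$diastole_frames
    } else {
      runs <- list(seq_len(dim(ceus)[3]))
    }
    corrected <- list()
    cycle_means <- list()
    for (rn in runs) {
      mc <- moco_cycle(sim_out$bmode[, , rn, drop = FALSE],
                       ceus[, , rn, drop = FALSE],
                       spacing = proc$bspline_spacing %||% 32L,
                       lambda = proc$tp_lambda %||% 0.01)
      corrected[[length(corrected) + 1L]] <- mc$ceus_corrected
      cycle_means[[length(cycle_means) + 1L]] <-
        log_compress(apply(pmax(mc$ceus_corrected, 0), c(1, 2), mean))
    }
    if (!no_gating && length(corrected) > 1L) {
      rig <- intercycle_rigid(cycle_means)
      for (k in seq_along(corrected)[-1L]) {
        tf <- list(affine = rig[[k]]$affine, ctrl_r = NULL, ctrl_c = NULL,
                   dims = dim(ceus)[1:2])
        for (f in seq_len(dim(corrected[[k]])[3]))
          corrected[[k]][, , f] <- apply_transform_image(
            corrected[[k]][, , f], tf)
      }
    }
    ceus <- array(unlist(corrected),
                  c(dim(ceus)[1:2], sum(vapply(corrected,
                                               function(x) dim(x)[3], 0L))))
    kept_frames <- unlist(runs)
  } else {
    kept_frames <- seq_len(dim(ceus)[3])
  }
  manifest <- stage_log(manifest, "moco", t0, frames_kept = length(kept_frames),
                        gating = !no_gating && do_moco)

  # ---- localize ----
  t0 <- as.numeric(Sys.time())
  locs <- localize_stack(ceus, grid, psf = psf,
                         sr_um = proc$sr_um %||% 13.5,
                         ncc_threshold = proc$ncc_threshold %||% 0.5)
  write_localizations_csv(locs, file.path(out_dir, "localizations.csv"))
  manifest <- stage_log(manifest, "localize", t0, n = nrow(locs))

  # ---- track ----
  t0 <- as.numeric(Sys.time())
  tracks <- track_localizations(locs, fr,
                                max_speed_mm_s = proc$max_speed_mm_s %||% 150,
                                min_frames = proc$min_track_frames %||% 4L)
  write_tracks_csv(tracks, file.path(out_dir, "tracks.csv"))
  manifest <- stage_log(manifest, "track", t0,
                        tracks = length(unique(tracks$track_id)))

  # ---- maps ----
  t0 <- as.numeric(Sys.time())
  if (nrow(tracks)) {
    maps <- render_maps(tracks, geom = geom)
    write_stack_tiff(maps$density, file.path(out_dir, "density.tif"),
                     meta = list(cell_um = maps$grid$cell_um,
                                 fwhm_um = maps$fwhm_um))
    write_stack_tiff(maps$speed, file.path(out_dir, "speed.tif"),
                     meta = list(cell_um = maps$grid$cell_um))
    dirm <- maps$direction; dirm[is.na(dirm)] <- -1
    write_stack_tiff(dirm, file.path(out_dir, "direction.tif"),
                     meta = list(cell_um = maps$grid$cell_um,
                                 undefined = -1))
    png::writePNG(compose_hsv(maps, "speed"),
                  file.path(out_dir, "speed_preview.png"))
  } else maps <- NULL
  manifest <- stage_log(manifest, "maps", t0)

  # ---- quantify ----
  t0 <- as.numeric(Sys.time())
  if (!is.null(maps)) {
    vd <- vessel_diameters(maps$density_raw, maps$grid$cell_um)
    if (length(vd$mids_um))
      write_table_full(data.frame(mid_um = vd$mids_um,
                                  proportion = vd$proportion),
                       file.path(out_dir, "diameter_hist.csv"))
    ss <- speed_stats(maps$speed)
    if (length(ss$mids_mm_s))
      write_table_full(data.frame(mid_mm_s = ss$mids_mm_s,
                                  proportion = ss$proportion),
                       file.path(out_dir, "speed_hist.csv"))
    if (length(unique(tracks$track_id)) >= 2L) {
      fr_res <- frc_resolution(tracks, maps$grid,
                               seed = proc$seed %||% 1L)
      write_table_full(data.frame(freq_per_um = fr_res$freq_um,
                                  frc = fr_res$frc,
                                  threshold = fr_res$threshold),
                       file.path(out_dir, "frc_curve.csv"))
      manifest$frc_resolution_um <- fr_res$resolution_um
    }
  }
  manifest <- stage_log(manifest, "quantify", t0)

  manifest$outputs <- list.files(out_dir)
  tmp <- file.path(out_dir, ".manifest.tmp")
  yaml::write_yaml(manifest, tmp)
  file.rename(tmp, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
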