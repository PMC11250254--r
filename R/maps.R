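# Super-resolution map rendering: trajectory accumulation on the 13.5 um
# localization grid, Gaussian-widened density, disk-smoothed speed and
# direction maps, HSV composition, and flow animation.

#' Super-resolved rendering grid
#'
#' Square-cell grid at the localization pitch (13.5 um by default).
#'
#' @param x_range_um,z_range_um length-2 extents, um.
#' @param cell_um cell size.
#' @return object of class `sr_grid` with `x_um`, `z_um` cell-centre vectors.
#' @export
sr_grid <- function(x_range_um, z_range_um, cell_um = 13.5) {
  check_positive(cell_um)
  nx <- max(2L, ceiling(diff(range(x_range_um)) / cell_um) + 1L)
  nz <- max(2L, ceiling(diff(range(z_range_um)) / cell_um) + 1L)
  structure(list(
    x_um = min(x_range_um) + (seq_len(nx) - 1) * cell_um,
    z_um = min(z_range_um) + (seq_len(nz) - 1) * cell_um,
    cell_um = cell_um), class = "sr_grid")
}

#' @rdname sr_grid
#' @param tracks a `track_set`. @param pad_um margin around the tracks.
#' @export
sr_grid_for_tracks <- function(tracks, cell_um = 13.5, pad_um = 20 * cell_um) {
  if (!nrow(tracks)) stopf("empty track set")
  sr_grid(range(tracks$x_um) + c(-pad_um, pad_um),
          range(tracks$z_um) + c(-pad_um, pad_um), cell_um)
}

# Supercover line rasterization: every cell a segment passes through.
# Returns linear cell indices into the [nz, nx] map.
supercover_cells <- function(grid, x0, z0, x1, z1) {
  cell <- grid$cell_um
  cx0 <- (x0 - grid$x_um[1]) / cell + 1
  cz0 <- (z0 - grid$z_um[1]) / cell + 1
  cx1 <- (x1 - grid$x_um[1]) / cell + 1
  cz1 <- (z1 - grid$z_um[1]) / cell + 1
  n <- max(2L, ceiling(2 * max(abs(cx1 - cx0), abs(cz1 - cz0))) + 1L)
  t <- seq(0, 1, length.out = n)
  ci <- round(cx0 + t * (cx1 - cx0))
  ri <- round(cz0 + t * (cz1 - cz0))
  nz <- length(grid$z_um); nx <- length(grid$x_um)
  ok <- ri >= 1 & ri <= nz & ci >= 1 & ci <= nx
  unique((ci[ok] - 1) * nz + ri[ok])
}

accumulate_tracks <- function(tracks, grid) {
  nz <- length(grid$z_um); nx <- length(grid$x_um)
  dens <- matrix(0, nz, nx)
  spd <- matrix(0, nz, nx)
  vx <- matrix(0, nz, nx)
  vz <- matrix(0, nz, nx)
  if (nrow(tracks)) for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    if (n < 2L) next
    for (k in seq_len(n - 1L)) {
      cells <- supercover_cells(grid, tr$x_um[k], tr$z_um[k],
                                tr$x_um[k + 1L], tr$z_um[k + 1L])
      s <- sqrt(tr$vx_mm_s[k]^2 + tr$vz_mm_s[k]^2)
      dens[cells] <- dens[cells] + 1
      spd[cells] <- spd[cells] + s
      vx[cells] <- vx[cells] + tr$vx_mm_s[k]
      vz[cells] <- vz[cells] + tr$vz_mm_s[k]
    }
  }
  list(dens = dens, spd = spd, vx = vx, vz = vz)
}

#' Render the localization density map
#'
#' Trajectories (straight lines between paired positions) are rasterized on
#' the super-resolved grid with supercover traversal and optionally widened
#' by a 2D Gaussian whose FWHM defaults to a quarter of the transmit
#' wavelength (`fwhm_um = NULL` renders the raw accumulation at the pixel
#' size).
#'
#' @param tracks a `track_set`. @param grid an [sr_grid()].
#' @param fwhm_um Gaussian FWHM in um, or `NULL` for no widening.
#' @return density matrix `[nz, nx]`.
#' @export
render_density <- function(tracks, grid, fwhm_um = NULL) {
  acc <- accumulate_tracks(tracks, grid)
  d <- acc$dens
  if (!is.null(fwhm_um) && fwhm_um > 0) {
    sigma <- fwhm_um / 2.3548 / grid$cell_um
    d <- conv2_zero(d, gaussian_kernel(sigma, max_size = min(dim(d))))
    d <- pmax(d, 0)                       # FFT roundoff can dip below zero
  }
  d
}

#' Render the flow-speed map
#'
#' Per-step speeds accumulated on trajectory cells; both the accumulated
#' speed and the accumulated density are smoothed with a disk whose diameter
#' equals the Gaussian FWHM, and the map is their ratio where density is
#' positive (zero elsewhere), which keeps the smoothing kernel from biasing
#' the speed estimate.
#'
#' @inheritParams render_density
#' @param fwhm_um disk diameter, um (also the density-widening FWHM).
#' @return speed matrix, mm/s.
#' @export
render_speed <- function(tracks, grid, fwhm_um = NULL) {
  acc <- accumulate_tracks(tracks, grid)
  num <- acc$spd; den <- acc$dens
  if (!is.null(fwhm_um) && fwhm_um > 0) {
    k <- disk_kernel(fwhm_um / grid$cell_um)
    num <- pmax(conv2_zero(num, k), 0); den <- pmax(conv2_zero(den, k), 0)
  }
  out <- matrix(0, nrow(num), ncol(num))
  pos <- den > 1e-9
  out[pos] <- num[pos] / den[pos]
  out
}

#' Render the flow-direction map
#'
#' Velocity components accumulated on trajectory cells, disk-smoothed and
#' divided by the smoothed density; the direction is the angle of the
#' averaged vector. Convention: 0 deg = +x (lateral right), 90 deg = -z
#' (towards the probe). Cells whose averaged vector is degenerate (near
#' zero) are `NA`.
#'
#' @inheritParams render_speed
#' @return direction matrix in degrees `[0, 360)`, `NA` where undefined.
#' @export
render_direction <- function(tracks, grid, fwhm_um = NULL) {
  acc <- accumulate_tracks(tracks, grid)
  vx <- acc$vx; vz <- acc$vz; den <- acc$dens
  if (!is.null(fwhm_um) && fwhm_um > 0) {
    k <- disk_kernel(fwhm_um / grid$cell_um)
    vx <- conv2_zero(vx, k); vz <- conv2_zero(vz, k)
    den <- pmax(conv2_zero(den, k), 0)
  }
  out <- matrix(NA_real_, nrow(vx), ncol(vx))
  pos <- den > 1e-9
  mvx <- vx[pos] / den[pos]; mvz <- vz[pos] / den[pos]
  mag <- sqrt(mvx^2 + mvz^2)
  ang <- (atan2(-mvz, mvx) * 180 / pi) %% 360
  ang[mag < 1e-9] <- NA_real_
  out[pos] <- ang
  out
}

#' Render the full SR map bundle
#'
#' @inheritParams render_speed
#' @param geom optional [acq_geometry()]; supplies the default FWHM
#'   (transmit wavelength / 4).
#' @return object of class `sr_maps`: `density`, `density_raw`, `speed`,
#'   `direction`, `grid`, `fwhm_um`.
#' @export
render_maps <- function(tracks, grid = NULL, fwhm_um = NULL, geom = NULL) {
  if (is.null(grid)) grid <- sr_grid_for_tracks(tracks)
  if (is.null(fwhm_um) && !is.null(geom))
    fwhm_um <- us_wavelength_um(geom$sound_speed, geom$f_tx_hz / 1e6) / 4
  structure(list(
    density = render_density(tracks, grid, fwhm_um),
    density_raw = render_density(tracks, grid, NULL),
    speed = render_speed(tracks, grid, fwhm_um),
    direction = render_direction(tracks, grid, fwhm_um),
    grid = grid, fwhm_um = fwhm_um), class = "sr_maps")
}

#' Compose an HSV flow image
#'
#' Hue encodes speed or direction, value encodes (normalized) density,
#' saturation is fixed; zero-density pixels are black.
#'
#' @param maps an `sr_maps` bundle.
#' @param mode `"speed"` or `"direction"`.
#' @param sat saturation. @param gamma value-channel gamma on the density.
#' @param speed_max hue-scale ceiling, mm/s (defaults to the 99th
#'   percentile of the speed map).
#' @return array `[nz, nx, 3]` of RGB values in `[0, 1]`.
#' @export
compose_hsv <- function(maps, mode = c("speed", "direction"), sat = 0.9,
                        gamma = 0.5, speed_max = NULL) {
  mode <- match.arg(mode)
  dens <- pmax(maps$density, 0)
  v <- if (max(dens) > 0) (dens / max(dens))^gamma else dens
  if (mode == "speed") {
    sp <- maps$speed
    if (is.null(speed_max))
      speed_max <- if (any(sp > 0)) stats::quantile(sp[sp > 0], 0.99) else 1
    h <- 0.667 * (1 - pmin(sp / speed_max, 1))    # blue (slow) -> red (fast)
  } else {
    h <- (maps$direction %||% 0) / 360
    h[is.na(h)] <- 0
    v[is.na(maps$direction)] <- v[is.na(maps$direction)] * 0
  }
  col <- grDevices::hsv(pmin(pmax(h, 0), 1), sat, pmin(pmax(v, 0), 1))
  rgb <- grDevices::col2rgb(col) / 255
  out <- array(0, c(nrow(dens), ncol(dens), 3))
  out[, , 1] <- matrix(rgb[1, ], nrow(dens))
  out[, , 2] <- matrix(rgb[2, ], nrow(dens))
  out[, , 3] <- matrix(rgb[3, ], nrow(dens))
  out
}

#' Animate bubble flow along trajectories
#'
#' Advects a marker along each track at its estimated speed and renders one
#' marker table (and optionally a PNG) per output frame. Markers moving
#' upwards (towards the probe, negative z velocity) use the warm palette,
#' downward-moving markers the cold palette.
#'
#' @param tracks a `track_set`. @param fps output frame rate.
#' @param out_dir optional directory for PNG frames.
#' @param duration_s animation span (defaults to the track time span).
#' @param maps optional `sr_maps` used as the background.
#' @return invisible list of per-frame data.frames
#'   (`x_um, z_um, palette`), attribute `files` when PNGs were written.
#' @export
animate_flow <- function(tracks, fps = 30, out_dir = NULL,
                         duration_s = NULL, maps = NULL) {
  fr <- attr(tracks, "frame_rate") %||% 305
  if (!nrow(tracks)) stopf("empty track set")
  t0 <- (min(tracks$frame) - 1) / fr
  t1 <- (max(tracks$frame) - 1) / fr
  duration_s <- duration_s %||% max(t1 - t0, 1 / fps)
  n_out <- max(1L, ceiling(duration_s * fps))
  frames <- vector("list", n_out)
  ids <- unique(tracks$track_id)
  for (k in seq_len(n_out)) {
    t <- t0 + (k - 1) / fps
    rows <- list()
    for (id in ids) {
      tr <- tracks[tracks$track_id == id, , drop = FALSE]
      tt <- (tr$frame - 1) / fr
      if (t < tt[1] || t > tt[length(tt)]) next
      x <- stats::approx(tt, tr$x_um, xout = t)$y
      z <- stats::approx(tt, tr$z_um, xout = t)$y
      vz <- stats::approx(tt, tr$vz_mm_s, xout = t, rule = 2)$y
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = id, x_um = x, z_um = z,
        palette = if (vz < 0) "warm" else "cold")
    }
    frames[[k]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(track_id = integer(), x_um = numeric(), z_um = numeric(),
                 palette = character())
  }
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    grid <- if (!is.null(maps)) maps$grid else sr_grid_for_tracks(tracks)
    bg <- if (!is.null(maps)) maps$density / max(maps$density, 1e-12) else
      matrix(0, length(grid$z_um), length(grid$x_um))
    files <- character(n_out)
    for (k in seq_len(n_out)) {
      img <- array(rep(bg * 0.5, 3), c(dim(bg), 3))
      fr_k <- frames[[k]]
      if (nrow(fr_k)) {
        ri <- round((fr_k$z_um - grid$z_um[1]) / grid$cell_um) + 1
        ci <- round((fr_k$x_um - grid$x_um[1]) / grid$cell_um) + 1
        ok <- ri >= 1 & ri <= nrow(bg) & ci >= 1 & ci <= ncol(bg)
        warm <- fr_k$palette == "warm"
        img[cbind(ri[ok & warm], ci[ok & warm], 1)] <- 1
        img[cbind(ri[ok & !warm], ci[ok & !warm], 3)] <- 1
      }
      files[k] <- file.path(out_dir, sprintf("frame_%04d.png", k))
      png::writePNG(img, files[k])
    }
  }
  invisible(structure(frames, files = files, fps = fps))
}
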