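# Shared fixture builders (everything generated in code, fixed seeds).

# Smooth random texture in [0, 1], speckle-like at the given correlation
# scale; stands in for a log-compressed B-mode frame.
make_texture <- function(nr, nc, sigma = 3, seed = 5) {
  withr::with_seed(seed, {
    raw <- matrix(rnorm(nr * nc), nr, nc)
    k <- srulm:::gaussian_kernel(sigma, max_size = min(nr, nc))
    sm <- srulm:::conv2_zero(raw, k)
    (sm - min(sm)) / diff(range(sm))
  })
}

# Ground truth with a single bubble record stream (one frame).
single_bubble_gt <- function(x_um, z_um, intensity = 1, frame_rate = 305) {
  structure(data.frame(frame = 1L, id = 1L, x_um = x_um, z_um = z_um,
                       vx_mm_s = 0, vz_mm_s = 0, intensity = intensity),
            frame_rate = frame_rate, n_frames = 1L, seed = 0L,
            class = c("ground_truth", "data.frame"))
}

# Isolated point-target frames at a depth; returns per-target localization
# errors (um) of the NCC + weighted-centroid localizer, the acceptance
# measurement reused by the criterion test and by module tests.
localization_errors <- function(depth_mm, n = 50, snr_db = 40, seed = 7) {
  psf <- psf_model()
  w <- psf_at(psf, depth_mm)
  sx <- w$lat_fwhm_um / 2.3548; sz <- w$ax_fwhm_um / 2.3548
  half_x <- 4.2 * sx; half_z <- 6 * sz
  errs <- rep(NA_real_, n)
  rng <- withr::with_seed(seed, list(
    x0 = runif(n, -135, 135),
    z0 = depth_mm * 1e3 + runif(n, -67.8, 67.8)))
  grid <- cart_grid(c((depth_mm * 1e3 - half_z) / 1e3,
                      (depth_mm * 1e3 + half_z) / 1e3),
                    c(-half_x / 1e3, half_x / 1e3))
  szp <- sz / grid$dz_um; sxp <- sx / grid$dx_um
  hz <- ceiling(2.5 * szp); hx <- ceiling(2.5 * sxp)
  tpl <- outer(exp(-((-hz):hz)^2 / (2 * szp^2)),
               exp(-((-hx):hx)^2 / (2 * sxp^2)))
  for (i in seq_len(n)) {
    gt <- single_bubble_gt(rng$x0[i], rng$z0[i])
    sim <- render_ceus_stack(gt, psf, grid, snr_db = snr_db,
                             seed = seed + i, bmode = FALSE)
    frame <- sim$ceus[, , 1]
    mask <- threshold_frame(frame)
    ps <- extract_patches(mask, frame)
    if (!length(ps)) next
    p <- ps[[which.max(vapply(ps, function(q) sum(q$img), 0))]]
    l <- localize_patch(p, tpl, grid)
    if (!nrow(l)) next
    j <- which.min((l$x_um - rng$x0[i])^2 + (l$z_um - rng$z0[i])^2)
    errs[i] <- sqrt((l$x_um[j] - rng$x0[i])^2 + (l$z_um[j] - rng$z0[i])^2)
  }
  errs
}

# Two bubbles on crossing straight paths, grid-snapped; ground truth ids.
crossing_scene <- function(seed, frame_rate = 305, n_fr = 12) {
  withr::with_seed(seed, {
    t <- (0:(n_fr - 1)) / frame_rate
    v1 <- c(runif(1, 60, 100), runif(1, 30, 50)) * 1e3
    v2 <- c(-runif(1, 60, 100), runif(1, 30, 50)) * 1e3
    p0_1 <- c(0, 60000) - v1 * 6 / frame_rate
    p0_2 <- c(runif(1, 300, 700), 60000) - v2 * 6 / frame_rate
    d <- rbind(
      data.frame(frame = 1:n_fr, id = 1L, x_um = p0_1[1] + v1[1] * t,
                 z_um = p0_1[2] + v1[2] * t, intensity = 1.0),
      data.frame(frame = 1:n_fr, id = 2L, x_um = p0_2[1] + v2[1] * t,
                 z_um = p0_2[2] + v2[2] * t, intensity = 1.05))
    d$x_um <- round(d$x_um / 13.5) * 13.5
    d$z_um <- round(d$z_um / 13.5) * 13.5
    d
  })
}

# Identity switches of a track set against ground-truth ids.
count_switches <- function(ts, gt) {
  s <- 0L
  for (tid in unique(ts$track_id)) {
    tr <- ts[ts$track_id == tid, , drop = FALSE]
    ids <- vapply(seq_len(nrow(tr)), function(i) {
      g <- gt[gt$frame == tr$frame[i], , drop = FALSE]
      g$id[which.min((g$x_um - tr$x_um[i])^2 + (g$z_um - tr$z_um[i])^2)]
    }, 0L)
    s <- s + sum(ids[-1] != ids[-length(ids)])
  }
  s
}

# Fraction of frame-to-frame links that connect localizations of the same
# ground-truth bubble.
link_accuracy <- function(ts, gt, cell = 13.5) {
  key <- paste(gt$frame, round(gt$x_um / cell), round(gt$z_um / cell))
  id_of <- stats::setNames(gt$id, key)
  ok <- 0L; tot <- 0L
  for (tid in unique(ts$track_id)) {
    tr <- ts[ts$track_id == tid, , drop = FALSE]
    ids <- id_of[paste(tr$frame, round(tr$x_um / cell), round(tr$z_um / cell))]
    tot <- tot + length(ids) - 1L
    ok <- ok + sum(ids[-1] == ids[-length(ids)], na.rm = TRUE)
  }
  ok / tot
}

# Small polar grid centred on a region of interest.
roi_polar_grid <- function(r_mm, theta_deg, half_r_mm = 2, half_theta = 3,
                           dr_um = 67.8, dtheta_deg = 0.5) {
  structure(list(
    r_um = seq((r_mm - half_r_mm) * 1e3, (r_mm + half_r_mm) * 1e3, by = dr_um),
    theta_deg = seq(theta_deg - half_theta, theta_deg + half_theta,
                    by = dtheta_deg),
    dr_um = dr_um, dtheta_deg = dtheta_deg), class = "polar_grid")
}
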