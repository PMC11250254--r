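# Synthetic acquisition simulator: ground-truthed vessel trees, microbubble
# transits, periodic cardiac tissue motion, depth-dependent PSFs, rendered
# CEUS/B-mode stacks, and desk-scale RF channel data.
#
# Defaults emulate the study conditions this pipeline targets: a 2 MHz-class
# phased array imaging myocardium at up to 120 mm depth, slow-bolus/infusion
# bubble concentrations (sparse bubbles), 30 dB SNR stacks, and diastolic
# in-plane deformation with ~1.5 mm peak.

#' Construct a ground-truth vessel phantom
#'
#' Families: `"parallel_pair"` (two straight vessels at a set centreline
#' separation, the classical resolution phantom), `"branching"` (a binary
#' tree with Murray-scaled diameters), and `"ring"` (a circular arc).
#'
#' @param type phantom family.
#' @param centre_mm (x, z) centre of the phantom, mm.
#' @param separation_um centreline separation for `parallel_pair`, um.
#' @param length_mm vessel length, mm.
#' @param diameter_um vessel diameter, um.
#' @param speed_mm_s mean flow speed, mm/s.
#' @param n_levels branching depth for `branching`.
#' @param radius_mm ring radius for `ring`.
#' @param orientation_deg rotation of the phantom in the imaging plane.
#' @param seed integer seed (phantoms are deterministic given the seed).
#' @return object of class `vessel_tree`: list of segments, each with a
#'   polyline `points_um` (columns x, z), `diameter_um`, `speed_mm_s` and a
#'   `parent` index (NA for roots).
#' @export
vessel_phantom <- function(type = c("parallel_pair", "branching", "ring"),
                           centre_mm = c(0, 70),
                           separation_um = 300,
                           length_mm = 10,
                           diameter_um = 150,
                           speed_mm_s = 30,
                           n_levels = 3L,
                           radius_mm = 5,
                           orientation_deg = 0,
                           seed = 1L) {
  type <- match.arg(type)
  cx <- centre_mm[1] * 1e3; cz <- centre_mm[2] * 1e3
  th <- orientation_deg * pi / 180
  rot <- function(p) {
    cbind(x = cos(th) * p[, 1] - sin(th) * p[, 2],
          z = sin(th) * p[, 1] + cos(th) * p[, 2])
  }
  seg <- function(pts, dia, spd, parent = NA_integer_) {
    pts <- rot(pts)
    list(points_um = cbind(x_um = pts[, 1] + cx, z_um = pts[, 2] + cz),
         diameter_um = dia, speed_mm_s = spd, parent = parent)
  }
  L <- length_mm * 1e3
  segs <- switch(type,
    parallel_pair = {
      s <- seq(-L / 2, L / 2, length.out = 64L)
      list(
        seg(cbind(s, rep(-separation_um / 2, length(s))), diameter_um, speed_mm_s),
        seg(cbind(s, rep(+separation_um / 2, length(s))), diameter_um, speed_mm_s)
      )
    },
    branching = with_seed(seed, {
      out <- list()
      grow <- function(p0, dir, len, dia, spd, parent, level) {
        p1 <- p0 + dir * len
        s <- seq(0, 1, length.out = 32L)
        pts <- cbind(p0[1] + s * (p1[1] - p0[1]), p0[2] + s * (p1[2] - p0[2]))
        out[[length(out) + 1L]] <<- seg(pts, dia, spd, parent)
        id <- length(out)
        if (level < n_levels) {
          for (sgn in c(-1, 1)) {
            a <- sgn * (25 + stats::runif(1, -5, 5)) * pi / 180
            R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
            grow(p1, as.vector(R %*% dir), len * 0.75, dia * 0.79^1,
                 spd * 0.85, id, level + 1L)
          }
        }
      }
      grow(c(0, -L / 2), c(0, 1), L / 2, diameter_um, speed_mm_s,
           NA_integer_, 1L)
      out
    }),
    ring = {
      a <- seq(0, 2 * pi, length.out = 128L)
      r <- radius_mm * 1e3
      list(seg(cbind(r * cos(a), r * sin(a)), diameter_um, speed_mm_s))
    }
  )
  structure(list(segments = segs, seed = as.integer(seed), type = type),
            class = "vessel_tree")
}

#' Empty vessel tree
#' @export
empty_vessel_tree <- function() {
  structure(list(segments = list(), seed = NA_integer_, type = "empty"),
            class = "vessel_tree")
}

seg_lengths <- function(seg) {
  p <- seg$points_um
  sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
}

# Position and unit tangent at arc length s along a polyline.
seg_point_at <- function(seg, s) {
  p <- seg$points_um
  dl <- seg_lengths(seg)
  cl <- c(0, cumsum(dl))
  total <- cl[length(cl)]
  s <- pmin(pmax(s, 0), total)
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(i, length(dl))
  f <- (s - cl[i]) / dl[i]
  tx <- (p[i + 1, 1] - p[i, 1]) / dl[i]
  tz <- (p[i + 1, 2] - p[i, 2]) / dl[i]
  cbind(x_um = p[i, 1] + f * (p[i + 1, 1] - p[i, 1]),
        z_um = p[i, 2] + f * (p[i + 1, 2] - p[i, 2]),
        tx = tx, tz = tz)
}

#' Simulate microbubble transit through a vessel tree
#'
#' Bubbles arrive as a Poisson process (rate shared across segments in
#' proportion to length), draw a speed from the configured law (default
#' lognormal, the distribution used to describe micro-flow speeds), and are
#' advected along the centreline. Per-frame records are emitted at the
#' compounded frame rate.
#'
#' @param tree a [vessel_phantom()].
#' @param duration_s acquisition duration, s.
#' @param frame_rate compounded frame rate, Hz (default 305).
#' @param bubble_rate mean bubble arrivals per second over the whole tree.
#' @param speed_law list: `dist = "lognormal"` with `meanlog`, `sdlog`
#'   (log mm/s), or `dist = "constant"` (per-segment mean speed).
#' @param intensity_law list with `meanlog`, `sdlog` for per-bubble echo
#'   intensity (lognormal, dimensionless).
#' @param seed integer seed.
#' @return object of class `ground_truth`: data.frame with columns
#'   `frame, id, x_um, z_um, vx_mm_s, vz_mm_s, intensity`, plus attributes
#'   `tree`, `frame_rate`, `n_frames`, `seed`.
#' @export
simulate_transit <- function(tree, duration_s, frame_rate = 305,
                             bubble_rate = 20,
                             speed_law = list(dist = "lognormal",
                                              meanlog = log(30), sdlog = 0.4),
                             intensity_law = list(meanlog = 0, sdlog = 0.25),
                             seed = 1L) {
  check_positive(duration_s, frame_rate)
  if (bubble_rate < 0) stopf("invalid parameter: bubble_rate must be >= 0")
  n_frames <- max(1L, floor(duration_s * frame_rate))
  times <- (seq_len(n_frames) - 1) / frame_rate
  segs <- tree$segments
  recs <- list()
  if (length(segs) && bubble_rate > 0) {
    recs <- with_seed(seed, {
      lens <- vapply(segs, function(s) sum(seg_lengths(s)), 0)
      w <- lens / sum(lens)
      out <- list()
      id0 <- 0L
      for (k in seq_along(segs)) {
        sg <- segs[[k]]
        len <- lens[k]
        # allow bubbles already inside at t=0: extend arrival window backwards
        # by the slowest plausible transit time
        vmin <- if (identical(speed_law$dist, "constant")) sg$speed_mm_s else
          exp(speed_law$meanlog - 3 * speed_law$sdlog)
        lead <- len / (max(vmin, 1e-3) * 1e3)
        rate_k <- bubble_rate * w[k]
        n_b <- stats::rpois(1, rate_k * (duration_s + lead))
        if (n_b == 0) next
        t0 <- stats::runif(n_b, -lead, duration_s)
        v <- if (identical(speed_law$dist, "constant"))
          rep(sg$speed_mm_s, n_b)
        else
          stats::rlnorm(n_b, speed_law$meanlog, speed_law$sdlog)
        inten <- stats::rlnorm(n_b, intensity_law$meanlog, intensity_law$sdlog)
        for (b in seq_len(n_b)) {
          s_t <- (times - t0[b]) * v[b] * 1e3   # um along centreline
          inside <- s_t >= 0 & s_t <= len
          if (!any(inside)) next
          pt <- seg_point_at(sg, s_t[inside])
          id0 <- id0 + 1L
          out[[length(out) + 1L]] <- data.frame(
            frame = which(inside), id = id0,
            x_um = pt[, "x_um"], z_um = pt[, "z_um"],
            vx_mm_s = v[b] * pt[, "tx"], vz_mm_s = v[b] * pt[, "tz"],
            intensity = inten[b]
          )
        }
      }
      out
    })
  }
  gt <- if (length(recs)) do.call(rbind, recs) else
    data.frame(frame = integer(), id = integer(), x_um = numeric(),
               z_um = numeric(), vx_mm_s = numeric(), vz_mm_s = numeric(),
               intensity = numeric())
  gt <- gt[order(gt$frame, gt$id), , drop = FALSE]
  rownames(gt) <- NULL
  structure(gt, tree = tree, frame_rate = frame_rate, n_frames = n_frames,
            seed = as.integer(seed), class = c("ground_truth", "data.frame"))
}

#' Periodic cardiac tissue-motion model
#'
#' Displacement field `u(p, t) = a(phase) * [affine(p) + nonrigid(p)]` with a
#' smooth systolic envelope `a`: `sin(pi * phase/systole_fraction)^2` during
#' systole and zero during diastole, so the field is periodic
#' (`u(., t) == u(., t + period)`) and diastole is motion-free in the model.
#' The combined field is normalized so the peak in-plane displacement over
#' `domain` equals `peak_um`.
#'
#' @param period_s cardiac period, s.
#' @param systole_fraction fraction of the cycle occupied by systolic motion.
#' @param peak_um peak in-plane displacement, um (study range 1400-1700).
#' @param translation_um length-2 (x, z) translation amplitude, um (before
#'   the overall peak normalization).
#' @param rotation_deg rotation amplitude about the domain centre.
#' @param scale relative scale amplitude (1 = none).
#' @param nonrigid_um amplitude of the smooth non-rigid component, um
#'   (before the overall peak normalization).
#' @param control_spacing_mm spacing of the non-rigid control grid.
#' @param domain list with `x_mm`, `z_mm` length-2 ranges the motion acts on.
#' @param seed seed for the non-rigid component.
#' @return object of class `motion_model`.
#' @export
motion_model <- function(period_s = 0.8, systole_fraction = 0.35,
                         peak_um = 1500,
                         translation_um = c(800, 400), rotation_deg = 0.5,
                         scale = 1.005, nonrigid_um = 150,
                         control_spacing_mm = 8,
                         domain = list(x_mm = c(-20, 20), z_mm = c(40, 100)),
                         seed = 1L) {
  check_positive(period_s, systole_fraction, control_spacing_mm)
  xr <- domain$x_mm * 1e3; zr <- domain$z_mm * 1e3
  ncx <- max(2L, ceiling(diff(range(xr)) / (control_spacing_mm * 1e3)) + 1L)
  ncz <- max(2L, ceiling(diff(range(zr)) / (control_spacing_mm * 1e3)) + 1L)
  ctrl <- with_seed(seed, list(
    ux = matrix(stats::rnorm(ncz * ncx), ncz, ncx),
    uz = matrix(stats::rnorm(ncz * ncx), ncz, ncx)
  ))
  mm <- structure(list(
    period_s = period_s, systole_fraction = systole_fraction,
    peak_um = peak_um, translation_um = translation_um,
    rotation_deg = rotation_deg, scale = scale, nonrigid_um = nonrigid_um,
    domain = domain, ctrl = ctrl, ctrl_dims = c(ncz, ncx),
    norm = 1, seed = as.integer(seed)
  ), class = "motion_model")
  # calibrate so the peak displacement over the domain equals peak_um
  gx <- seq(xr[1], xr[2], length.out = 41)
  gz <- seq(zr[1], zr[2], length.out = 41)
  pts <- cbind(x_um = rep(gx, each = 41), z_um = rep(gz, 41))
  u <- motion_displacement(mm, mm$period_s * mm$systole_fraction / 2, pts,
                           raw = TRUE)
  peak <- max(sqrt(u[, 1]^2 + u[, 2]^2))
  mm$norm <- if (peak > 0) peak_um / peak else 0
  mm
}

systole_envelope <- function(mm, t) {
  ph <- (t / mm$period_s) %% 1
  ifelse(ph < mm$systole_fraction,
         sin(pi * ph / mm$systole_fraction)^2, 0)
}

#' Evaluate the tissue displacement field
#'
#' @param mm a [motion_model()].
#' @param t time, s.
#' @param pts n x 2 matrix of (x_um, z_um) positions.
#' @param raw internal: skip peak normalization.
#' @return n x 2 matrix of displacements (ux_um, uz_um).
#' @export
motion_displacement <- function(mm, t, pts, raw = FALSE) {
  a <- systole_envelope(mm, t)
  if (a == 0 && !raw) return(matrix(0, nrow(pts), 2,
                                    dimnames = list(NULL, c("ux_um", "uz_um"))))
  xr <- mm$domain$x_mm * 1e3; zr <- mm$domain$z_mm * 1e3
  cx <- mean(xr); cz <- mean(zr)
  th <- mm$rotation_deg * pi / 180
  dx <- pts[, 1] - cx; dz <- pts[, 2] - cz
  # affine deviation from identity (rotation + scale + translation)
  ax <- (cos(th) * dx - sin(th) * dz) * mm$scale + cx + mm$translation_um[1] - pts[, 1]
  az <- (sin(th) * dx + cos(th) * dz) * mm$scale + cz + mm$translation_um[2] - pts[, 2]
  # smooth non-rigid: bilinear interpolation of the control grid
  ncz <- mm$ctrl_dims[1]; ncx <- mm$ctrl_dims[2]
  ri <- (pts[, 2] - zr[1]) / (zr[2] - zr[1]) * (ncz - 1) + 1
  ci <- (pts[, 1] - xr[1]) / (xr[2] - xr[1]) * (ncx - 1) + 1
  nx <- interp_bilinear(mm$ctrl$ux, ri, ci) * mm$nonrigid_um
  nz <- interp_bilinear(mm$ctrl$uz, ri, ci) * mm$nonrigid_um
  u <- cbind(ux_um = ax + nx, uz_um = az + nz) * a
  if (!raw) u <- u * mm$norm
  u
}

#' Apply tissue motion to a ground truth
#'
#' Displaces bubble positions (and, downstream, the tissue template) by the
#' same periodic field; per-frame velocities are updated with the centred
#' finite difference of the field so positions and velocities stay
#' consistent. The model is attached so renderers and recovery tests can
#' query the true fields.
#'
#' @param gt a [simulate_transit()] result.
#' @param mm a [motion_model()].
#' @return a `ground_truth` with displaced positions and `motion` attribute.
#' @export
apply_tissue_motion <- function(gt, mm) {
  fr <- attr(gt, "frame_rate")
  if (nrow(gt)) {
    t <- (gt$frame - 1) / fr
    pts <- cbind(gt$x_um, gt$z_um)
    dt <- 1 / fr
    for (tt in unique(t)) {
      i <- t == tt
      u <- motion_displacement(mm, tt, pts[i, , drop = FALSE])
      up <- motion_displacement(mm, tt + dt, pts[i, , drop = FALSE])
      um <- motion_displacement(mm, tt - dt, pts[i, , drop = FALSE])
      gt$x_um[i] <- gt$x_um[i] + u[, 1]
      gt$z_um[i] <- gt$z_um[i] + u[, 2]
      gt$vx_mm_s[i] <- gt$vx_mm_s[i] + (up[, 1] - um[, 1]) / (2 * dt) / 1e3
      gt$vz_mm_s[i] <- gt$vz_mm_s[i] + (up[, 2] - um[, 2]) / (2 * dt) / 1e3
    }
  }
  attr(gt, "motion") <- mm
  gt
}

#' Depth-dependent point-spread-function model
#'
#' Lateral/axial FWHM interpolated linearly in depth between anchor points;
#' the defaults match a 2 MHz-class phased array whose contrast-mode lateral
#' FWHM grows from 1.7 mm at 30 mm depth to 5.85 mm at 120 mm.
#'
#' @param depths_mm anchor depths. @param lateral_fwhm_um,axial_fwhm_um FWHM
#'   at the anchors, um.
#' @return object of class `psf_model`.
#' @export
psf_model <- function(depths_mm = c(30, 120),
                      lateral_fwhm_um = c(1700, 5850),
                      axial_fwhm_um = c(500, 800)) {
  if (is.unsorted(depths_mm)) stopf("depths_mm must be ascending")
  if (any(lateral_fwhm_um <= 0) || any(axial_fwhm_um <= 0))
    stopf("invalid parameter: FWHM must be positive")
  structure(list(depths_mm = depths_mm, lateral_fwhm_um = lateral_fwhm_um,
                 axial_fwhm_um = axial_fwhm_um), class = "psf_model")
}

#' @rdname psf_model
#' @param psf a `psf_model`. @param depth_mm query depth.
#' @return list with `lat_fwhm_um`, `ax_fwhm_um` at the query depth.
#' @export
psf_at <- function(psf, depth_mm) {
  f <- function(y) stats::approx(psf$depths_mm, y, xout = depth_mm,
                                 rule = 2)$y
  list(lat_fwhm_um = f(psf$lateral_fwhm_um), ax_fwhm_um = f(psf$axial_fwhm_um))
}

splat_bubbles <- function(img, grid, x_um, z_um, inten, psf) {
  z <- grid$z_um; x <- grid$x_um
  for (b in seq_along(x_um)) {
    w <- psf_at(psf, z_um[b] / 1e3)
    sx <- w$lat_fwhm_um / 2.3548; sz <- w$ax_fwhm_um / 2.3548
    zi <- which(abs(z - z_um[b]) <= 3.5 * sz)
    xi <- which(abs(x - x_um[b]) <= 3.5 * sx)
    if (!length(zi) || !length(xi)) next
    gz <- exp(-(z[zi] - z_um[b])^2 / (2 * sz^2))
    gx <- exp(-(x[xi] - x_um[b])^2 / (2 * sx^2))
    img[zi, xi] <- img[zi, xi] + inten[b] * outer(gz, gx)
  }
  img
}

#' Render a CEUS/B-mode stack from ground truth
#'
#' Each bubble is splatted with the local depth-dependent PSF onto the
#' Cartesian grid; white Gaussian noise is added at the requested SNR
#' (defined as the ratio, in dB, of the peak signal amplitude of the
#' noiseless stack to the noise standard deviation). A paired B-mode stack
#' renders a smooth tissue speckle template displaced by the same motion
#' field the ground truth carries.
#'
#' @param gt a `ground_truth` (optionally after [apply_tissue_motion()]).
#' @param psf a [psf_model()].
#' @param grid a [cart_grid()].
#' @param snr_db signal-to-noise ratio, dB (Inf for noise-free).
#' @param seed integer seed for noise and the tissue template.
#' @param bmode render the paired tissue stack?
#' @return object of class `ceus_sim`: list with `ceus`, `bmode` (arrays
#'   `[nz, nx, n_frames]`), `noiseless`, `grid`, `gt`, and per-frame true
#'   displacement fields when motion is present.
#' @export
render_ceus_stack <- function(gt, psf, grid, snr_db = 30, seed = 1L,
                              bmode = TRUE) {
  n_frames <- attr(gt, "n_frames")
  fr <- attr(gt, "frame_rate")
  nz <- length(grid$z_um); nx <- length(grid$x_um)
  clean <- array(0, c(nz, nx, n_frames))
  for (f in seq_len(n_frames)) {
    i <- gt$frame == f
    if (any(i))
      clean[, , f] <- splat_bubbles(matrix(0, nz, nx), grid,
                                    gt$x_um[i], gt$z_um[i], gt$intensity[i],
                                    psf)
  }
  peak <- max(clean)
  stack <- clean
  if (is.finite(snr_db) && peak > 0) {
    sigma <- peak * 10^(-snr_db / 20)
    stack <- clean + with_seed(seed, array(stats::rnorm(length(clean), 0, sigma),
                                           dim(clean)))
  } else sigma <- 0
  mm <- attr(gt, "motion")
  bm <- NULL
  if (bmode) {
    template <- with_seed(seed + 1L, {
      raw <- matrix(stats::rnorm(nz * nx), nz, nx)
      k <- gaussian_kernel(2, max_size = min(nz, nx))
      sm <- conv2_zero(raw, k)
      sm - min(sm) + 0.1 * diff(range(sm))
    })
    bm <- array(0, c(nz, nx, n_frames))
    pix <- cbind(rep(grid$x_um, each = nz), rep(grid$z_um, nx))
    for (f in seq_len(n_frames)) {
      if (is.null(mm)) { bm[, , f] <- template; next }
      u <- motion_displacement(mm, (f - 1) / fr, pix)
      # first-order inverse warp: material point at p - u(p) maps to p
      ri <- (pix[, 2] - u[, 2] - grid$z_um[1]) / grid$dz_um + 1
      ci <- (pix[, 1] - u[, 1] - grid$x_um[1]) / grid$dx_um + 1
      bm[, , f] <- matrix(interp_bilinear(template, ri, ci), nz, nx)
    }
  }
  structure(list(ceus = stack, bmode = bm, noiseless = clean, grid = grid,
                 gt = gt, frame_rate = fr, snr_db = snr_db,
                 noise_sigma = sigma, motion = mm, seed = as.integer(seed)),
            class = "ceus_sim")
}

gauss_pulse <- function(t, f_hz, n_cycles = 2) {
  sigma <- n_cycles / (2 * f_hz) / 2.3548 * 2  # envelope FWHM = pulse length/2
  exp(-t^2 / (2 * sigma^2)) * sin(2 * pi * f_hz * t)
}

#' Simulate RF channel data for one diverging-wave transmit
#'
#' Desk-scale single-scattering model: each channel trace is a superposition
#' of delayed transmit pulses, with delay
#' `(|scatterer - virtual_source| - source_offset + |scatterer - element|)/c`.
#' Amplitude modulation is modelled through the transmit amplitude: the
#' full pulse drives the whole aperture (amplitude 1), each half pulse
#' drives one interleaved element subgroup (amplitude 1/2). Linear
#' scatterers respond proportionally to the incident amplitude; nonlinear
#' scatterers respond as `amplitude^gamma` (default gamma 1.5), so the AM
#' combination `full - (half_a + half_b)` cancels only the linear part.
#'
#' @param scatterers data.frame with `x_um`, `z_um`, `amp`, and optional
#'   `gamma` (response exponent; 1 = linear).
#' @param geom an [acq_geometry()].
#' @param angle_deg steering angle of the transmit.
#' @param pulse one of `"full"`, `"half_a"`, `"half_b"`.
#' @param t_max_s trace duration (defaults to the two-way imaging depth).
#' @param n_cycles pulse length in cycles.
#' @return numeric matrix `[n_samples, n_elements]` with attributes `fs`
#'   (sample rate, 4 x f_tx) and `t` (sample times).
#' @export
simulate_rf <- function(scatterers, geom, angle_deg = 0,
                        pulse = c("full", "half_a", "half_b"),
                        t_max_s = NULL, n_cycles = 2) {
  pulse <- match.arg(pulse)
  fs <- 4 * geom$f_tx_hz
  c_um_s <- geom$sound_speed * 1e6
  t_max_s <- t_max_s %||% (2.2 * geom$imaging_depth_um / c_um_s)
  nt <- ceiling(t_max_s * fs)
  t <- (seq_len(nt) - 1) / fs
  nch <- geom$n_elements
  out <- matrix(0, nt, nch)
  if (!nrow(scatterers)) return(structure(out, fs = fs, t = t))
  a_tx <- if (pulse == "full") 1 else 0.5
  gamma <- scatterers$gamma %||% rep(1, nrow(scatterers))
  if (is.null(scatterers$gamma)) gamma <- rep(1, nrow(scatterers))
  th <- angle_deg * pi / 180
  d <- geom$virtual_source_depth_um
  vs <- c(-d * sin(th), -d * cos(th))        # virtual source behind the array
  ex <- geom$element_positions_um
  for (s in seq_len(nrow(scatterers))) {
    sx <- scatterers$x_um[s]; sz <- scatterers$z_um[s]
    tx_path <- sqrt((sx - vs[1])^2 + (sz - vs[2])^2) - d
    resp <- scatterers$amp[s] * a_tx^gamma[s]
    for (ch in seq_len(nch)) {
      rx_path <- sqrt((sx - ex[ch])^2 + sz^2)
      tau <- (tx_path + rx_path) / c_um_s
      out[, ch] <- out[, ch] + resp * gauss_pulse(t - tau, geom$f_tx_hz,
                                                  n_cycles)
    }
  }
  structure(out, fs = fs, t = t)
}

#' Simulate a full AM group (half, full, half) for one angle
#' @inheritParams simulate_rf
#' @return list with elements `half_a`, `full`, `half_b`.
#' @export
simulate_rf_am <- function(scatterers, geom, angle_deg = 0, t_max_s = NULL,
                           n_cycles = 2) {
  list(half_a = simulate_rf(scatterers, geom, angle_deg, "half_a", t_max_s, n_cycles),
       full = simulate_rf(scatterers, geom, angle_deg, "full", t_max_s, n_cycles),
       half_b = simulate_rf(scatterers, geom, angle_deg, "half_b", t_max_s, n_cycles))
}

#' Simulate an RF frame sequence for moving scatterers
#'
#' Fires the configured angle sequence frame by frame, advancing a scatterer
#' path between transmit events; used to exercise compounding and the
#' inter-angle Doppler motion correction.
#'
#' @param path_fn function(t_s) returning the scatterer data.frame at time t.
#' @param geom an [acq_geometry()].
#' @param n_frames number of compounded frames.
#' @param am if TRUE produce AM triplets per angle and return the contrast
#'   combination; if FALSE one (full) pulse per angle.
#' @param t_max_s trace duration.
#' @return list `frames`, each a list over angles of `[nt, nch]` matrices;
#'   attribute `t_tx` holds per-transmit times.
#' @export
simulate_rf_sequence <- function(path_fn, geom, n_frames = 2, am = FALSE,
                                 t_max_s = NULL) {
  angles <- geom$steering_angles_deg
  npg <- if (am) geom$n_am_pulses else 1L
  tx_per_frame <- length(angles) * npg
  frames <- vector("list", n_frames)
  k <- 0L
  for (f in seq_len(n_frames)) {
    fr_angles <- vector("list", length(angles))
    for (a in seq_along(angles)) {
      if (am) {
        traces <- lapply(c("half_a", "full", "half_b"), function(p) {
          tt <- k / geom$prf; k <<- k + 1L
          simulate_rf(path_fn(tt), geom, angles[a], p, t_max_s)
        })
        fr_angles[[a]] <- am_contrast(traces[[1]], traces[[2]], traces[[3]])
        attr(fr_angles[[a]], "fs") <- attr(traces[[1]], "fs")
      } else {
        tt <- k / geom$prf; k <- k + 1L
        fr_angles[[a]] <- simulate_rf(path_fn(tt), geom, angles[a], "full",
                                      t_max_s)
      }
    }
    frames[[f]] <- fr_angles
  }
  structure(list(frames = frames, geom = geom, am = am,
                 pulses_per_angle = npg), class = "rf_sequence")
}
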