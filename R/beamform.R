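# Contrast-specific beamforming: AM combination, residual-tissue suppression,
# delay-and-sum (DAS) and coherence-to-variance (CV) beamforming, inter-angle
# bubble-motion correction, and scan conversion.
#
# B-mode images use plain DAS (linear in echo amplitude, which the SVD tissue
# filter downstream requires); CEUS images use the CV beamformer for side-lobe
# and noise suppression. That split is fixed.

#' Amplitude-modulation contrast combination
#'
#' `full - (half_a + half_b)`. For a perfectly linear medium the two
#' half-amplitude echoes sum to the full-amplitude echo and the residual is
#' zero; nonlinear (bubble) echoes survive.
#'
#' @param half_a,full,half_b equal-shape numeric arrays of RF samples.
#' @return the contrast RF residual, same shape.
#' @export
am_contrast <- function(half_a, full, half_b) {
  if (!identical(dim(half_a) %||% length(half_a), dim(full) %||% length(full)) ||
      !identical(dim(half_b) %||% length(half_b), dim(full) %||% length(full)))
    stopf("AM traces must have identical shapes")
  full - (half_a + half_b)
}

#' Temporal moving-average subtraction
#'
#' Subtracts from each frame the mean over a centred `window` of frames of
#' the same steering angle (default 3 frames, ~10 ms at 305 Hz), removing
#' residual static tissue while preserving moving-bubble signal. Edge frames
#' use truncated windows so the frame count is preserved.
#'
#' @param x numeric array whose *last* dimension indexes frames.
#' @param window window length in frames (odd).
#' @return filtered array, same shape.
#' @export
moving_average_subtract <- function(x, window = 3L) {
  d <- dim(x) %||% c(length(x))
  nf <- d[length(d)]
  if (nf < window) stopf("stack has %d frames, need at least %d", nf, window)
  half <- (window - 1L) %/% 2L
  m <- matrix(x, ncol = nf)
  out <- m
  for (f in seq_len(nf)) {
    w <- max(1L, f - half):min(nf, f + half)
    out[, f] <- m[, f] - rowMeans(m[, w, drop = FALSE])
  }
  array(out, d)
}

# Two-way time-of-flight sample indices for one steering angle: transmit from
# the virtual source (path minus source offset) plus receive to each element.
tof_delay_idx <- function(geom, angle_deg, px_um, pz_um, fs) {
  c_um_s <- geom$sound_speed * 1e6
  d <- geom$virtual_source_depth_um
  th <- angle_deg * pi / 180
  vs <- c(-d * sin(th), -d * cos(th))
  tx <- sqrt((px_um - vs[1])^2 + (pz_um - vs[2])^2) - d
  list(tx_s = tx / c_um_s, c_um_s = c_um_s)
}

grid_pixels <- function(grid) {
  if (inherits(grid, "polar_grid")) {
    nr <- length(grid$r_um); nt <- length(grid$theta_deg)
    r <- rep(grid$r_um, nt)
    th <- rep(grid$theta_deg, each = nr) * pi / 180
    list(px = r * sin(th), pz = r * cos(th), dims = c(nr, nt))
  } else {
    nz <- length(grid$z_um); nx <- length(grid$x_um)
    list(px = rep(grid$x_um, each = nz), pz = rep(grid$z_um, nx),
         dims = c(nz, nx))
  }
}

#' Per-channel delayed samples for one angle
#'
#' Samples each channel's analytic trace at the pixel's two-way
#' time-of-flight (linear interpolation in time). The returned tensor is the
#' common substrate for DAS (plain sums) and the CV beamformer (variance
#' weighting).
#'
#' @param rf `[nt, nch]` matrix (real RF is converted to its analytic
#'   signal), with attribute `fs` or an explicit `fs` argument.
#' @param geom an [acq_geometry()]. @param angle_deg steering angle.
#' @param grid a [polar_grid()] or [cart_grid()].
#' @param fs sample rate, Hz.
#' @return complex matrix `[n_pixels, nch]` with attribute `dims`.
#' @export
delay_channel_samples <- function(rf, geom, angle_deg, grid,
                                  fs = attr(rf, "fs")) {
  if (is.null(fs)) stopf("sample rate `fs` is required")
  if (!is.complex(rf)) rf <- analytic_signal(rf)
  g <- grid_pixels(grid)
  dly <- tof_delay_idx(geom, angle_deg, g$px, g$pz, fs)
  ex <- geom$element_positions_um
  out <- matrix(0 + 0i, length(g$px), geom$n_elements)
  for (ch in seq_len(geom$n_elements)) {
    rx_s <- sqrt((g$px - ex[ch])^2 + g$pz^2) / dly$c_um_s
    idx <- (dly$tx_s + rx_s) * fs + 1
    out[, ch] <- interp_linear_idx(rf[, ch], idx)
  }
  attr(out, "dims") <- g$dims
  out
}

#' Delay-and-sum beamforming of one angle
#'
#' Pixel value is the coherent sum over channels of the analytic traces
#' sampled at the two-way time-of-flight.
#'
#' @inheritParams delay_channel_samples
#' @return complex image matrix on `grid`.
#' @export
das_beamform <- function(rf, geom, angle_deg, grid, fs = attr(rf, "fs")) {
  s <- delay_channel_samples(rf, geom, angle_deg, grid, fs)
  matrix(rowSums(s), attr(s, "dims")[1], attr(s, "dims")[2])
}

#' Coherence-to-variance compounding
#'
#' For each pixel, with delayed samples `s` pooled across all channels and
#' all steering angles: coherent sum `S = sum(s)`, adaptive weight
#' `w = |S/N|^2 / var(s)` (squared coherent mean over the pooled complex
#' sample variance, an SNR-like quantity), clipped to `w_max`; the pixel is
#' `w * S`. Zero variance (full coherence) takes `w = w_max`.
#'
#' @param samples complex matrix `[n_pixels, nch * n_angles]` (cbind of
#'   [delay_channel_samples()] outputs), attribute `dims` kept from them.
#' @param w_max weight ceiling.
#' @param dims image dims if `samples` lacks the attribute.
#' @return complex image matrix.
#' @export
cv_compound <- function(samples, w_max = 1, dims = attr(samples, "dims")) {
  n <- ncol(samples)
  S <- rowSums(samples)
  mu <- S / n
  v <- rowSums(abs(samples - mu)^2) / pmax(n - 1, 1)
  w <- ifelse(v <= .Machine$double.eps * n, w_max,
              pmin(abs(mu)^2 / v, w_max))
  img <- w * S
  if (!is.null(dims)) img <- matrix(img, dims[1], dims[2])
  img
}

#' DAS compounding across angles (for comparison with CV)
#' @inheritParams cv_compound
#' @export
das_compound <- function(samples, dims = attr(samples, "dims")) {
  img <- rowSums(samples)
  if (!is.null(dims)) img <- matrix(img, dims[1], dims[2])
  img
}

#' Inter-angle bubble-motion correction
#'
#' Multi-angle compounding assumes bubbles stay put between steering angles;
#' moving bubbles decorrelate the per-angle images. The axial velocity is
#' estimated per pixel from the lag-1 complex autocorrelation between
#' repeats of the same steering angle in consecutive compounded frames
#' (`dz = phase * lambda / (4 pi)` per frame), and each angle image is then
#' shifted along depth to the compounding-centre time before summation. No
#' phase-rotation step is applied (analytic, not IQ, signals).
#'
#' The estimator aliases above `lambda * frame_rate / 4` axial speed.
#'
#' @param per_angle array `[nr, ntheta, n_angles, n_frames]` of complex
#'   per-angle polar images (>= 2 frames).
#' @param geom an [acq_geometry()].
#' @param grid the [polar_grid()] the images live on.
#' @param pulses_per_angle transmits consumed per angle (n_am_pulses for AM
#'   groups, 1 for plain transmits).
#' @return list: `corrected` array like `per_angle`, `v_axial_mm_s` the
#'   per-pixel velocity estimate, `frame_rate`.
#' @export
interangle_motion_correct <- function(per_angle, geom, grid,
                                      pulses_per_angle = geom$n_am_pulses) {
  d <- dim(per_angle)
  if (length(d) != 4L) stopf("per_angle must be [nr, ntheta, n_angles, n_frames]")
  na <- d[3]; nf <- d[4]
  if (na != length(geom$steering_angles_deg))
    stopf("angle axis (%d) does not match the geometry's %d steering angles",
          na, length(geom$steering_angles_deg))
  if (nf < 2L) stopf("need at least 2 compounded frames for the Doppler estimate")
  lambda_um <- geom$sound_speed * 1e6 / geom$f_tx_hz
  frame_rate <- geom$prf / (na * pulses_per_angle)
  # lag-1 autocorrelation pooled over angles and frame pairs
  R <- matrix(0 + 0i, d[1], d[2])
  for (a in seq_len(na)) for (f in seq_len(nf - 1L))
    R <- R + per_angle[, , a, f] * Conj(per_angle[, , a, f + 1L])
  # positive phase of R = phase(f) - phase(f+1); moving away from the probe
  # (dz > 0) decreases the sampled phase, so dz = +Arg(R) * lambda / (4 pi)
  dz_frame <- Arg(R) * lambda_um / (4 * pi)
  v_axial <- dz_frame * frame_rate / 1e3            # mm/s, + = away from probe
  t_angle <- pulses_per_angle / geom$prf
  centre <- (na + 1) / 2
  corrected <- per_angle
  dr <- grid$dr_um
  nr <- d[1]
  for (a in seq_len(na)) {
    tau <- (a - centre) * t_angle                  # time offset from centre
    shift_px <- dz_frame * tau * frame_rate / dr   # axial shift in r cells
    if (max(abs(shift_px)) == 0) next
    for (f in seq_len(nf)) {
      img <- per_angle[, , a, f]
      ri <- matrix(seq_len(nr), nr, d[2]) + shift_px
      # windowed-sinc interpolation: the analytic carrier (~lambda/2 per
      # 67.8 um cell) must survive the fractional shift unattenuated
      for (cc in seq_len(d[2]))
        corrected[, cc, a, f] <- interp_lanczos_idx(img[, cc], ri[, cc])
    }
  }
  list(corrected = corrected, v_axial_mm_s = v_axial, frame_rate = frame_rate)
}

#' Scan conversion from polar to Cartesian coordinates
#'
#' Spline (Catmull-Rom bicubic) interpolation of an envelope image onto the
#' Cartesian grid; pixels outside the acquired sector are zero and flagged
#' in the validity mask.
#'
#' @param img real matrix on `pgrid` (envelope/magnitude image).
#' @param pgrid a [polar_grid()]. @param cgrid a [cart_grid()].
#' @return list `image` (matrix on `cgrid`) and `mask` (logical).
#' @export
scan_convert <- function(img, pgrid, cgrid) {
  nz <- length(cgrid$z_um); nx <- length(cgrid$x_um)
  x <- rep(cgrid$x_um, each = nz); z <- rep(cgrid$z_um, nx)
  r <- sqrt(x^2 + z^2)
  th <- atan2(x, z) * 180 / pi
  ri <- (r - pgrid$r_um[1]) / pgrid$dr_um + 1
  ci <- (th - pgrid$theta_deg[1]) / pgrid$dtheta_deg + 1
  inside <- ri >= 1 & ri <= length(pgrid$r_um) &
    ci >= 1 & ci <= length(pgrid$theta_deg)
  # replicate-pad by 2 cells so sector-edge pixels interpolate cleanly
  pad <- 2L
  pimg <- img[c(rep(1L, pad), seq_len(nrow(img)), rep(nrow(img), pad)),
              c(rep(1L, pad), seq_len(ncol(img)), rep(ncol(img), pad))]
  vals <- numeric(length(r))
  vals[inside] <- interp_bicubic(pimg, ri[inside] + pad, ci[inside] + pad)
  list(image = matrix(vals, nz, nx), mask = matrix(inside, nz, nx))
}

#' Beamform an RF frame sequence into per-angle polar images
#'
#' Convenience wrapper: runs [das_beamform()] per angle on each frame of a
#' [simulate_rf_sequence()] result (or an equivalent structure).
#'
#' @param seq an `rf_sequence`. @param grid a [polar_grid()].
#' @return complex array `[nr, ntheta, n_angles, n_frames]`.
#' @export
beamform_sequence <- function(seq, grid) {
  geom <- seq$geom
  angles <- geom$steering_angles_deg
  nf <- length(seq$frames)
  first <- das_beamform(seq$frames[[1]][[1]], geom, angles[1], grid,
                        fs = attr(seq$frames[[1]][[1]], "fs"))
  out <- array(0 + 0i, c(nrow(first), ncol(first), length(angles), nf))
  for (f in seq_len(nf)) for (a in seq_along(angles)) {
    rf <- seq$frames[[f]][[a]]
    out[, , a, f] <- das_beamform(rf, geom, angles[a], grid,
                                  fs = attr(rf, "fs"))
  }
  out
}
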