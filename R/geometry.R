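# Acquisition model: probe, diverging-wave virtual source, pulse sequence,
# and the polar/Cartesian grid conventions used by every other module.
#
# Unit conventions (internal): lengths in micrometres, times in seconds,
# frequencies in Hz. Constructors accept the field-customary mixed units
# (mm, MHz) and convert at the boundary. Coordinate frame: the array centre is
# at (x = 0, z = 0), z grows with depth, lateral x is signed, and the polar
# angle theta is measured from the z axis (broadside), positive towards +x.

#' Acquisition geometry for a diverging-wave phased-array sequence
#'
#' Describes the probe, the virtual source behind the array, and the
#' angle/amplitude-modulation (AM) pulse sequence. Defaults describe a
#' 2 MHz-class 80-element cardiac phased array driven with six steering
#' angles in a triangle ordering and a three-pulse AM sequence
#' (half, full, half amplitude).
#'
#' @param n_elements number of (effective single-row) elements.
#' @param pitch_um element pitch in micrometres.
#' @param virtual_source_depth_mm distance of the diverging-wave virtual
#'   source behind the array centre, millimetres.
#' @param sound_speed speed of sound in m/s (soft-tissue default 1540).
#' @param f_tx_mhz transmit frequency, MHz.
#' @param f_center_mhz probe centre frequency, MHz.
#' @param prf pulse repetition frequency, Hz.
#' @param steering_angles_deg ordered steering angles in degrees; the default
#'   is the ascending-then-descending triangle sequence
#'   (-15, -3, 9, 15, 3, -9).
#' @param n_am_pulses pulses per AM group (3: half, full, half).
#' @param imaging_depth_mm imaging depth, millimetres.
#' @return an object of class `acq_geometry`.
#' @examples
#' g <- acq_geometry()
#' aperture_width_mm(g)      # 21.6
#' compounded_frame_rate(g$prf, length(g$steering_angles_deg), g$n_am_pulses)
#' @export
acq_geometry <- function(n_elements = 80L,
                         pitch_um = 270,
                         virtual_source_depth_mm = 21.6,
                         sound_speed = 1540,
                         f_tx_mhz = 2.4,
                         f_center_mhz = 2.84,
                         prf = 5490,
                         steering_angles_deg = c(-15, -3, 9, 15, 3, -9),
                         n_am_pulses = 3L,
                         imaging_depth_mm = 120) {
  check_positive(n_elements, pitch_um, virtual_source_depth_mm, sound_speed,
                 f_tx_mhz, f_center_mhz, prf, n_am_pulses, imaging_depth_mm)
  if (length(steering_angles_deg) %% 2L != 0L)
    stopf("invalid parameter: steering_angles_deg must have even length")
  n_elements <- as.integer(n_elements)
  # lateral element centres, symmetric about the array centre
  positions <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch_um
  g <- structure(list(
    n_elements = n_elements,
    pitch_um = pitch_um,
    element_positions_um = positions,
    virtual_source_depth_um = virtual_source_depth_mm * 1e3,
    sound_speed = sound_speed,
    f_tx_hz = f_tx_mhz * 1e6,
    f_center_hz = f_center_mhz * 1e6,
    prf = prf,
    steering_angles_deg = steering_angles_deg,
    n_am_pulses = as.integer(n_am_pulses),
    imaging_depth_um = imaging_depth_mm * 1e3
  ), class = "acq_geometry")
  g
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat("<acq_geometry>\n")
  cat(sprintf("  %d elements, pitch %g um (aperture %.1f mm)\n",
              x$n_elements, x$pitch_um, aperture_width_mm(x)))
  cat(sprintf("  virtual source %.1f mm behind array, FOV %.1f deg\n",
              x$virtual_source_depth_um / 1e3, angular_fov(x)))
  cat(sprintf("  f_tx %.2f MHz, PRF %g Hz, %d angles x %d AM pulses -> %.1f fps\n",
              x$f_tx_hz / 1e6, x$prf, length(x$steering_angles_deg),
              x$n_am_pulses,
              compounded_frame_rate(x$prf, length(x$steering_angles_deg),
                                    x$n_am_pulses)))
  invisible(x)
}

#' Aperture width of a geometry in millimetres
#' @param geom an [acq_geometry()].
#' @export
aperture_width_mm <- function(geom) geom$n_elements * geom$pitch_um / 1e3

#' Compounded frame rate of an angle/AM sequence
#'
#' One compounded frame consumes `n_angles * n_am_pulses` transmits, so the
#' frame rate is `prf / (n_angles * n_am_pulses)`; e.g. 5490 Hz with six
#' angles and three AM pulses gives 305 Hz.
#'
#' @param prf pulse repetition frequency, Hz.
#' @param n_angles number of steering angles per compound frame.
#' @param n_am_pulses pulses per AM group.
#' @return frames per second.
#' @export
compounded_frame_rate <- function(prf, n_angles, n_am_pulses) {
  check_positive(prf, n_angles, n_am_pulses)
  prf / (n_angles * n_am_pulses)
}

#' Angular field of view of a diverging-wave transmit
#'
#' The sector half-angle is `atan((aperture/2) / virtual_source_depth)`:
#' rays from the virtual source through the aperture edges bound the
#' insonified sector.
#'
#' @param aperture_width_mm aperture width, mm (or an [acq_geometry()]).
#' @param virtual_source_depth_mm virtual source depth behind the array, mm.
#' @return full opening angle in degrees.
#' @export
angular_fov <- function(aperture_width_mm, virtual_source_depth_mm = NULL) {
  if (inherits(aperture_width_mm, "acq_geometry")) {
    g <- aperture_width_mm
    virtual_source_depth_mm <- g$virtual_source_depth_um / 1e3
    aperture_width_mm <- aperture_width_mm(g)
  }
  check_positive(aperture_width_mm, virtual_source_depth_mm)
  2 * atan((aperture_width_mm / 2) / virtual_source_depth_mm) * 180 / pi
}

#' Acoustic wavelength in micrometres
#'
#' @param sound_speed speed of sound, m/s.
#' @param f_mhz frequency, MHz.
#' @return wavelength in micrometres (`sound_speed / f`).
#' @export
us_wavelength_um <- function(sound_speed, f_mhz) {
  check_positive(sound_speed, f_mhz)
  sound_speed / (f_mhz * 1e6) * 1e6
}

#' @rdname us_wavelength_um
#' @export
half_wavelength_um <- function(sound_speed, f_mhz) {
  us_wavelength_um(sound_speed, f_mhz) / 2
}

#' Polar reconstruction grid
#'
#' Beamforming grid in polar coordinates (range r from the array centre,
#' angle theta from broadside). Default spacings are 67.8 um radially and
#' 0.5 degrees angularly.
#'
#' @param r_max_mm maximum range, mm.
#' @param theta_span_deg full angular span, degrees (centred on broadside).
#' @param dr_um radial spacing, um.
#' @param dtheta_deg angular spacing, degrees.
#' @return object of class `polar_grid` with sample vectors `r_um`,
#'   `theta_deg`.
#' @export
polar_grid <- function(r_max_mm, theta_span_deg, dr_um = 67.8,
                       dtheta_deg = 0.5) {
  check_positive(r_max_mm, theta_span_deg, dr_um, dtheta_deg)
  r_max_um <- r_max_mm * 1e3
  if (dr_um > r_max_um || dtheta_deg > theta_span_deg)
    stopf("invalid parameter: grid spacing exceeds grid extent")
  nr <- ceiling(r_max_um / dr_um) + 1L
  nt <- ceiling(theta_span_deg / dtheta_deg) + 1L
  structure(list(
    r_um = (seq_len(nr) - 1) * dr_um,
    theta_deg = seq(-theta_span_deg / 2, by = dtheta_deg, length.out = nt),
    dr_um = dr_um, dtheta_deg = dtheta_deg
  ), class = "polar_grid")
}

#' Cartesian scan-converted grid
#'
#' Depth/lateral grid with the array centre at (x = 0, z = 0) and z growing
#' with depth. Default spacings: 67.8 um along depth and 135.0 um laterally.
#'
#' @param z_range_mm numeric length-2, depth range in mm.
#' @param x_range_mm numeric length-2, lateral range in mm.
#' @param dz_um,dx_um spacings in um.
#' @return object of class `cart_grid` with sample vectors `z_um`, `x_um`.
#' @export
cart_grid <- function(z_range_mm, x_range_mm, dz_um = 67.8, dx_um = 135.0) {
  check_positive(dz_um, dx_um)
  z0 <- min(z_range_mm) * 1e3; z1 <- max(z_range_mm) * 1e3
  x0 <- min(x_range_mm) * 1e3; x1 <- max(x_range_mm) * 1e3
  if (dz_um > (z1 - z0) || dx_um > (x1 - x0))
    stopf("invalid parameter: grid spacing exceeds grid extent")
  structure(list(
    z_um = seq(z0, z1 + dz_um - 1e-9, by = dz_um),
    x_um = seq(x0, x1 + dx_um - 1e-9, by = dx_um),
    dz_um = dz_um, dx_um = dx_um
  ), class = "cart_grid")
}

#' Build the default polar and Cartesian grids for a geometry
#'
#' The polar grid spans `[0, imaging_depth]` radially and the full angular
#' field of view; the Cartesian grid bounds the scan-converted sector.
#'
#' @param geom an [acq_geometry()].
#' @param dr_um,dtheta_deg polar spacings.
#' @param dz_um,dx_um Cartesian spacings.
#' @return list with elements `polar` and `cart`.
#' @export
build_grids <- function(geom, dr_um = 67.8, dtheta_deg = 0.5,
                        dz_um = 67.8, dx_um = 135.0) {
  fov <- angular_fov(geom)
  depth_mm <- geom$imaging_depth_um / 1e3
  pg <- polar_grid(depth_mm, fov, dr_um, dtheta_deg)
  half <- fov / 2 * pi / 180
  xmax <- depth_mm * sin(half)
  cg <- cart_grid(c(0, depth_mm), c(-xmax, xmax), dz_um, dx_um)
  list(polar = pg, cart = cg)
}

#' Polar/Cartesian coordinate transforms
#'
#' `polar_to_cart()` maps range/angle to (x, z) with `x = r sin(theta)`,
#' `z = r cos(theta)`; `cart_to_polar()` inverts the mapping.
#'
#' @param r_um range, um. @param theta_deg angle from broadside, degrees.
#' @return two-column matrix.
#' @export
polar_to_cart <- function(r_um, theta_deg) {
  th <- theta_deg * pi / 180
  cbind(x_um = r_um * sin(th), z_um = r_um * cos(th))
}

#' @rdname polar_to_cart
#' @param x_um,z_um Cartesian coordinates, um.
#' @export
cart_to_polar <- function(x_um, z_um) {
  cbind(r_um = sqrt(x_um^2 + z_um^2),
        theta_deg = atan2(x_um, z_um) * 180 / pi)
}

#' Read or write an acquisition geometry config file
#'
#' Serializes a geometry to a structured-text (YAML) config; the same file
#' seeds the simulator and the pipeline CLI.
#'
#' @param geom an [acq_geometry()]. @param path file path.
#' @export
write_geometry <- function(geom, path) {
  lst <- unclass(geom)
  lst$element_positions_um <- NULL  # derived
  yaml::write_yaml(list(geometry = lst), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  if (is.null(g)) stopf("config has no `geometry` section: %s", path)
  acq_geometry(
    n_elements = g$n_elements, pitch_um = g$pitch_um,
    virtual_source_depth_mm = g$virtual_source_depth_um / 1e3,
    sound_speed = g$sound_speed, f_tx_mhz = g$f_tx_hz / 1e6,
    f_center_mhz = g$f_center_hz / 1e6, prf = g$prf,
    steering_angles_deg = unlist(g$steering_angles_deg),
    n_am_pulses = g$n_am_pulses,
    imaging_depth_mm = g$imaging_depth_um / 1e3
  )
}
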