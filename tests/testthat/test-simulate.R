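test_that("vessel phantoms honour their construction parameters", {
  tr <- vessel_phantom("parallel_pair", separation_um = 300)
  expect_length(tr$segments, 2)
  # minimum pairwise centreline distance equals the requested separation
  p1 <- tr$segments[[1]]$points_um; p2 <- tr$segments[[2]]$points_um
  d <- sqrt(outer(p1[, 1], p2[, 1], `-`)^2 + outer(p1[, 2], p2[, 2], `-`)^2)
  expect_equal(min(d), 300)
  expect_length(empty_vessel_tree()$segments, 0)
  # determinism
  expect_equal(vessel_phantom("branching", seed = 42),
               vessel_phantom("branching", seed = 42))
  t3 <- vessel_phantom("branching", n_levels = 3L)
  expect_length(t3$segments, 7)   # binary tree, 3 levels
})

test_that("bubble transit kinematics and count conservation hold", {
  tree <- vessel_phantom("parallel_pair", separation_um = 2000, length_mm = 8,
                         speed_mm_s = 25)
  expect_equal(nrow(simulate_transit(tree, 1, 100, bubble_rate = 0)), 0)
  gt <- simulate_transit(tree, 1, 100, bubble_rate = 10,
                         speed_law = list(dist = "constant"), seed = 3)
  # constant speed: per-frame displacement = v / frame_rate along the vessel
  for (id in unique(gt$id)[1:3]) {
    b <- gt[gt$id == id, ]
    if (nrow(b) < 3) next
    steps <- sqrt(diff(b$x_um)^2 + diff(b$z_um)^2)
    expect_equal(steps, rep(25 / 100 * 1e3, length(steps)), tolerance = 1e-9)
    # velocities consistent with positions (finite differences)
    expect_equal(diff(b$x_um) * 100 / 1e3, b$vx_mm_s[-nrow(b)],
                 tolerance = 1e-6)
  }
  # reproducibility
  gt2 <- simulate_transit(tree, 1, 100, bubble_rate = 10,
                          speed_law = list(dist = "constant"), seed = 3)
  expect_identical(as.data.frame(gt), as.data.frame(gt2))
})

test_that("lognormal transit speeds match the closed-form mean", {
  n <- 2e4
  mu <- log(30); sg <- 0.4
  v <- withr::with_seed(11, rlnorm(n, mu, sg))
  true_mean <- exp(mu + sg^2 / 2)
  se <- sqrt((exp(sg^2) - 1) * exp(2 * mu + sg^2) / n)
  expect_lt(abs(mean(v) - true_mean), 3 * se)
})

test_that("tissue motion model is periodic, calibrated, and composable", {
  dom <- list(x_mm = c(-10, 10), z_mm = c(50, 70))
  mm <- motion_model(period_s = 0.8, peak_um = 1500, domain = dom, seed = 2)
  pts <- cbind(runif(50, -1e4, 1e4), runif(50, 5e4, 7e4))
  # periodicity
  expect_equal(motion_displacement(mm, 0.31, pts),
               motion_displacement(mm, 0.31 + 0.8, pts), tolerance = 1e-12)
  # peak displacement equals the configured amplitude
  gx <- seq(-1e4, 1e4, length.out = 41); gz <- seq(5e4, 7e4, length.out = 41)
  gpts <- cbind(rep(gx, each = 41), rep(gz, 41))
  peak_t <- 0.8 * mm$systole_fraction / 2
  u <- motion_displacement(mm, peak_t, gpts)
  expect_equal(max(sqrt(u[, 1]^2 + u[, 2]^2)), 1500, tolerance = 1e-6)
  # zero amplitude -> identity; diastole -> zero displacement
  mm0 <- motion_model(peak_um = 0, domain = dom)
  expect_true(all(motion_displacement(mm0, peak_t, pts) == 0))
  expect_true(all(motion_displacement(mm, 0.79, pts) == 0))
  # pure translation shifts every position equally
  mmt <- motion_model(period_s = 0.8, peak_um = 1000,
                      translation_um = c(1, 0), rotation_deg = 0, scale = 1,
                      nonrigid_um = 0, domain = dom)
  ut <- motion_displacement(mmt, peak_t, pts)
  expect_equal(ut[, 1], rep(1000, nrow(pts)), tolerance = 1e-9)
  expect_equal(ut[, 2], rep(0, nrow(pts)), tolerance = 1e-9)
})

test_that("applying tissue motion keeps positions and velocities consistent", {
  tree <- vessel_phantom("parallel_pair", separation_um = 2000, length_mm = 8)
  gt <- simulate_transit(tree, 0.5, 100, bubble_rate = 10,
                         speed_law = list(dist = "constant"), seed = 4)
  mm <- motion_model(period_s = 0.4, peak_um = 800,
                     domain = list(x_mm = c(-10, 10), z_mm = c(55, 85)))
  gtm <- apply_tissue_motion(gt, mm)
  b <- gtm[gtm$id == gtm$id[1], ]
  if (nrow(b) >= 5) {
    fd_vx <- diff(b$x_um) * 100 / 1e3
    mid <- 2:(length(fd_vx))
    # central-difference velocities track the finite differences closely
    expect_lt(stats::median(abs((b$vx_mm_s[mid] -
                                   (fd_vx[mid] + fd_vx[mid - 1]) / 2))), 0.5)
  }
  expect_s3_class(attr(gtm, "motion"), "motion_model")
})

test_that("PSF model interpolates FWHM monotonically with depth", {
  psf <- psf_model()
  w30 <- psf_at(psf, 30); w75 <- psf_at(psf, 75); w120 <- psf_at(psf, 120)
  expect_equal(w30$lat_fwhm_um, 1700)
  expect_equal(w120$lat_fwhm_um, 5850)
  expect_true(w30$lat_fwhm_um < w75$lat_fwhm_um)
  expect_true(w75$lat_fwhm_um < w120$lat_fwhm_um)
  expect_error(psf_model(lateral_fwhm_um = c(-1, 5)), "positive")
})

test_that("rendered stacks place bubbles, respect SNR, and self-calibrate", {
  grid <- cart_grid(c(28, 32), c(-3, 3))
  gt <- single_bubble_gt(400, 30000)
  sim <- render_ceus_stack(gt, psf_model(), grid, snr_db = Inf, bmode = FALSE)
  pk <- which(sim$ceus[, , 1] == max(sim$ceus[, , 1]), arr.ind = TRUE)
  expect_lt(abs(grid$z_um[pk[1]] - 30000), grid$dz_um / 2 + 1e-9)
  expect_lt(abs(grid$x_um[pk[2]] - 400), grid$dx_um / 2 + 1e-9)
  # measured SNR within 1 dB of the request
  simn <- render_ceus_stack(gt, psf_model(), grid, snr_db = 30, seed = 9,
                            bmode = FALSE)
  noise <- simn$ceus - simn$noiseless
  snr_meas <- 20 * log10(max(simn$noiseless) / stats::sd(noise))
  expect_lt(abs(snr_meas - 30), 1)
  # splatted point image reproduces the model FWHM within 5%
  fwhm_of <- function(prof, step) {
    half <- max(prof) / 2
    above <- which(prof > half)
    l <- min(above); r <- max(above)
    sl <- l - 1 + (prof[l - 1] - half) / (prof[l - 1] - prof[l])
    sr <- r + (prof[r] - half) / (prof[r] - prof[r + 1])
    (sr - sl) * step
  }
  prof <- sim$ceus[, which.min(abs(grid$x_um - 400)), 1]
  expect_lt(abs(fwhm_of(prof, grid$dz_um) -
                  psf_at(psf_model(), 30)$ax_fwhm_um) /
              psf_at(psf_model(), 30)$ax_fwhm_um, 0.05)
  lat <- sim$ceus[which.min(abs(grid$z_um - 30000)), , 1]
  expect_lt(abs(fwhm_of(lat, grid$dx_um) - 1700) / 1700, 0.05)
  # two far-apart bubbles give two components above half max
  gt2 <- structure(rbind(as.data.frame(single_bubble_gt(-3000, 29000)),
                         transform(as.data.frame(single_bubble_gt(3000, 39000)),
                                   id = 2L)),
                   frame_rate = 305, n_frames = 1L,
                   class = c("ground_truth", "data.frame"))
  grid2 <- cart_grid(c(26, 42), c(-6, 6))
  sim2 <- render_ceus_stack(gt2, psf_model(), grid2, snr_db = Inf,
                            bmode = FALSE)
  m <- sim2$ceus[, , 1] > max(sim2$ceus[, , 1]) / 2
  expect_equal(max(srulm:::label_components8(m)), 2)
})

test_that("RF simulation obeys the two-segment time-of-flight and AM rules", {
  geom <- acq_geometry(imaging_depth_mm = 50)
  z0 <- 35000
  rf <- simulate_rf(data.frame(x_um = 0, z_um = z0, amp = 1), geom, 0, "full")
  ch <- 40   # near the array centre
  ex <- geom$element_positions_um[ch]
  c_um <- geom$sound_speed * 1e6
  # analytic oracle: straight transmit path minus source offset + receive
  tau <- ((z0 + geom$virtual_source_depth_um) - geom$virtual_source_depth_um +
            sqrt(z0^2 + ex^2)) / c_um
  env <- abs(analytic_signal(rf[, ch]))
  t_pk <- attr(rf, "t")[which.max(env)]
  expect_lt(abs(t_pk - tau), 1 / attr(rf, "fs"))
  # linear cancellation below -40 dB of the full echo
  am <- simulate_rf_am(data.frame(x_um = c(0, 2500), z_um = c(30000, 40000),
                                  amp = c(1, 0.6)), geom, 9)
  resid <- am_contrast(am$half_a, am$full, am$half_b)
  expect_lt(10 * log10(sum(resid^2) / sum(am$full^2)), -40)
  # nonlinear scatterer survives the AM combination
  amn <- simulate_rf_am(data.frame(x_um = 0, z_um = 30000, amp = 1,
                                   gamma = 1.5), geom, 0)
  rn <- am_contrast(amn$half_a, amn$full, amn$half_b)
  expect_gt(sum(rn^2) / sum(amn$full^2), 1e-3)
})
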