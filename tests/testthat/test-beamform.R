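test_that("AM combination is the linear residual operator", {
  a <- array(runif(24), c(2, 3, 4)); b <- array(runif(24), c(2, 3, 4))
  f <- array(runif(24), c(2, 3, 4))
  expect_equal(am_contrast(f / 2, f, f / 2), array(0, c(2, 3, 4)))
  expect_equal(am_contrast(a, f * 0, b), -(a + b))
  expect_error(am_contrast(a, f[, , 1:2], b), "identical shapes")
})

test_that("moving-average subtraction matches a brute-force oracle", {
  set.seed(2)
  x <- array(rnorm(5 * 4 * 7), c(5, 4, 7))
  got <- moving_average_subtract(x, 3)
  # brute force with truncated edge windows
  for (f in 1:7) {
    w <- max(1, f - 1):min(7, f + 1)
    ref <- x[, , f] - apply(x[, , w, drop = FALSE], c(1, 2), mean)
    expect_equal(got[, , f], ref)
  }
  # static stack -> zeros
  st <- array(3.2, c(4, 4, 6))
  expect_equal(moving_average_subtract(st), array(0, c(4, 4, 6)))
  # single-frame impulse retains 2/3 amplitude in its own frame
  imp <- array(0, c(3, 3, 5)); imp[2, 2, 3] <- 1
  expect_equal(moving_average_subtract(imp)[2, 2, 3], 2 / 3)
  expect_error(moving_average_subtract(array(0, c(2, 2, 2)), 3), "frames")
})

test_that("DAS focuses a point target on the polar grid", {
  geom <- acq_geometry(imaging_depth_mm = 50)
  pg <- roi_polar_grid(35, 4)
  xy <- polar_to_cart(35000, 4)
  rf <- simulate_rf(data.frame(x_um = xy[1], z_um = xy[2], amp = 1),
                    geom, -3, "full")
  img <- das_beamform(rf, geom, -3, pg)
  pk <- which(abs(img) == max(abs(img)), arr.ind = TRUE)
  expect_lt(abs(pg$r_um[pk[1]] - 35000), pg$dr_um)
  expect_lt(abs(pg$theta_deg[pk[2]] - 4), pg$dtheta_deg)
  # zero traces -> zero image
  expect_equal(max(abs(das_beamform(rf * 0, geom, -3, pg, attr(rf, "fs")))), 0)
  # two axial scatterers 10 mm apart: two peaks of comparable amplitude
  pg2 <- roi_polar_grid(35, 4, half_r_mm = 7, half_theta = 2)
  xyb <- polar_to_cart(c(30000, 40000), c(4, 4))
  rf2 <- simulate_rf(data.frame(x_um = xyb[, 1], z_um = xyb[, 2],
                                amp = c(1, 1)), geom, -3, "full")
  img2 <- abs(das_beamform(rf2, geom, -3, pg2))
  col <- which.min(abs(pg2$theta_deg - 4))
  prof <- img2[, col]
  p1 <- max(prof[pg2$r_um < 35000]); p2 <- max(prof[pg2$r_um > 35000])
  expect_lt(abs(p1 - p2) / max(p1, p2), 0.2)
})

test_that("CV weighting suppresses incoherent noise and keeps coherent peaks", {
  set.seed(3)
  N <- 480
  noise <- matrix(complex(real = rnorm(1500 * N), imaginary = rnorm(1500 * N)),
                  1500, N)
  attr(noise, "dims") <- c(1500, 1)
  das <- das_compound(noise); cv <- cv_compound(noise)
  supp_db <- 20 * log10(mean(abs(cv)) / mean(abs(das)))
  expect_lt(supp_db, -20)
  # fully coherent samples: weight = w_max, pixel proportional to the sum
  coh <- matrix(2 + 1i, 4, N); attr(coh, "dims") <- c(4, 1)
  expect_equal(cv_compound(coh, w_max = 1), das_compound(coh))
  # point target: CV and DAS peak at the same pixel
  geom <- acq_geometry(imaging_depth_mm = 50)
  pg <- roi_polar_grid(30, 0, half_r_mm = 1.5, half_theta = 2)
  xy <- polar_to_cart(30000, 0.5)
  samples <- NULL
  for (a in geom$steering_angles_deg) {
    rf <- simulate_rf(data.frame(x_um = xy[1], z_um = xy[2], amp = 1),
                      geom, a, "full")
    samples <- cbind(samples, delay_channel_samples(rf, geom, a, pg))
  }
  attr(samples, "dims") <- c(length(pg$r_um), length(pg$theta_deg))
  pk_das <- which.max(abs(das_compound(samples)))
  pk_cv <- which.max(abs(cv_compound(samples)))
  expect_equal(pk_cv, pk_das)
})

test_that("inter-angle Doppler correction recovers axial motion", {
  geom <- acq_geometry(imaging_depth_mm = 50)
  pg <- roi_polar_grid(30, 0)
  run_speed <- function(v_mm_s) {
    path <- function(t) data.frame(x_um = 0, z_um = 30000 + v_mm_s * 1e3 * t,
                                   amp = 1)
    sq <- simulate_rf_sequence(path, geom, n_frames = 3, am = FALSE)
    pa <- beamform_sequence(sq, pg)
    mc <- interangle_motion_correct(pa, geom, pg, pulses_per_angle = 1)
    unc <- abs(apply(pa[, , , 2], c(1, 2), sum))
    cor_ <- abs(apply(mc$corrected[, , , 2], c(1, 2), sum))
    pk <- which(unc == max(unc), arr.ind = TRUE)
    list(peak_unc = max(unc), peak_cor = max(cor_),
         v_est = mc$v_axial_mm_s[pk[1], pk[2]])
  }
  st <- run_speed(0)
  expect_equal(st$peak_cor, st$peak_unc, tolerance = 1e-9)
  expect_equal(st$v_est, 0, tolerance = 1e-6)
  mv <- run_speed(100)
  expect_gt(mv$peak_cor, mv$peak_unc)          # correction raises the peak
  slow <- run_speed(30)
  expect_lt(abs(slow$v_est - 30) / 30, 0.1)    # below the aliasing limit
  expect_lt(abs(mv$v_est - 100) / 100, 0.1)
  # unmatched angle axis is rejected
  expect_error(interangle_motion_correct(array(0i, c(4, 4, 3, 2)), geom, pg),
               "steering angles")
})

test_that("scan conversion maps the sector faithfully", {
  pg <- polar_grid(60, 40)
  cg <- cart_grid(c(20, 55), c(-15, 15))
  img <- outer(pg$r_um, pg$theta_deg,
               function(r, th) 1 + 0.5 * sin(r / 3000) * cos(th / 4))
  sc <- scan_convert(img, pg, cg)
  # uniform input stays uniform inside the mask
  u <- scan_convert(matrix(1, length(pg$r_um), length(pg$theta_deg)), pg, cg)
  expect_lt(max(abs(u$image[u$mask] - 1)), 1e-6)
  expect_true(all(u$image[!u$mask] == 0))
  # a polar point appears at (r sin, r cos)
  ip <- img * 0; ip[500, 60] <- 1
  sp <- scan_convert(ip, pg, cg)
  pk <- which(sp$image == max(sp$image), arr.ind = TRUE)
  xz <- polar_to_cart(pg$r_um[500], pg$theta_deg[60])
  expect_lt(abs(cg$x_um[pk[2]] - xz[1]), cg$dx_um)
  expect_lt(abs(cg$z_um[pk[1]] - xz[2]), cg$dz_um)
  # smooth round trip in the sector interior: RMS below 1% of range
  sel_r <- which(pg$r_um > 25000 & pg$r_um < 50000)
  sel_t <- which(abs(pg$theta_deg) < 15)
  pp <- expand.grid(r = pg$r_um[sel_r], th = pg$theta_deg[sel_t])
  xy <- polar_to_cart(pp$r, pp$th)
  ri <- (xy[, 2] - cg$z_um[1]) / cg$dz_um + 1
  ci <- (xy[, 1] - cg$x_um[1]) / cg$dx_um + 1
  vals <- srulm:::interp_bicubic(sc$image, ri, ci)
  tru <- img[cbind(match(pp$r, pg$r_um), match(pp$th, pg$theta_deg))]
  expect_lt(sqrt(mean((vals - tru)^2)) / diff(range(img)), 0.01)
})

test_that("the full contrast chain suppresses linear tissue", {
  geom <- acq_geometry(imaging_depth_mm = 50)
  pg <- roi_polar_grid(32, 0, half_r_mm = 3, half_theta = 2)
  # linear tissue scatterers only: contrast channel is empty after AM
  set.seed(7)
  tissue <- data.frame(x_um = runif(12, -1200, 1200),
                       z_um = runif(12, 29500, 34500),
                       amp = runif(12, 0.5, 1), gamma = 1)
  am_t <- simulate_rf_am(tissue, geom, -3)
  ceus_t <- das_beamform(am_contrast(am_t$half_a, am_t$full, am_t$half_b),
                         geom, -3, pg, fs = attr(am_t$full, "fs"))
  bmode <- das_beamform(am_t$full, geom, -3, pg, fs = attr(am_t$full, "fs"))
  expect_lt(sum(abs(ceus_t)^2) / sum(abs(bmode)^2), 1e-3)
  # adding a nonlinear bubble: the contrast channel localizes it
  sc <- rbind(tissue, data.frame(x_um = 0, z_um = 32000, amp = 0.8,
                                 gamma = 1.5))
  am <- simulate_rf_am(sc, geom, -3)
  ceus <- das_beamform(am_contrast(am$half_a, am$full, am$half_b),
                       geom, -3, pg, fs = attr(am$full, "fs"))
  pk <- which(abs(ceus) == max(abs(ceus)), arr.ind = TRUE)
  expect_lt(abs(pg$r_um[pk[1]] - 32000), 3 * pg$dr_um)
})

test_that("compounding more angles of a static point raises the peak", {
  geom <- acq_geometry(imaging_depth_mm = 50)
  pg <- roi_polar_grid(30, 0, half_r_mm = 1, half_theta = 1.5)
  xy <- polar_to_cart(30000, 0)
  imgs <- lapply(geom$steering_angles_deg, function(a) {
    rf <- simulate_rf(data.frame(x_um = xy[1], z_um = xy[2], amp = 1),
                      geom, a, "full")
    das_beamform(rf, geom, a, pg)
  })
  peaks <- vapply(seq_along(imgs), function(k)
    max(abs(Reduce(`+`, imgs[1:k]))), 0)
  expect_true(all(diff(peaks) > 0))
})
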