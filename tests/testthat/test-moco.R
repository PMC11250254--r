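# Gating and the two-level motion-correction machinery.

make_motion_stack <- function(frame_rate = 50, duration = 4, seed = 2,
                              peak_um = 1500) {
  grid <- cart_grid(c(55, 65), c(-5, 5), dz_um = 135, dx_um = 135)
  gt <- simulate_transit(empty_vessel_tree(), duration, frame_rate, 0,
                         seed = seed)
  mm <- motion_model(period_s = 0.8, peak_um = peak_um,
                     systole_fraction = 0.35,
                     domain = list(x_mm = c(-5, 5), z_mm = c(55, 65)),
                     seed = seed)
  gt <- apply_tissue_motion(gt, mm)
  sim <- render_ceus_stack(gt, psf_model(), grid, snr_db = Inf, seed = seed)
  list(sim = sim, mm = mm, grid = grid, frame_rate = frame_rate)
}

test_that("gating finds systole starts and diastole plateaus", {
  fx <- make_motion_stack()
  ci <- gate_diastole(fx$sim$bmode, fx$frame_rate)
  expect_equal(ci$period_s, 0.8, tolerance = 0.05)
  # one start per cycle, spaced by the period
  expect_equal(length(ci$systole_starts), 5)
  expect_equal(diff(ci$systole_starts), rep(40, 4), tolerance = 0.2)
  # every detected start lies inside a systolic interval of the construction
  phases <- ((ci$systole_starts - 1) / fx$frame_rate) %% 0.8
  expect_true(all(phases < 0.35 + 0.04))
  # diastole plateaus clipped to [0.2, 0.4] s and disjoint
  lens <- vapply(ci$diastole_frames, length, 0L) / fx$frame_rate
  expect_true(all(lens >= 0.2 - 1e-9 & lens <= 0.4 + 1e-9))
  expect_equal(anyDuplicated(unlist(ci$diastole_frames)), 0)
  # identical adjacent frames correlate exactly 1
  cc <- frame_correlation(fx$sim$bmode[, , c(1, 1, 2, 3)])
  expect_identical(cc[1], 1)
  expect_lt(cc[2], 1)
})

test_that("a static stack takes the defined no-periodicity error path", {
  st <- array(rep(make_texture(20, 20), 12), c(20, 20, 12))
  err <- tryCatch(gate_diastole(st, 50), condition = function(c) c)
  expect_s3_class(err, "srulm_no_periodicity")
  expect_length(err$correlation, 11)
})

test_that("SVD tissue extraction keeps tissue, drops sparse movers", {
  # rank-1 static stack reconstructs exactly
  tex <- make_texture(24, 24, seed = 8)
  st <- array(rep(tex, 10), c(24, 24, 10))
  expect_equal(tissue_from_svd(st, 0.05), st, tolerance = 1e-10)
  # fraction = 1 is the identity
  set.seed(1)
  rnd <- array(rnorm(24 * 24 * 10), c(24, 24, 10))
  expect_equal(tissue_from_svd(rnd, 1), rnd, tolerance = 1e-10)
  # static tissue + sparse bright moving dots: tissue recovered < 10% error
  dots <- st
  set.seed(2)
  for (f in 1:10) dots[sample(24, 1), sample(24, 1), f] <-
      dots[sample(24, 1), sample(24, 1), f] + 3
  rec <- tissue_from_svd(dots, 0.05)
  expect_lt(sqrt(mean((rec - st)^2)) / sqrt(mean(st^2)), 0.1)
})

test_that("reference selection favours typical frames and breaks ties low", {
  tex <- make_texture(32, 32, seed = 3)
  same <- array(rep(tex, 6), c(32, 32, 6))
  expect_identical(select_reference(same), 1L)
  expect_identical(select_reference(same[, , 1, drop = FALSE]), 1L)
  # an outlier frame is never selected
  out <- same
  out[, , 4] <- matrix(runif(32 * 32), 32, 32)
  expect_true(select_reference(out) != 4L)
})

test_that("affine registration recovers a known 3-pixel translation", {
  img <- make_texture(96, 96)
  tf_true <- list(affine = cbind(diag(2), c(3, -3)), ctrl_r = NULL,
                  ctrl_c = NULL, dims = c(96, 96))
  moving <- apply_transform_image(img, tf_true)
  tf <- register_pair(moving, img, nonrigid = FALSE)
  # recovered transform is the inverse translation
  expect_equal(tf$affine[, 3], c(-3, 3), tolerance = 0.1 / 3)
  expect_lt(max(abs(tf$affine[, 1:2] - diag(2))), 1e-3)
  # moving == fixed -> identity within 1e-3 px
  tf0 <- register_pair(img, img, nonrigid = FALSE)
  expect_lt(max(abs(tf0$affine[, 3])), 1e-3)
  expect_error(register_pair(img * NA, img), "non-finite")
})

test_that("B-spline registration recovers a known smooth 10-px warp", {
  img <- make_texture(96, 96)
  bw <- srulm:::bspline_setup(96, 96, 32)
  ctrl <- withr::with_seed(9, list(
    r = matrix(rnorm(bw$ncr * bw$ncc), bw$ncr, bw$ncc),
    c = matrix(rnorm(bw$ncr * bw$ncc), bw$ncr, bw$ncc)))
  ur <- bw$Br %*% ctrl$r %*% t(bw$Bc); uc <- bw$Br %*% ctrl$c %*% t(bw$Bc)
  sc <- 10 / max(sqrt(ur^2 + uc^2))
  tf_w <- list(affine = cbind(diag(2), c(0, 0)), ctrl_r = ctrl$r * sc,
               ctrl_c = ctrl$c * sc, spacing = 32, dims = c(96, 96))
  fixed <- apply_transform_image(img, tf_w)
  tf <- register_pair(img, fixed, spacing = 16, lambda = 0.001, border = 8)
  interior <- 13:84
  rr <- rep(interior, length(interior))
  cc <- rep(interior, each = length(interior))
  q_rec <- transform_points(tf, cbind(rr, cc))
  q_true <- transform_points(tf_w, cbind(rr, cc))
  err <- sqrt(rowSums((q_rec - q_true)^2))
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("point warps agree with image warps and invert correctly", {
  img <- make_texture(64, 64, seed = 12)
  tf <- identity_transform(c(64, 64), spacing = 16)
  tf$affine <- cbind(matrix(c(1.01, 0.02, -0.01, 0.99), 2, 2), c(2, -1.5))
  tf$ctrl_r[3, 3] <- 2; tf$ctrl_c[4, 4] <- -2
  # identity field leaves a stack unchanged
  st <- array(rep(img, 3), c(64, 64, 3))
  expect_identical(warp_stack(st, rep(list(identity_transform(c(64, 64))), 3)),
                   st)
  # round trip point inversion
  pts <- cbind(runif(40, 10, 54), runif(40, 10, 54))
  fwd <- transform_points(tf, pts)
  back <- invert_transform_points(tf, fwd)
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 0.5)
  # a bright landmark moves where the point warp says it should
  lm <- matrix(0, 64, 64); lm[30, 40] <- 1
  sm <- srulm:::conv2_zero(lm, srulm:::gaussian_kernel(1.5))
  w <- apply_transform_image(sm, tf)
  pk <- which(w == max(w), arr.ind = TRUE)
  src <- invert_transform_points(tf, cbind(30, 40))  # where (30,40) lands
  expect_lt(sqrt(sum((pk - src)^2)), 1.3)
})

test_that("inter-cycle rigid registration recovers shift and rotation", {
  tex <- make_texture(80, 80, seed = 6)
  expect_equal(intercycle_rigid(list(tex, tex))[[2]]$theta_deg, 0,
               tolerance = 1e-3)
  # 2-px shift
  tf_s <- list(affine = cbind(diag(2), c(2, 0)), ctrl_r = NULL,
               ctrl_c = NULL, dims = c(80, 80))
  shifted <- apply_transform_image(tex, tf_s)
  rig <- intercycle_rigid(list(tex, shifted))
  # transforms map first-cycle coordinates into cycle k (for resampling),
  # so a +2-row shifted copy is aligned by the inverse translation
  expect_equal(rig[[2]]$dr, -2, tolerance = 0.2 / 2)
  # 2-degree rotation about the centre
  th <- 2 * pi / 180
  ctr <- c(40.5, 40.5)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tf_r <- list(affine = cbind(R, ctr - R %*% ctr), ctrl_r = NULL,
               ctrl_c = NULL, dims = c(80, 80))
  rotated <- apply_transform_image(tex, tf_r)
  rig2 <- intercycle_rigid(list(tex, rotated))
  expect_equal(abs(rig2[[2]]$theta_deg), 2, tolerance = 0.1)
})

test_that("full motion correction reduces 1.5 mm cardiac motion below 0.2 mm", {
  fr <- 30
  grid <- cart_grid(c(55, 69.7), c(-7.4, 7.4), dz_um = 135, dx_um = 135)
  gt <- simulate_transit(empty_vessel_tree(), 0.82, fr, 0, seed = 3)
  mm <- motion_model(period_s = 0.8, peak_um = 1500,
                     domain = list(x_mm = c(-7.4, 7.4), z_mm = c(55, 69.7)),
                     seed = 3)
  gt <- apply_tissue_motion(gt, mm)
  sim <- render_ceus_stack(gt, psf_model(), grid, snr_db = Inf, seed = 3)
  bm <- sim$bmode
  nf <- dim(bm)[3]
  mc <- moco_cycle(bm, bm, spacing = 16, lambda = 0.01, svd_fraction = 0.5)
  # reference frame pixels are untouched
  expect_identical(mc$bmode_corrected[, , mc$reference], bm[, , mc$reference])
  lm <- expand.grid(r = seq(15, 95, by = 10), c = seq(15, 95, by = 10))
  pix <- cbind(grid$x_um[lm$c], grid$z_um[lm$r])
  uref <- motion_displacement(mm, (mc$reference - 1) / fr, pix)
  resid <- unc <- numeric(nf)
  for (f in seq_len(nf)) {
    q <- pix - uref
    W <- q
    for (it in 1:10) W <- q + motion_displacement(mm, (f - 1) / fr, W)
    unc[f] <- mean(sqrt(rowSums((W - pix)^2)))
    pr <- cbind((pix[, 2] - grid$z_um[1]) / grid$dz_um + 1,
                (pix[, 1] - grid$x_um[1]) / grid$dx_um + 1)
    West_px <- transform_points(mc$transforms[[f]], pr)
    West <- cbind(grid$x_um[1] + (West_px[, 2] - 1) * grid$dx_um,
                  grid$z_um[1] + (West_px[, 1] - 1) * grid$dz_um)
    resid[f] <- mean(sqrt(rowSums((West - W)^2)))
  }
  expect_gt(max(unc), 1000)            # motion really was ~1.5 mm peak
  expect_lt(mean(resid), 200)          # corrected below 0.2 mm
  expect_lt(max(resid), 200 * 2)       # even the worst systolic frame is close
})
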