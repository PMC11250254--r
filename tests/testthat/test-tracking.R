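test_that("assignment solver finds the global optimum (brute force oracle)", {
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v))
    out <- NULL
    for (i in seq_along(v)) out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(2:5, 1); m <- n + sample(0:2, 1)
    C <- matrix(round(runif(n * m) * 100), n, m)
    C[sample(n * m, 2)] <- 1e9              # near-forbidden entries
    a <- assignment_solve(C)
    expect_equal(anyDuplicated(a), 0)
    pm <- perms(seq_len(m))
    best <- min(apply(pm, 1, function(p) sum(C[cbind(seq_len(n), p[seq_len(n)])])))
    expect_equal(sum(C[cbind(seq_len(n), a)]), best)
  }
  expect_identical(assignment_solve(matrix(0, 0, 3)), integer())
})

test_that("Kalman prediction is constant-velocity with growing uncertainty", {
  km <- srulm:::kalman_matrices(0.1, q = c(1, 1), r_var = 1)
  tr <- srulm:::new_track_state(100, 200, c(50, -30), 1, 1L, 1L, km)
  pred <- kalman_predict(list(tr), km)[[1]]
  expect_equal(pred$pred, c(100 + 5, 200 - 3))
  # zero velocity: prediction = last position
  tr0 <- srulm:::new_track_state(7, 8, c(0, 0), 1, 1L, 2L, km)
  expect_equal(kalman_predict(list(tr0), km)[[1]]$pred, c(7, 8))
  # innovation covariance grows monotonically with Q
  km_big <- srulm:::kalman_matrices(0.1, q = c(100, 100), r_var = 1)
  S_small <- kalman_predict(list(tr), km)[[1]]$S
  S_big <- kalman_predict(list(srulm:::new_track_state(100, 200, c(50, -30),
                                                       1, 1L, 1L, km_big)),
                          km_big)[[1]]$S
  expect_true(all(diag(S_big) > diag(S_small)))
})

test_that("pairing respects the search window and enumerated optima", {
  fr <- 305
  km <- srulm:::kalman_matrices(1 / fr, q = c(1e7, 1e7))
  mk_track <- function(x, z, v, id, inten = 1)
    srulm:::new_track_state(x, z, v, inten, 1L, id, km)
  # one track, one in-window localization -> paired
  tr <- kalman_predict(list(mk_track(0, 0, c(0, 0), 1L)), km)
  loc <- data.frame(x_um = 30, z_um = 20, intensity = 1)
  asg <- pair_frame(tr, loc, fr)
  expect_equal(nrow(asg$pairs), 1)
  # displacement beyond 150 mm/s / frame rate -> dummy (new track)
  too_far <- data.frame(x_um = 150 / fr * 1e3 + 50, z_um = 0, intensity = 1)
  asg2 <- pair_frame(tr, too_far, fr)
  expect_equal(nrow(asg2$pairs), 0)
  expect_equal(asg2$unmatched_locs, 1L)
  # two crossing bubbles: assignment equals the cheaper enumerated pairing
  tra <- kalman_predict(list(mk_track(0, 0, c(3e4, 0), 1L, 1.0),
                             mk_track(400, 0, c(-3e4, 0), 2L, 2.0)), km)
  locs <- data.frame(x_um = c(98, 302), z_um = c(0, 0),
                     intensity = c(1.0, 2.0))
  asg3 <- pair_frame(tra, locs, fr)
  cost_of_pairing <- function(perm) {
    sum(vapply(1:2, function(i) {
      t <- tra[[i]]; j <- perm[i]
      ic <- abs(t$intensity - locs$intensity[j]) /
        max(t$intensity, locs$intensity[j])
      y <- c(locs$x_um[j] - t$pred[1], locs$z_um[j] - t$pred[2])
      ic / max(srulm:::mvn2_density(y, t$S), 1e-12)
    }, 0))
  }
  best <- if (cost_of_pairing(c(1, 2)) <= cost_of_pairing(c(2, 1)))
    c(1, 2) else c(2, 1)
  got <- asg3$pairs[order(asg3$pairs[, 1]), 2]
  expect_equal(got, best)
  # empty inputs
  asg0 <- pair_frame(list(), data.frame(x_um = 1, z_um = 1, intensity = 1), fr)
  expect_equal(nrow(asg0$pairs), 0)
})

test_that("fuzzy initialization averages in-window candidate velocities", {
  fr <- 305
  expect_equal(as.numeric(fuzzy_init(
    data.frame(x_um = 0, z_um = 0, intensity = 1),
    data.frame(x_um = numeric(), z_um = numeric(), intensity = numeric()),
    fr)), c(0, 0))
  # exactly one neighbour: velocity = displacement x frame rate
  one <- fuzzy_init(data.frame(x_um = 100, z_um = 50, intensity = 1),
                    data.frame(x_um = 0, z_um = 0, intensity = 1), fr)
  expect_equal(as.numeric(one), c(100 * fr, 50 * fr))
  # several neighbours: inside the convex hull of candidate velocities
  prev <- data.frame(x_um = c(0, 120, -60), z_um = c(0, 40, 90),
                     intensity = c(1, 1.3, 0.8))
  v <- fuzzy_init(data.frame(x_um = 30, z_um = 30, intensity = 1), prev, fr)
  cand <- cbind((30 - prev$x_um) * fr, (30 - prev$z_um) * fr)
  expect_gte(v[1], min(cand[, 1])); expect_lte(v[1], max(cand[, 1]))
  expect_gte(v[2], min(cand[, 2])); expect_lte(v[2], max(cand[, 2]))
  # out-of-window neighbours ignored
  far <- data.frame(x_um = 5e4, z_um = 5e4, intensity = 1)
  expect_equal(as.numeric(fuzzy_init(data.frame(x_um = 0, z_um = 0,
                                                intensity = 1), far, fr)),
               c(0, 0))
})

test_that("process noise is recovered from warm-up tracks", {
  fr <- 305; dt <- 1 / fr
  # noiseless constant-velocity tracks -> variance far below measurement noise
  locs_cv <- do.call(rbind, lapply(0:2, function(b)
    data.frame(frame = 1:30, x_um = b * 5e4 + (1:30) * 100,
               z_um = b * 5e4, intensity = 1)))
  est <- estimate_process_noise(locs_cv, fr, max_speed_mm_s = 1e5)
  expect_lt(max(est$q) * dt, 1e-3 * 13.5^2 / 12)
  # white-acceleration model recovered within 20%
  q_true <- 5e8
  sim <- withr::with_seed(3, {
    nsteps <- 10000
    v <- matrix(0, nsteps, 2); p <- matrix(0, nsteps, 2)
    for (k in 2:nsteps) {
      v[k, ] <- v[k - 1, ] + rnorm(2, 0, sqrt(q_true * dt))
      p[k, ] <- p[k - 1, ] + v[k - 1, ] * dt
    }
    p
  })
  locs_wa <- do.call(rbind, lapply(0:(nrow(sim) / 40 - 1), function(b) {
    i <- b * 40 + 1:40
    data.frame(frame = 1:40, x_um = sim[i, 1] + b * 1e6, z_um = sim[i, 2],
               intensity = 1)
  }))
  est2 <- estimate_process_noise(locs_wa, fr, warmup_frames = 40,
                                 max_speed_mm_s = 1e6)
  expect_lt(max(abs(est2$q - q_true) / q_true), 0.2)
  # empty input takes the default path
  est0 <- estimate_process_noise(data.frame(frame = integer(), x_um = numeric(),
                                            z_um = numeric(),
                                            intensity = numeric()), fr)
  expect_true(est0$default)
})

test_that("track-length filtering keeps only tracks of >= 4 frames", {
  fr <- 100
  mk <- function(id, n) data.frame(track_id = id, frame = 1:n,
                                   x_um = (1:n) * 50, z_um = 0,
                                   vx_mm_s = 5, vz_mm_s = 0, intensity = 1)
  ts <- structure(rbind(mk(1, 2), mk(2, 3), mk(3, 4), mk(4, 5)),
                  frame_rate = fr, class = c("track_set", "data.frame"))
  kept <- finalize_tracks(ts, fr, min_frames = 4L)
  expect_setequal(unique(kept$track_id), c(3, 4))
  all_kept <- finalize_tracks(ts, fr, min_frames = 1L)
  expect_setequal(unique(all_kept$track_id), 1:4)
  empty <- finalize_tracks(list(), fr)
  expect_equal(nrow(empty), 0)
})

test_that("tracker reaches 95% identity accuracy; Kalman beats NN on crossings", {
  # standard simulation: parallel vessels, lognormal speeds, snapped locs
  tree <- vessel_phantom("parallel_pair", centre_mm = c(0, 70),
                         separation_um = 3000, length_mm = 12,
                         speed_mm_s = 40)
  gt <- simulate_transit(tree, 1.0, 305, bubble_rate = 40,
                         speed_law = list(dist = "lognormal",
                                          meanlog = log(40), sdlog = 0.3),
                         seed = 4)
  locs <- data.frame(frame = gt$frame, x_um = round(gt$x_um / 13.5) * 13.5,
                     z_um = round(gt$z_um / 13.5) * 13.5,
                     intensity = gt$intensity)
  ts <- track_localizations(locs, 305)
  expect_gte(link_accuracy(ts, gt), 0.95)
  # assignment is one-to-one: never more track points in a frame than
  # localizations (coordinate collisions from grid snapping are allowed)
  per_frame_ts <- table(ts$frame)
  per_frame_locs <- table(locs$frame)
  expect_true(all(per_frame_ts <=
                    per_frame_locs[names(per_frame_ts)]))
  # per-track mean speed within 10% for constant-flow simulation
  gtc <- simulate_transit(tree, 1.0, 305, bubble_rate = 20,
                          speed_law = list(dist = "constant"), seed = 6)
  locs_c <- data.frame(frame = gtc$frame, x_um = round(gtc$x_um / 13.5) * 13.5,
                       z_um = round(gtc$z_um / 13.5) * 13.5,
                       intensity = gtc$intensity)
  tsc <- track_localizations(locs_c, 305)
  sp <- tapply(sqrt(tsc$vx_mm_s^2 + tsc$vz_mm_s^2), tsc$track_id, mean,
               na.rm = TRUE)
  expect_lt(abs(mean(sp) - 40) / 40, 0.1)
  # ablation: the motion model strictly wins on crossing scenes
  sw_k <- 0L; sw_n <- 0L
  for (seed in 1:12) {
    sc <- crossing_scene(seed)
    l <- sc[, c("frame", "x_um", "z_um", "intensity")]
    sw_k <- sw_k + count_switches(track_localizations(l, 305,
                                                      method = "kalman"), sc)
    sw_n <- sw_n + count_switches(track_localizations(l, 305,
                                                      method = "nn"), sc)
  }
  expect_lt(sw_k, sw_n)
})
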