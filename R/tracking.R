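# Feature-motion-model microbubble tracking: constant-velocity Kalman
# prediction, an intensity-plus-motion pairing cost, globally optimal
# bipartite assignment with dummy nodes, fuzzy velocity initialization for
# new tracks, data-driven process-noise estimation, and track-length
# filtering.

#' Globally optimal rectangular assignment (Hungarian algorithm)
#'
#' Minimizes the total cost of a one-to-one row-to-column assignment
#' (shortest-augmenting-path formulation, O(n^3)). Rows must not outnumber
#' columns; use [pair_frame()] for the dummy-augmented tracking problem.
#'
#' @param cost numeric matrix, `nrow <= ncol`, finite entries.
#' @return integer vector: assigned column per row.
#' @export
assignment_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer())
  if (n > m) stopf("cost matrix must have nrow <= ncol")
  if (any(!is.finite(cost))) stopf("cost matrix must be finite (use a large sentinel)")
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)         # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- cost[i0, free_j] - u[i0] - v[free_j + 1L]
      better <- cur < minv[free_j]
      if (any(better)) {
        bj <- free_j[better]
        minv[bj] <- cur[better]
        way[bj + 1L] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      uj <- which(used) - 1L                 # used "column" ids incl. 0
      rows_used <- p[uj + 1L]
      u[rows_used[rows_used > 0L]] <- u[rows_used[rows_used > 0L]] + delta
      v[uj + 1L] <- v[uj + 1L] - delta
      nf <- which(!used[-1L])
      minv[nf] <- minv[nf] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}

# --- Kalman constant-velocity model ----------------------------------------

kalman_matrices <- function(dt, q = c(1e4, 1e4), r_var = 13.5^2 / 12) {
  F <- diag(4)
  F[1, 3] <- dt; F[2, 4] <- dt
  H <- cbind(diag(2), matrix(0, 2, 2))
  # discrete white-acceleration process noise per axis
  Qa <- function(qq) qq * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
  Q <- matrix(0, 4, 4)
  Q[c(1, 3), c(1, 3)] <- Qa(q[1])
  Q[c(2, 4), c(2, 4)] <- Qa(q[2])
  R <- diag(rep(r_var, 2))
  list(F = F, H = H, Q = Q, R = R)
}

new_track_state <- function(x_um, z_um, v_um_s, intensity, frame, id, km,
                            v_var = NULL) {
  P <- diag(c(km$R[1, 1], km$R[2, 2],
              v_var %||% rep(max(1e6, 4 * km$Q[3, 3]), 2)))
  list(id = id, x = c(x_um, z_um, v_um_s), P = P, intensity = intensity,
       frames = frame, xs = x_um, zs = z_um, ints = intensity)
}

#' Kalman constant-velocity prediction
#'
#' Propagates each track one step: `x' = F x`, `P' = F P F' + Q`, and
#' returns the predicted measurement and innovation covariance
#' `S = H P' H' + R` used by the pairing probability.
#'
#' @param tracks list of track states. @param km matrices from the tracker.
#' @return list of tracks with `pred` (length-2) and `S` (2 x 2) fields.
#' @export
kalman_predict <- function(tracks, km) {
  lapply(tracks, function(tr) {
    xp <- km$F %*% tr$x
    Pp <- km$F %*% tr$P %*% t(km$F) + km$Q
    tr$xp <- as.vector(xp)
    tr$Pp <- Pp
    tr$pred <- as.vector(km$H %*% xp)
    tr$S <- km$H %*% Pp %*% t(km$H) + km$R
    tr
  })
}

kalman_update <- function(tr, z, km) {
  y <- z - km$H %*% tr$xp
  S <- tr$S
  K <- tr$Pp %*% t(km$H) %*% solve(S)
  tr$x <- as.vector(tr$xp + K %*% y)
  tr$P <- (diag(4) - K %*% km$H) %*% tr$Pp
  tr
}

mvn2_density <- function(y, S) {
  dt <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / dt
  q <- y[1]^2 * inv[1, 1] + 2 * y[1] * y[2] * inv[1, 2] + y[2]^2 * inv[2, 2]
  exp(-q / 2) / (2 * pi * sqrt(dt))
}

#' Pair active tracks with new localizations
#'
#' The cost of a candidate pair is the intensity difference normalized by
#' the stronger of the two intensities, divided by the Kalman innovation
#' likelihood (bivariate Gaussian density, floored at `p_floor`). Candidate
#' pairs are restricted to displacements within `max_speed / frame_rate`.
#' Tracks and localizations may fall to dummy partners when every real
#' pairing exceeds the dummy cost limit; the assignment (including dummies)
#' is the exact global cost minimum.
#'
#' @param tracks predicted track list ([kalman_predict()]).
#' @param locs data.frame with `x_um`, `z_um`, `intensity`.
#' @param frame_rate Hz. @param max_speed_mm_s search-window speed limit.
#' @param p_floor floor on the motion probability.
#' @param dummy_cost dummy cost limit; `NULL` derives it as the cost of a
#'   median intensity mismatch at the search-window edge.
#' @return list `pairs` (two-column matrix track-index, loc-index),
#'   `unmatched_tracks`, `unmatched_locs`.
#' @export
pair_frame <- function(tracks, locs, frame_rate, max_speed_mm_s = 150,
                       p_floor = 1e-12, dummy_cost = NULL) {
  nt <- length(tracks); nl <- nrow(locs)
  if (nt == 0L || nl == 0L)
    return(list(pairs = matrix(0L, 0, 2),
                unmatched_tracks = seq_len(nt),
                unmatched_locs = seq_len(nl)))
  win_um <- max_speed_mm_s / frame_rate * 1e3
  BIG <- 1e9
  C <- matrix(BIG, nt, nl)
  icost <- matrix(NA_real_, nt, nl)
  for (i in seq_len(nt)) {
    tr <- tracks[[i]]
    last <- c(utils::tail(tr$xs, 1L), utils::tail(tr$zs, 1L))
    disp <- sqrt((locs$x_um - last[1])^2 + (locs$z_um - last[2])^2)
    ok <- which(disp <= win_um)
    for (j in ok) {
      ic <- abs(tr$intensity - locs$intensity[j]) /
        max(tr$intensity, locs$intensity[j])
      y <- c(locs$x_um[j] - tr$pred[1], locs$z_um[j] - tr$pred[2])
      p <- max(mvn2_density(y, tr$S), p_floor)
      icost[i, j] <- ic
      C[i, j] <- ic / p
    }
  }
  if (is.null(dummy_cost)) {
    med_ic <- stats::median(icost[is.finite(C) & C < BIG], na.rm = TRUE)
    if (!is.finite(med_ic)) med_ic <- 0.5
    # typical motion probability at the window edge
    S_med <- diag(rep(stats::median(vapply(tracks,
                                           function(t) t$S[1, 1], 0)), 2))
    p_edge <- max(mvn2_density(c(win_um, 0), S_med), p_floor)
    dummy_cost <- max(med_ic, 0.05) / p_edge
  }
  n <- nt + nl
  A <- matrix(BIG, n, n)
  A[seq_len(nt), seq_len(nl)] <- C
  for (i in seq_len(nt)) A[i, nl + i] <- dummy_cost
  for (j in seq_len(nl)) A[nt + j, j] <- dummy_cost
  A[(nt + 1):n, (nl + 1):n] <- 0
  sol <- assignment_solve(A)
  pairs <- cbind(track = seq_len(nt), loc = sol[seq_len(nt)])
  real <- pairs[, 2] <= nl & A[cbind(pairs[, 1], pairs[, 2])] < BIG
  pairs <- pairs[real, , drop = FALSE]
  list(pairs = pairs,
       unmatched_tracks = setdiff(seq_len(nt), pairs[, 1]),
       unmatched_locs = setdiff(seq_len(nl), pairs[, 2]))
}

#' Fuzzy velocity initialization for a newly appeared bubble
#'
#' Instead of assuming a static start, the initial velocity is the
#' membership-weighted average of the velocities implied by every
#' previous-frame localization inside the search window; memberships decay
#' with distance and with relative intensity mismatch. With no in-window
#' neighbour the initial velocity is zero.
#'
#' @param loc one-row data.frame (`x_um`, `z_um`, `intensity`).
#' @param prev_locs previous-frame localizations.
#' @param frame_rate Hz. @param max_speed_mm_s search window.
#' @return length-2 velocity (um/s) with attribute `spread` (membership-
#'   weighted velocity variance, used to seed the state covariance).
#' @export
fuzzy_init <- function(loc, prev_locs, frame_rate, max_speed_mm_s = 150) {
  win_um <- max_speed_mm_s / frame_rate * 1e3
  if (is.null(prev_locs) || nrow(prev_locs) == 0L)
    return(structure(c(0, 0), spread = NULL))
  dx <- loc$x_um - prev_locs$x_um
  dz <- loc$z_um - prev_locs$z_um
  d <- sqrt(dx^2 + dz^2)
  ok <- d <= win_um
  if (!any(ok)) return(structure(c(0, 0), spread = NULL))
  dx <- dx[ok]; dz <- dz[ok]; d <- d[ok]
  di <- abs(loc$intensity - prev_locs$intensity[ok]) /
    pmax(loc$intensity, prev_locs$intensity[ok])
  m <- exp(-(d / (win_um / 2))^2) * exp(-(di / 0.5)^2)
  m <- m / sum(m)
  vx <- dx * frame_rate; vz <- dz * frame_rate
  v <- c(sum(m * vx), sum(m * vz))
  spread <- c(sum(m * (vx - v[1])^2), sum(m * (vz - v[2])^2))
  structure(v, spread = spread)
}

#' Estimate the process-noise covariance from the data
#'
#' A warm-up pass of plain nearest-neighbour tracking yields provisional
#' tracks; the empirical variance of their frame-to-frame velocity
#' increments gives the white-acceleration intensity `q` per axis
#' (`var(dv) = q * dt`). The measurement noise `R` is fixed from the
#' localization grid quantization. Too few warm-up steps fall back to a
#' documented default.
#'
#' @param locs localization data.frame (`frame, x_um, z_um, intensity`).
#' @param frame_rate Hz.
#' @param warmup_frames frames used for the warm-up pass.
#' @param max_speed_mm_s gating speed.
#' @param default_q fallback white-acceleration intensity (um^2/s^3).
#' @return list `q` (length-2), `n_steps` used.
#' @export
estimate_process_noise <- function(locs, frame_rate, warmup_frames = 30L,
                                   max_speed_mm_s = 150,
                                   default_q = 1e7) {
  dt <- 1 / frame_rate
  frames <- sort(unique(locs$frame))
  frames <- frames[seq_len(min(length(frames), warmup_frames))]
  win_um <- max_speed_mm_s / frame_rate * 1e3
  # greedy NN linking
  tracks <- list()
  active <- list()
  for (f in frames) {
    cur <- locs[locs$frame == f, , drop = FALSE]
    used <- rep(FALSE, nrow(cur))
    nxt <- list()
    for (tr in active) {
      last <- tr$pos[nrow(tr$pos), ]
      d <- sqrt((cur$x_um - last[1])^2 + (cur$z_um - last[2])^2)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= win_um) {
        used[j] <- TRUE
        tr$pos <- rbind(tr$pos, c(cur$x_um[j], cur$z_um[j]))
        nxt[[length(nxt) + 1L]] <- tr
      } else tracks[[length(tracks) + 1L]] <- tr
    }
    for (j in which(!used))
      nxt[[length(nxt) + 1L]] <- list(pos = matrix(c(cur$x_um[j], cur$z_um[j]),
                                                   1, 2))
    active <- nxt
  }
  tracks <- c(tracks, active)
  dvx <- c(); dvz <- c()
  for (tr in tracks) {
    if (nrow(tr$pos) < 3L) next
    v <- diff(tr$pos) / dt
    dvx <- c(dvx, diff(v[, 1]))
    dvz <- c(dvz, diff(v[, 2]))
  }
  if (length(dvx) < 8L)
    return(list(q = c(default_q, default_q), n_steps = length(dvx),
                default = TRUE))
  list(q = c(stats::var(dvx) / dt, stats::var(dvz) / dt),
       n_steps = length(dvx), default = FALSE)
}

#' Track localizations across frames
#'
#' Runs the feature-motion-model tracker over a localization table:
#' per frame, Kalman prediction, global assignment ([pair_frame()]),
#' Kalman update of matched tracks, termination of unmatched tracks
#' (consecutive-frame linking only), and fuzzy-initialized new tracks.
#'
#' @param locs data.frame `frame, x_um, z_um, intensity`.
#' @param frame_rate Hz.
#' @param max_speed_mm_s search-window speed.
#' @param method `"kalman"` (feature-motion-model) or `"nn"` (greedy
#'   nearest-neighbour ablation).
#' @param q process-noise intensity per axis; `NULL` estimates it with
#'   [estimate_process_noise()].
#' @param r_var measurement variance (um^2), default the 13.5 um grid
#'   quantization variance.
#' @param min_frames minimum track length kept by [finalize_tracks()].
#' @param p_floor,dummy_cost forwarded to [pair_frame()].
#' @return a `track_set` (see [finalize_tracks()]).
#' @export
track_localizations <- function(locs, frame_rate, max_speed_mm_s = 150,
                                method = c("kalman", "nn"), q = NULL,
                                r_var = 13.5^2 / 12, min_frames = 4L,
                                p_floor = 1e-12, dummy_cost = NULL) {
  method <- match.arg(method)
  dt <- 1 / frame_rate
  if (is.null(q)) {
    est <- estimate_process_noise(locs, frame_rate,
                                  max_speed_mm_s = max_speed_mm_s)
    q <- est$q
  }
  km <- kalman_matrices(dt, q = q, r_var = r_var)
  frames <- if (nrow(locs)) seq(min(locs$frame), max(locs$frame)) else integer()
  active <- list()
  done <- list()
  next_id <- 1L
  prev_locs <- NULL
  win_um <- max_speed_mm_s / frame_rate * 1e3
  for (f in frames) {
    cur <- locs[locs$frame == f, , drop = FALSE]
    if (length(active)) active <- kalman_predict(active, km)
    if (method == "nn" && length(active) && nrow(cur)) {
      # greedy nearest-neighbour ablation (no motion model in the cost)
      used <- rep(FALSE, nrow(cur))
      pairs <- matrix(0L, 0, 2)
      last <- t(vapply(active, function(tr)
        c(utils::tail(tr$xs, 1L), utils::tail(tr$zs, 1L)), numeric(2)))
      for (i in seq_along(active)) {
        d <- sqrt((cur$x_um - last[i, 1])^2 + (cur$z_um - last[i, 2])^2)
        d[used] <- Inf
        j <- which.min(d)
        if (length(j) && is.finite(d[j]) && d[j] <= win_um) {
          used[j] <- TRUE
          pairs <- rbind(pairs, c(i, j))
        }
      }
      asg <- list(pairs = pairs,
                  unmatched_tracks = setdiff(seq_along(active), pairs[, 1]),
                  unmatched_locs = which(!used))
    } else {
      asg <- pair_frame(active, cur, frame_rate, max_speed_mm_s,
                        p_floor = p_floor, dummy_cost = dummy_cost)
    }
    keep <- vector("list", nrow(asg$pairs))
    if (nrow(asg$pairs)) for (k in seq_len(nrow(asg$pairs))) {
      i <- asg$pairs[k, 1]; j <- asg$pairs[k, 2]
      tr <- kalman_update(active[[i]], c(cur$x_um[j], cur$z_um[j]), km)
      tr$intensity <- cur$intensity[j]
      tr$frames <- c(tr$frames, f)
      tr$xs <- c(tr$xs, cur$x_um[j]); tr$zs <- c(tr$zs, cur$z_um[j])
      tr$ints <- c(tr$ints, cur$intensity[j])
      keep[[k]] <- tr
    }
    for (i in asg$unmatched_tracks) done[[length(done) + 1L]] <- active[[i]]
    for (j in asg$unmatched_locs) {
      v0 <- fuzzy_init(cur[j, , drop = FALSE], prev_locs, frame_rate,
                       max_speed_mm_s)
      tr <- new_track_state(cur$x_um[j], cur$z_um[j], as.numeric(v0),
                            cur$intensity[j], f, next_id, km,
                            v_var = attr(v0, "spread"))
      next_id <- next_id + 1L
      keep[[length(keep) + 1L]] <- tr
    }
    active <- keep
    prev_locs <- cur
  }
  done <- c(done, active)
  finalize_tracks(done, frame_rate, min_frames = min_frames)
}

#' Filter tracks by length and compute per-step velocities
#'
#' Bubbles appearing in fewer than `min_frames` frames are low-confidence
#' and removed (default: tracked over at least four frames). Per-step
#' velocity is the displacement times the frame rate; the final point of a
#' track inherits the preceding step's velocity.
#'
#' @param raw_tracks internal track-state list, or a `track_set`.
#' @param frame_rate Hz. @param min_frames minimum length kept.
#' @return object of class `track_set`: data.frame
#'   `track_id, frame, x_um, z_um, vx_mm_s, vz_mm_s, intensity`.
#' @export
finalize_tracks <- function(raw_tracks, frame_rate, min_frames = 4L) {
  if (inherits(raw_tracks, "track_set")) {
    ts <- raw_tracks
    keep <- as.vector(table(ts$track_id)[as.character(ts$track_id)]) >= min_frames
    out <- ts[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "frame_rate") <- attr(ts, "frame_rate")
    class(out) <- class(ts)
    return(out)
  }
  res <- list()
  for (tr in raw_tracks) {
    n <- length(tr$frames)
    if (n < min_frames) next
    vx <- c(diff(tr$xs), NA) * frame_rate / 1e3
    vz <- c(diff(tr$zs), NA) * frame_rate / 1e3
    if (n >= 2L) { vx[n] <- vx[n - 1L]; vz[n] <- vz[n - 1L] }
    res[[length(res) + 1L]] <- data.frame(
      track_id = tr$id, frame = tr$frames, x_um = tr$xs, z_um = tr$zs,
      vx_mm_s = vx, vz_mm_s = vz, intensity = tr$ints)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(track_id = integer(), frame = integer(), x_um = numeric(),
               z_um = numeric(), vx_mm_s = numeric(), vz_mm_s = numeric(),
               intensity = numeric())
  rownames(out) <- NULL
  structure(out, frame_rate = frame_rate,
            class = c("track_set", "data.frame"))
}
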