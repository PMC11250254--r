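# Cardiac gating and two-level tissue motion correction:
#   - frame-intensity-correlation gating selects diastolic frames;
#   - intra-cycle: SVD tissue extraction, then affine (Levenberg-Marquardt)
#     plus B-spline non-rigid (steepest descent, SSD + thin-plate penalty)
#     registration to a per-cycle reference frame, warm-started frame to
#     frame;
#   - inter-cycle: rigid registration of cycle-averaged CEUS images.

#' Log compression for registration
#'
#' Envelope image to log scale over a fixed dynamic range (default 50 dB),
#' rescaled to `[0, 1]` grey levels.
#'
#' @param img nonnegative matrix. @param dyn_db dynamic range, dB.
#' @param ref_max reference (0 dB) level; defaults to the image maximum.
#' @export
log_compress <- function(img, dyn_db = 50, ref_max = NULL) {
  m <- ref_max %||% max(img)
  if (m <= 0) return(img * 0)
  db <- 20 * log10(pmax(img, m * 10^(-dyn_db / 20 - 1)) / m)
  db <- pmax(db, -dyn_db)
  (db + dyn_db) / dyn_db
}

#' Adjacent-frame normalized correlation trace
#'
#' `cor` of consecutive vectorized frames; the gating signal. Constant
#' frame pairs correlate as 1.
#'
#' @param stack array `[nz, nx, n_frames]`.
#' @return numeric vector of length `n_frames - 1`.
#' @export
frame_correlation <- function(stack) {
  nf <- dim(stack)[3]
  m <- matrix(stack, ncol = nf)
  cc <- vapply(seq_len(nf - 1L), function(f)
    suppressWarnings(stats::cor(m[, f], m[, f + 1L])), 0)
  cc[is.na(cc)] <- 1
  cc
}

#' Cardiac-cycle gating from frame intensity correlation
#'
#' The normalized cross-correlation between adjacent frames drops sharply at
#' the start of systole; its local minima (separated by a refractory window
#' of 0.4 times the estimated period) index the cycles. Diastole is the
#' high-correlation plateau before each systole start (frames whose
#' correlation exceeds the cycle's 75th percentile), clipped to at most
#' `max_diastole_s` of data; plateaus shorter than `min_diastole_s` are
#' dropped.
#'
#' @param bmode array `[nz, nx, n_frames]`.
#' @param frame_rate frames per second.
#' @param min_diastole_s,max_diastole_s plateau duration bounds (0.2-0.4 s).
#' @return object of class `cycle_index`: `systole_starts`, list
#'   `diastole_frames` per cycle, `correlation` trace, `period_s`.
#' @export
gate_diastole <- function(bmode, frame_rate, min_diastole_s = 0.2,
                          max_diastole_s = 0.4) {
  nf <- dim(bmode)[3]
  if (nf < 3L) stopf("stack too short for gating")
  cc <- frame_correlation(bmode)
  s <- 1 - cc
  if (max(s) < 1e-5)
    stop(structure(class = c("srulm_no_periodicity", "error", "condition"),
                   list(message = "no cardiac periodicity detected in the frame correlation trace",
                        call = NULL, correlation = cc)))
  # period from the autocorrelation of the dissimilarity trace
  sc <- s - mean(s)
  ac <- stats::acf(sc, lag.max = length(s) - 2L, plot = FALSE)$acf[, 1, 1]
  lag_min <- max(3L, round(0.25 * frame_rate))
  cand <- seq(lag_min, length(ac) - 1L)
  pk <- cand[which.max(ac[cand + 1L])]
  period_s <- pk / frame_rate
  refractory <- max(2L, round(0.4 * pk))
  # greedy minima selection on the correlation trace
  ord <- order(cc)
  thr <- mean(cc) - 0.25 * (mean(cc) - min(cc))
  starts <- integer()
  for (i in ord) {
    if (cc[i] > thr) break
    if (!length(starts) || all(abs(starts - i) >= refractory))
      starts <- c(starts, i)
  }
  starts <- sort(starts)
  if (length(starts) < 1L)
    stop(structure(class = c("srulm_no_periodicity", "error", "condition"),
                   list(message = "no systolic minima found in the correlation trace",
                        call = NULL, correlation = cc)))
  bounds <- c(0L, starts, nf)
  dia <- list()
  for (k in seq_len(length(starts))) {
    lo <- bounds[k] + 1L; hi <- starts[k] - 1L
    if (hi <= lo) next
    seg <- lo:hi
    q <- stats::quantile(cc[pmin(seg, nf - 1L)], 0.75)
    good <- cc[pmin(seg, nf - 1L)] >= q
    # longest contiguous plateau
    r <- rle(good)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    ibest <- which(r$values)[which.max(r$lengths[r$values])]
    plateau <- seg[(ends[ibest] - r$lengths[ibest] + 1L):ends[ibest]]
    max_n <- max(1L, round(max_diastole_s * frame_rate))
    if (length(plateau) > max_n)                  # keep the tail before systole
      plateau <- plateau[(length(plateau) - max_n + 1L):length(plateau)]
    if (length(plateau) / frame_rate + 1e-9 < min_diastole_s) next
    dia[[length(dia) + 1L]] <- plateau
  }
  structure(list(systole_starts = starts, diastole_frames = dia,
                 correlation = cc, period_s = period_s,
                 frame_rate = frame_rate),
            class = "cycle_index")
}

#' Tissue extraction by SVD rank truncation
#'
#' Reshapes the stack to a space-by-time matrix and reconstructs it from the
#' largest `fraction` of singular values (default 5%), suppressing fast
#' moving-bubble energy while keeping the quasi-static tissue.
#'
#' @param stack array `[nz, nx, n_frames]`.
#' @param fraction fraction of singular values kept.
#' @return array like `stack`.
#' @export
tissue_from_svd <- function(stack, fraction = 0.05) {
  d <- dim(stack)
  m <- matrix(stack, ncol = d[3])
  k <- min(d[3], max(1L, ceiling(fraction * min(dim(m)))))
  sv <- svd(m, nu = k, nv = k)
  rec <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  array(rec, d)
}

local_stats <- function(img, sigma = 1.5) {
  k <- gaussian_kernel(sigma, max_size = min(dim(img)))
  mu <- conv2_zero(img, k)
  mu2 <- conv2_zero(img^2, k)
  list(mu = mu, var = pmax(mu2 - mu^2, 0))
}

# Mean structural-similarity score between two equally scaled images.
ssim_score <- function(a, b, L = 1) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  k <- gaussian_kernel(1.5, max_size = min(dim(a)))
  mua <- conv2_zero(a, k); mub <- conv2_zero(b, k)
  va <- pmax(conv2_zero(a^2, k) - mua^2, 0)
  vb <- pmax(conv2_zero(b^2, k) - mub^2, 0)
  cab <- conv2_zero(a * b, k) - mua * mub
  s <- ((2 * mua * mub + c1) * (2 * cab + c2)) /
    ((mua^2 + mub^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Select the reference frame of a cycle
#'
#' The frame most similar (structural-similarity score) to the cycle-mean
#' frame; ties break to the lowest index.
#'
#' @param stack array `[nz, nx, n_frames]`.
#' @return frame index.
#' @export
select_reference <- function(stack) {
  nf <- dim(stack)[3]
  if (nf == 1L) return(1L)
  avg <- apply(stack, c(1, 2), mean)
  L <- max(stack, avg, 1e-12)
  scores <- vapply(seq_len(nf),
                   function(f) ssim_score(stack[, , f] / L, avg / L), 0)
  which.max(scores)   # which.max returns the first (lowest) index on ties
}

# --- transforms -------------------------------------------------------------

# A transform maps *fixed* (reference) pixel coordinates (row, col) to
# *moving* coordinates: T(p) = A %*% (r, c, 1) + u(p), with u the B-spline
# displacement. identity_transform() has A = [I 0], u = 0.

#' Identity transform
#' @param dims image dims. @param spacing B-spline control spacing, px.
#' @export
identity_transform <- function(dims, spacing = 32) {
  b <- bspline_setup(dims[1], dims[2], spacing)
  list(affine = cbind(diag(2), c(0, 0)),
       ctrl_r = matrix(0, b$ncr, b$ncc), ctrl_c = matrix(0, b$ncr, b$ncc),
       spacing = spacing, dims = dims)
}

cubic_bspline <- function(t) {
  at <- abs(t)
  out <- numeric(length(t))
  i1 <- at < 1
  out[i1] <- (2 / 3 - at[i1]^2 + at[i1]^3 / 2)
  i2 <- at >= 1 & at < 2
  out[i2] <- (2 - at[i2])^3 / 6
  out
}

# Basis matrices for a cubic B-spline control lattice covering the image.
bspline_setup <- function(nr, nc, spacing) {
  make_B <- function(n) {
    nctrl <- ceiling((n - 1) / spacing) + 3L
    pos <- (seq_len(nctrl) - 2L) * spacing + 1
    B <- outer(seq_len(n), pos, function(p, q) cubic_bspline((p - q) / spacing))
    B
  }
  Br <- make_B(nr); Bc <- make_B(nc)
  list(Br = Br, Bc = Bc, ncr = ncol(Br), ncc = ncol(Bc))
}

transform_coords <- function(tf, rr, cc) {
  A <- tf$affine
  r2 <- A[1, 1] * rr + A[1, 2] * cc + A[1, 3]
  c2 <- A[2, 1] * rr + A[2, 2] * cc + A[2, 3]
  if (!is.null(tf$ctrl_r) && (any(tf$ctrl_r != 0) || any(tf$ctrl_c != 0))) {
    b <- bspline_setup(tf$dims[1], tf$dims[2], tf$spacing)
    ur <- b$Br %*% tf$ctrl_r %*% t(b$Bc)
    uc <- b$Br %*% tf$ctrl_c %*% t(b$Bc)
    ri <- pmin(pmax(round(rr), 1L), tf$dims[1])
    ci <- pmin(pmax(round(cc), 1L), tf$dims[2])
    idx <- (ci - 1L) * tf$dims[1] + ri
    r2 <- r2 + ur[idx]
    c2 <- c2 + uc[idx]
  }
  cbind(r2, c2)
}

#' Apply a transform to an image (resample into the reference frame)
#' @param img moving image. @param tf transform from [register_pair()].
#' @export
apply_transform_image <- function(img, tf) {
  nr <- tf$dims[1]; nc <- tf$dims[2]
  rr <- rep(seq_len(nr), nc); cc <- rep(seq_len(nc), each = nr)
  m <- transform_coords(tf, rr, cc)
  matrix(interp_bicubic(img, m[, 1], m[, 2]), nr, nc)
}

#' Map point coordinates through a transform
#'
#' `transform_points()` maps reference coordinates into the moving frame;
#' `invert_transform_points()` maps moving-frame (acquired) coordinates back
#' into the reference frame by fixed-point iteration, which is what
#' localization coordinates need.
#'
#' @param tf a transform. @param pts n x 2 matrix of (row, col) pixel coords.
#' @export
transform_points <- function(tf, pts) {
  transform_coords(tf, pts[, 1], pts[, 2])
}

#' @rdname transform_points
#' @param iters fixed-point iterations.
#' @export
invert_transform_points <- function(tf, pts, iters = 15L) {
  p <- pts
  for (i in seq_len(iters)) {
    q <- transform_coords(tf, p[, 1], p[, 2])
    p <- p - (q - pts)
  }
  p
}

warp_residual <- function(par, moving, fixed, mask) {
  tf <- list(affine = matrix(par, 2, 3), ctrl_r = NULL, ctrl_c = NULL,
             dims = dim(fixed))
  w <- apply_transform_image(moving, tf)
  (w - fixed)[mask]
}

register_affine <- function(moving, fixed, init = NULL, max_iter = 500,
                            border = 3L) {
  par0 <- if (is.null(init)) c(1, 0, 0, 1, 0, 0) else as.vector(init)
  nr <- nrow(fixed); nc <- ncol(fixed)
  mask <- matrix(FALSE, nr, nc)
  mask[(border + 1):(nr - border), (border + 1):(nc - border)] <- TRUE
  fit <- minpack.lm::nls.lm(
    par = par0, fn = warp_residual, moving = moving, fixed = fixed,
    mask = mask,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ptol = 1e-4,
                                         ftol = 1e-10))
  matrix(fit$par, 2, 3)
}

bending_energy <- function(C) {
  d2r <- diff(diff(C))                         # second differences down rows
  d2c <- t(diff(diff(t(C))))                   # down columns
  dcr <- diff(t(diff(t(C))))                   # mixed
  list(E = sum(d2r^2) + sum(d2c^2) + 2 * sum(dcr^2),
       grad = local({
         g <- matrix(0, nrow(C), ncol(C))
         add <- function(g, M, ri, ci) {
           g[ri, ci] <- g[ri, ci] + M
           g
         }
         nr <- nrow(C); nc <- ncol(C)
         # gradient of sum(d2r^2): d2r[i,] = C[i,]-2C[i+1,]+C[i+2,]
         g[1:(nr - 2), ] <- g[1:(nr - 2), ] + 2 * d2r
         g[2:(nr - 1), ] <- g[2:(nr - 1), ] - 4 * d2r
         g[3:nr, ] <- g[3:nr, ] + 2 * d2r
         g[, 1:(nc - 2)] <- g[, 1:(nc - 2)] + 2 * d2c
         g[, 2:(nc - 1)] <- g[, 2:(nc - 1)] - 4 * d2c
         g[, 3:nc] <- g[, 3:nc] + 2 * d2c
         g[1:(nr - 1), 1:(nc - 1)] <- g[1:(nr - 1), 1:(nc - 1)] + 4 * dcr
         g[2:nr, 1:(nc - 1)] <- g[2:nr, 1:(nc - 1)] - 4 * dcr
         g[1:(nr - 1), 2:nc] <- g[1:(nr - 1), 2:nc] - 4 * dcr
         g[2:nr, 2:nc] <- g[2:nr, 2:nc] + 4 * dcr
         g
       }))
}

register_bspline <- function(moving, fixed, affine, spacing = 32,
                             lambda = 0.01, max_iter = 500,
                             init_ctrl = NULL, pyramid_sigmas = c(6, 3, 0),
                             border = 3L) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  b <- bspline_setup(nr, nc, spacing)
  Cr <- init_ctrl$ctrl_r %||% matrix(0, b$ncr, b$ncc)
  Cc <- init_ctrl$ctrl_c %||% matrix(0, b$ncr, b$ncc)
  iters_per_level <- max(20L, ceiling(max_iter / length(pyramid_sigmas)))
  for (sg in pyramid_sigmas) {
    if (sg > 0) {
      k <- gaussian_kernel(sg, max_size = min(nr, nc))
      mov_s <- conv2_zero(moving, k)
      fix_s <- conv2_zero(fixed, k)
    } else {
      mov_s <- moving; fix_s <- fixed
    }
    res <- bspline_descend(mov_s, fix_s, affine, b, spacing, lambda,
                           iters_per_level, Cr, Cc, border = border)
    Cr <- res$ctrl_r; Cc <- res$ctrl_c
  }
  list(ctrl_r = Cr, ctrl_c = Cc)
}

bspline_descend <- function(moving, fixed, affine, b, spacing, lambda,
                            max_iter, Cr, Cc, border = 3L) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  rr <- rep(seq_len(nr), nc); cc <- rep(seq_len(nc), each = nr)
  ar <- affine[1, 1] * rr + affine[1, 2] * cc + affine[1, 3]
  ac <- affine[2, 1] * rr + affine[2, 2] * cc + affine[2, 3]
  # image gradients of the moving image (for the chain rule)
  gr <- moving * 0; gc <- moving * 0
  gr[2:(nr - 1), ] <- (moving[3:nr, ] - moving[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (moving[, 3:nc] - moving[, 1:(nc - 2)]) / 2
  mask <- matrix(0, nr, nc)
  mask[(border + 1):(nr - border), (border + 1):(nc - border)] <- 1
  npx <- sum(mask)
  # thin-plate penalty normalized to the SSD scale: per-control curvature in
  # units of (pixel displacement / control spacing)^2
  pen_norm <- 1 / (b$ncr * b$ncc * spacing^2)
  cost_of <- function(Cr, Cc) {
    ur <- b$Br %*% Cr %*% t(b$Bc); uc <- b$Br %*% Cc %*% t(b$Bc)
    w <- matrix(interp_bicubic(moving, ar + as.vector(ur), ac + as.vector(uc)),
                nr, nc)
    R <- (w - fixed) * mask
    ssd <- sum(R^2) / npx
    ber <- bending_energy(Cr); bec <- bending_energy(Cc)
    list(cost = ssd + lambda * pen_norm * (ber$E + bec$E),
         ssd = ssd, R = R, ur = ur, uc = uc,
         ber = ber, bec = bec)
  }
  st <- cost_of(Cr, Cc)
  step <- 1
  stall <- 0L
  B2r <- b$Br^2; B2c <- b$Bc^2
  for (it in seq_len(max_iter)) {
    # gradient: dSSD/dC = 2/npx * t(Br) %*% (R .* grad_sampled) %*% Bc,
    # preconditioned by the Gauss-Newton diagonal so the step is a
    # displacement-scale quantity (steepest descent in the scaled metric)
    wr <- matrix(interp_bicubic(gr, ar + as.vector(st$ur), ac + as.vector(st$uc)), nr, nc)
    wc <- matrix(interp_bicubic(gc, ar + as.vector(st$ur), ac + as.vector(st$uc)), nr, nc)
    Gr <- 2 / npx * t(b$Br) %*% (st$R * wr) %*% b$Bc +
      lambda * pen_norm * st$ber$grad
    Gc <- 2 / npx * t(b$Br) %*% (st$R * wc) %*% b$Bc +
      lambda * pen_norm * st$bec$grad
    # diagonal Hessian: data term plus the penalty's (constant ~24/control)
    pen_diag <- lambda * pen_norm * 24
    Dr <- 2 / npx * t(B2r) %*% (wr^2 * mask) %*% B2c + pen_diag
    Dc <- 2 / npx * t(B2r) %*% (wc^2 * mask) %*% B2c + pen_diag
    eps <- 1e-8 * max(Dr, Dc, 1e-12)
    Pr <- Gr / (Dr + eps); Pc <- Gc / (Dc + eps)
    cap <- 0.5 * spacing
    if (max(abs(Pr), abs(Pc)) < 1e-10) break
    Pr <- pmin(pmax(Pr, -cap), cap)          # per-control step clamp
    Pc <- pmin(pmax(Pc, -cap), cap)
    improved <- FALSE
    for (ls in 1:25) {
      Cr2 <- Cr - step * Pr; Cc2 <- Cc - step * Pc
      st2 <- cost_of(Cr2, Cc2)
      if (st2$cost < st$cost) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    rel <- (st$cost - st2$cost) / max(st$cost, 1e-12)
    Cr <- Cr2; Cc <- Cc2; st <- st2
    step <- min(step * 1.5, 4)
    # early stop: cost change below 0.001% for 20 consecutive iterations
    stall <- if (rel < 1e-5) stall + 1L else 0L
    if (stall >= 20L) break
  }
  list(ctrl_r = Cr, ctrl_c = Cc)
}

#' Two-stage affine + B-spline registration of an image pair
#'
#' Stage 1 estimates an affine transform by Levenberg-Marquardt on the sum
#' of squared intensity differences; stage 2 refines with a cubic B-spline
#' displacement field by steepest descent on SSD plus a thin-plate
#' (bending-energy) penalty. Both stages cap iterations at 500 and stop
#' early when the improvement falls below 0.001% for 20 iterations (stage 2)
#' or the parameter change falls below 1e-4 (stage 1). Inputs are expected
#' log-compressed to a fixed dynamic range and rescaled to grey scale.
#'
#' @param moving,fixed matrices on the same grid.
#' @param spacing B-spline control-point spacing in pixels (16 or 32 in the
#'   reference pipelines).
#' @param lambda thin-plate penalty weight relative to the (normalized) SSD.
#' @param max_iter iteration cap per stage.
#' @param init optional transform to warm-start from (previous frame).
#' @param nonrigid run the B-spline stage?
#' @param border image border (pixels) excluded from the SSD; widen it when
#'   large displacements drag out-of-bounds content into the frame.
#' @param pyramid_sigmas Gaussian smoothing levels (coarse to fine) for the
#'   B-spline stage; a single 0 skips the pyramid (warm-started frames).
#' @return transform list: `affine` (2 x 3), `ctrl_r`, `ctrl_c`, `spacing`,
#'   `dims`.
#' @export
register_pair <- function(moving, fixed, spacing = 32, lambda = 0.01,
                          max_iter = 500, init = NULL, nonrigid = TRUE,
                          border = 3L, pyramid_sigmas = c(6, 3, 0)) {
  if (any(!is.finite(moving)) || any(!is.finite(fixed)))
    stopf("non-finite values in registration input")
  A <- register_affine(moving, fixed, init = init$affine, max_iter = max_iter,
                       border = border)
  tf <- list(affine = A, ctrl_r = NULL, ctrl_c = NULL,
             spacing = spacing, dims = dim(fixed))
  if (nonrigid) {
    bs <- register_bspline(moving, fixed, A, spacing = spacing,
                           lambda = lambda, max_iter = max_iter,
                           init_ctrl = init[c("ctrl_r", "ctrl_c")],
                           border = border, pyramid_sigmas = pyramid_sigmas)
    tf$ctrl_r <- bs$ctrl_r; tf$ctrl_c <- bs$ctrl_c
  } else {
    b <- bspline_setup(nrow(fixed), ncol(fixed), spacing)
    tf$ctrl_r <- matrix(0, b$ncr, b$ncc)
    tf$ctrl_c <- matrix(0, b$ncr, b$ncc)
  }
  tf
}

#' Rigid registration between cycle-averaged CEUS images
#'
#' Estimates (rotation about the image centre, translation) aligning each
#' cycle's mean image to the first cycle's, by Levenberg-Marquardt on SSD.
#'
#' @param means list of cycle-mean images (log-compressed grey scale).
#' @return list of rigid transforms `(theta_deg, dr, dc)`; the first is the
#'   identity.
#' @export
intercycle_rigid <- function(means) {
  if (length(means) < 1L) stopf("need at least one cycle mean")
  ref <- means[[1L]]
  nr <- nrow(ref); nc <- ncol(ref)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  rigid_to_affine <- function(p) {
    th <- p[1] * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    t0 <- c(p[2], p[3]) + ctr - R %*% ctr
    cbind(R, t0)
  }
  out <- vector("list", length(means))
  out[[1L]] <- list(theta_deg = 0, dr = 0, dc = 0,
                    affine = cbind(diag(2), c(0, 0)))
  border <- 3L
  mask <- matrix(FALSE, nr, nc)
  mask[(border + 1):(nr - border), (border + 1):(nc - border)] <- TRUE
  for (k in seq_along(means)[-1L]) {
    fn <- function(p) {
      tf <- list(affine = rigid_to_affine(p), ctrl_r = NULL, ctrl_c = NULL,
                 dims = c(nr, nc))
      (apply_transform_image(means[[k]], tf) - ref)[mask]
    }
    fit <- minpack.lm::nls.lm(par = c(0, 0, 0), fn = fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ptol = 1e-6))
    out[[k]] <- list(theta_deg = fit$par[1], dr = fit$par[2],
                     dc = fit$par[3], affine = rigid_to_affine(fit$par))
  }
  out
}

#' Warp a stack (or point set) into the reference frame
#'
#' @param stack array `[nz, nx, n_frames]`.
#' @param transforms list of per-frame transforms (reference -> frame).
#' @return corrected array; the reference frame's pixels are untouched when
#'   its transform is the identity.
#' @export
warp_stack <- function(stack, transforms) {
  out <- stack
  for (f in seq_len(dim(stack)[3])) {
    tf <- transforms[[f]]
    if (is_identity_tf(tf)) next
    out[, , f] <- apply_transform_image(stack[, , f], tf)
  }
  out
}

is_identity_tf <- function(tf) {
  isTRUE(all.equal(tf$affine, cbind(diag(2), c(0, 0)), tolerance = 1e-12)) &&
    (is.null(tf$ctrl_r) || all(tf$ctrl_r == 0)) &&
    (is.null(tf$ctrl_c) || all(tf$ctrl_c == 0))
}

#' Intra-cycle motion correction of a frame run
#'
#' Extracts tissue by SVD, log-compresses, picks the reference frame, and
#' registers every frame to it (two-stage, warm-started from the neighbour
#' frame outward). Returns per-frame transforms plus the corrected stacks.
#'
#' @param bmode,ceus arrays `[nz, nx, n]` for one cycle (or the whole
#'   acquisition on the no-gating pathway).
#' @param spacing,lambda,max_iter registration parameters.
#' @param svd_fraction singular-value fraction for tissue extraction.
#' @param dyn_db log-compression dynamic range.
#' @return list: `transforms`, `reference`, `bmode_corrected`,
#'   `ceus_corrected`.
#' @export
moco_cycle <- function(bmode, ceus, spacing = 32, lambda = 0.01,
                       max_iter = 500, svd_fraction = 0.05, dyn_db = 50) {
  nf <- dim(bmode)[3]
  tissue <- tissue_from_svd(bmode, svd_fraction)
  lc <- array(0, dim(tissue))
  top <- max(tissue)
  for (f in seq_len(nf))
    lc[, , f] <- log_compress(pmax(tissue[, , f], 0), dyn_db, ref_max = top)
  ref <- select_reference(lc)
  tfs <- vector("list", nf)
  tfs[[ref]] <- identity_transform(dim(lc)[1:2], spacing)
  for (dir in c(1L, -1L)) {
    prev <- tfs[[ref]]
    f <- ref + dir
    first <- TRUE
    while (f >= 1L && f <= nf) {
      # full coarse-to-fine pyramid only for the first frame off the
      # reference; warm-started neighbours need only the fine level
      tfs[[f]] <- register_pair(lc[, , f], lc[, , ref], spacing = spacing,
                                lambda = lambda,
                                max_iter = if (first) max_iter else
                                  min(max_iter, 160L),
                                init = prev,
                                pyramid_sigmas = if (first) c(6, 3, 0) else
                                  c(3, 0))
      prev <- tfs[[f]]
      first <- FALSE
      f <- f + dir
    }
  }
  list(transforms = tfs, reference = ref,
       bmode_corrected = warp_stack(bmode, tfs),
       ceus_corrected = warp_stack(ceus, tfs))
}
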