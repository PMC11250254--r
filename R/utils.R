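# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(..., .names = NULL) {
  vals <- list(...)
  nms <- .names %||% sapply(substitute(list(...))[-1], deparse)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stopf("invalid parameter: `%s` must be positive and finite", nms[i])
  }
  invisible(TRUE)
}

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal of real-valued traces (columns of a
#' matrix, or a single vector), i.e. the signal plus i times its Hilbert
#' transform. Used to obtain complex channel data before delay-and-sum.
#'
#' @param x numeric vector or matrix (time along rows).
#' @return complex object of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(xm)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  X <- stats::mvfft(xm) * h
  out <- stats::mvfft(X, inverse = TRUE) / n
  if (vec) out[, 1L] else out
}

# Linear interpolation of (possibly complex) columns at fractional row indices.
# idx outside [1, n] contributes 0.
interp_linear_idx <- function(trace, idx) {
  n <- length(trace)
  i0 <- floor(idx)
  f <- idx - i0
  ok <- i0 >= 1 & i0 <= n - 1
  out <- rep(if (is.complex(trace)) 0 + 0i else 0, length(idx))
  if (any(ok)) {
    ii <- i0[ok]
    out[ok] <- trace[ii] * (1 - f[ok]) + trace[ii + 1L] * f[ok]
  }
  edge <- i0 == n & f == 0
  out[edge] <- trace[n]
  out
}

# Windowed-sinc (Lanczos-3) interpolation at fractional indices; near-unity
# frequency response at RF/analytic carrier frequencies where linear
# interpolation attenuates badly. Outside [1, n] -> 0.
interp_lanczos_idx <- function(trace, idx, a = 3L) {
  n <- length(trace)
  i0 <- floor(idx)
  f <- idx - i0
  zero <- if (is.complex(trace)) 0 + 0i else 0
  acc <- rep(zero, length(idx))
  wsum <- numeric(length(idx))
  for (k in (-a + 1L):a) {
    t <- f - k
    w <- ifelse(abs(t) < 1e-12, 1,
                a * sin(pi * t) * sin(pi * t / a) / (pi^2 * t^2))
    ii <- i0 + k
    ok <- ii >= 1 & ii <= n
    v <- rep(zero, length(idx))
    v[ok] <- trace[ii[ok]]
    acc <- acc + w * v
    wsum <- wsum + w
  }
  acc / wsum
}

# Catmull-Rom bicubic sampling of a matrix at fractional (row, col) positions.
# Positions outside the matrix return 0. Works for real and complex images.
interp_bicubic <- function(img, ri, ci) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  cubw <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    list(
      (-t3 + 2 * t2 - t) / 2,
      (3 * t3 - 5 * t2 + 2) / 2,
      (-3 * t3 + 4 * t2 + t) / 2,
      (t3 - t2) / 2
    )
  }
  wr <- cubw(fr); wc <- cubw(fc)
  zero <- if (is.complex(img)) 0 + 0i else 0
  acc <- rep(zero, length(ri))
  for (dr in -1:2) {
    rr <- r0 + dr
    okr <- rr >= 1 & rr <= nr
    for (dc in -1:2) {
      cc <- c0 + dc
      ok <- okr & cc >= 1 & cc <= nc
      if (!any(ok)) next
      v <- rep(zero, length(ri))
      v[ok] <- img[(cc[ok] - 1) * nr + rr[ok]]
      acc <- acc + wr[[dr + 2L]] * wc[[dc + 2L]] * v
    }
  }
  acc
}

# Bilinear sampling (clamped at borders), for displacement-field lookups.
interp_bilinear <- function(img, ri, ci) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(ri, 1), nr); ci <- pmin(pmax(ci, 1), nc)
  r0 <- pmin(floor(ri), nr - 1L); c0 <- pmin(floor(ci), nc - 1L)
  fr <- ri - r0; fc <- ci - c0
  idx <- function(r, c) (c - 1) * nr + r
  img[idx(r0, c0)] * (1 - fr) * (1 - fc) +
    img[idx(r0 + 1L, c0)] * fr * (1 - fc) +
    img[idx(r0, c0 + 1L)] * (1 - fr) * fc +
    img[idx(r0 + 1L, c0 + 1L)] * fr * fc
}

# Zero-padded FFT convolution with the kernel centred ("same" output size).
# Plain stats::fft with nextn() padding; far less per-call overhead than the
# S4 image classes for the many small convolutions the localizer performs.
conv2_zero <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- stats::nextn(nr + kr - 1L, c(2L, 3L, 5L))
  pc <- stats::nextn(nc + kc - 1L, c(2L, 3L, 5L))
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- img
  B <- matrix(0, pr, pc); B[seq_len(kr), seq_len(kc)] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    (pr * pc)
  r0 <- (kr + 1L) %/% 2L; c0 <- (kc + 1L) %/% 2L
  full[r0 + seq_len(nr) - 1L, c0 + seq_len(nc) - 1L, drop = FALSE]
}

corr2_zero <- function(img, kern) {
  conv2_zero(img, kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern))),
                       drop = FALSE])
}

# Local sums over a (2h+1) x (2w+1) window with zero padding, via integral
# images: exact and O(n) (used by the adaptive threshold and the NCC).
box_sum <- function(img, h, w) {
  nr <- nrow(img); nc <- ncol(img)
  colcs <- function(m) {
    k <- ncol(m)
    cs <- matrix(cumsum(m), nrow(m), k)
    if (k > 1L) cs <- cs - matrix(rep(c(0, cs[nrow(m), -k]), each = nrow(m)),
                                  nrow(m), k)
    cs
  }
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- t(colcs(t(colcs(img))))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - w, 1L); c2 <- pmin(seq_len(nc) + w, nc)
  P[r2 + 1L, c2 + 1L, drop = FALSE] - P[r1, c2 + 1L, drop = FALSE] -
    P[r2 + 1L, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
}

gaussian_kernel <- function(sigma_px, max_size = NULL) {
  h <- max(1L, ceiling(3 * sigma_px))
  if (!is.null(max_size)) h <- min(h, (max_size - 1L) %/% 2L)
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma_px^2))
  k <- outer(k, k)
  k / sum(k)
}

disk_kernel <- function(diameter_px) {
  r <- max(0.5, diameter_px / 2)
  h <- ceiling(r - 0.5)
  x <- (-h):h
  d2 <- outer(x^2, x^2, `+`)
  k <- (d2 <= r^2) * 1
  k / sum(k)
}

# 8-connected labeling of a logical mask. Returns an integer matrix of labels
# (0 = background). Pixel counts are typically small (thresholded CEUS).
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx_fg <- which(mask)
  if (!length(idx_fg)) return(lab)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (s in idx_fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- integer(256L)
    queue[1L] <- s
    head <- 1L; tail <- 1L
    lab[s] <- cur
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      pr <- ((p - 1L) %% nr) + 1L
      nb <- p + off
      keep <- rep(TRUE, 8L)
      if (pr == 1L) keep[c(1L, 5L, 7L)] <- FALSE
      if (pr == nr) keep[c(2L, 6L, 8L)] <- FALSE
      nb <- nb[keep]
      nb <- nb[nb >= 1L & nb <= nr * nc]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        if (tail + length(nb) > length(queue))
          queue <- c(queue, integer(length(queue) + length(nb)))
        queue[tail + seq_along(nb)] <- nb
        tail <- tail + length(nb)
      }
    }
  }
  lab
}

# Robust local RNG scoping: evaluate expr under a seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
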