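# Quantification: Fourier ring correlation resolution, vessel morphometry
# by skeleton + distance transform, flow-speed statistics with a lognormal
# fit, and cross-section profile analysis.

#' Fourier ring correlation between two half-data maps
#'
#' `FRC(k) = Re(sum F1 F2*) / sqrt(sum|F1|^2 sum|F2|^2)` over rings of one
#' frequency sample; the resolution is the inverse spatial frequency of the
#' first crossing below the half-bit information threshold
#' `T(n) = (0.2071 + 1.9102/sqrt(n)) / (1.2071 + 0.9102/sqrt(n))` with `n`
#' the per-ring sample count.
#'
#' @param map1,map2 equally sized matrices on a square-cell grid.
#' @param cell_um cell size, um.
#' @return object of class `frc_result`: `freq_um` (cycles/um), `frc`,
#'   `threshold`, `n_per_ring`, `resolution_um`, `crossed` (FALSE when the
#'   curve never drops below the threshold; the resolution is then the grid
#'   Nyquist wavelength `2 * cell_um`).
#' @export
frc_curve <- function(map1, map2, cell_um = 13.5) {
  if (!all(dim(map1) == dim(map2))) stopf("maps must have identical dims")
  N <- max(dim(map1))
  if (N %% 2L == 1L) N <- N + 1L
  pad <- function(m) {
    out <- matrix(0, N, N)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  F1 <- stats::fft(pad(map1)); F2 <- stats::fft(pad(map2))
  f_idx <- c(0:(N / 2), (-(N / 2 - 1)):(-1))   # unshifted FFT frequencies
  K <- round(sqrt(outer(f_idx^2, f_idx^2, `+`)))
  kmax <- N %/% 2L
  num <- rowsum(as.vector(Re(F1 * Conj(F2))), as.vector(K))
  d1 <- rowsum(as.vector(abs(F1)^2), as.vector(K))
  d2 <- rowsum(as.vector(abs(F2)^2), as.vector(K))
  n_ring <- rowsum(rep(1, length(K)), as.vector(K))
  ks <- as.integer(rownames(num))
  sel <- ks >= 1L & ks <= kmax
  ks <- ks[sel]
  frc <- num[sel] / sqrt(pmax(d1[sel] * d2[sel], .Machine$double.xmin))
  n_ring <- n_ring[sel]
  thr <- (0.2071 + 1.9102 / sqrt(n_ring)) / (1.2071 + 0.9102 / sqrt(n_ring))
  freq <- ks / (N * cell_um)
  below <- which(frc < thr)
  if (length(below)) {
    i <- below[1]
    if (i > 1L) {
      # linear interpolation of the crossing between samples i-1 and i
      d0 <- frc[i - 1L] - thr[i - 1L]; d1x <- frc[i] - thr[i]
      f_cross <- freq[i - 1L] + (freq[i] - freq[i - 1L]) * d0 / (d0 - d1x)
    } else f_cross <- freq[1]
    res <- 1 / f_cross
    crossed <- TRUE
  } else {
    res <- 2 * cell_um
    crossed <- FALSE
  }
  structure(list(freq_um = freq, frc = frc, threshold = thr,
                 n_per_ring = as.vector(n_ring), resolution_um = res,
                 crossed = crossed, cell_um = cell_um),
            class = "frc_result")
}

#' FRC resolution of a track set
#'
#' Whole tracks (never split within a track) are randomly halved; the two
#' subsets are rendered identically (raw 13.5 um accumulation by default)
#' and the FRC of the two maps gives the image resolution.
#'
#' @param tracks a `track_set`. @param grid an [sr_grid()].
#' @param seed split seed. @param fwhm_um optional Gaussian widening applied
#'   to both half-maps before the FRC.
#' @return an `frc_result` with the `split_seed` recorded.
#' @export
frc_resolution <- function(tracks, grid = NULL, seed = 1L, fwhm_um = NULL) {
  ids <- unique(tracks$track_id)
  if (length(ids) < 2L) stopf("need at least 2 tracks to split")
  if (is.null(grid)) grid <- sr_grid_for_tracks(tracks)
  half <- with_seed(seed, sample(ids, floor(length(ids) / 2)))
  m1 <- render_density(tracks[tracks$track_id %in% half, , drop = FALSE],
                       grid, fwhm_um)
  m2 <- render_density(tracks[!tracks$track_id %in% half, , drop = FALSE],
                       grid, fwhm_um)
  out <- frc_curve(m1, m2, grid$cell_um)
  out$split_seed <- as.integer(seed)
  out
}

# Zhang-Suen thinning, vectorized over the mask.
#' Morphological skeleton of a binary mask
#' @param mask logical/0-1 matrix.
#' @return logical matrix: one-pixel-wide centre lines.
#' @export
skeletonize <- function(mask) {
  img <- mask != 0
  nr <- nrow(img); nc <- ncol(img)
  sh <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- sh(img, 1, 0);  p3 <- sh(img, 1, 1);  p4 <- sh(img, 0, 1)
      p5 <- sh(img, -1, 1); p6 <- sh(img, -1, 0); p7 <- sh(img, -1, -1)
      p8 <- sh(img, 0, -1); p9 <- sh(img, 1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqp <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nr, nc)
      for (k in 1:8) A <- A + (!seqp[[k]] & seqp[[k + 1]])
      if (phase == 1) {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Vessel-diameter distribution from a density map
#'
#' The map is binarized (any positive density), skeletonized, and the
#' Euclidean distance transform gives the centre-line-to-boundary distance;
#' the local diameter is twice that distance. The distribution is
#' length-weighted (one count per skeleton pixel), binned at 50 um and
#' capped at 1,500 um.
#'
#' @param density_map matrix. @param cell_um cell size.
#' @param bin_um bin width. @param cap_um diameters above this count in the
#'   cap bin.
#' @return list: `diameters_um` per skeleton pixel, `breaks_um`, `mids_um`,
#'   `proportion` (sums to 1), `n_skeleton`.
#' @export
vessel_diameters <- function(density_map, cell_um = 13.5, bin_um = 50,
                             cap_um = 1500) {
  mask <- density_map > 0
  if (!any(mask))
    return(list(diameters_um = numeric(), breaks_um = numeric(),
                mids_um = numeric(), proportion = numeric(), n_skeleton = 0L))
  skel <- skeletonize(mask)
  dist_px <- EBImage::distmap(mask * 1)
  d_um <- pmax(2 * dist_px[skel] - 1, 1) * cell_um
  d_um <- pmin(d_um, cap_um)
  breaks <- seq(0, cap_um, by = bin_um)
  h <- hist(d_um, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  list(diameters_um = d_um, breaks_um = breaks, mids_um = h$mids,
       proportion = h$counts / sum(h$counts), n_skeleton = sum(skel))
}

#' Flow-speed distribution and lognormal fit
#'
#' Histogram of the non-zero pixels of the SR speed map (5 mm/s bins,
#' proportions of non-zero pixels) plus the closed-form maximum-likelihood
#' lognormal fit of the non-zero values.
#'
#' @param speed_map matrix of speeds, mm/s.
#' @param bin_mm_s bin width.
#' @return list: `breaks_mm_s`, `mids_mm_s`, `proportion`, `meanlog`,
#'   `sdlog`, `n`.
#' @export
speed_stats <- function(speed_map, bin_mm_s = 5) {
  v <- speed_map[speed_map > 0]
  if (!length(v))
    return(list(breaks_mm_s = numeric(), mids_mm_s = numeric(),
                proportion = numeric(), meanlog = NA_real_,
                sdlog = NA_real_, n = 0L))
  breaks <- seq(0, ceiling(max(v) / bin_mm_s) * bin_mm_s, by = bin_mm_s)
  h <- hist(v, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  lv <- log(v)
  list(breaks_mm_s = breaks, mids_mm_s = h$mids,
       proportion = h$counts / sum(h$counts),
       meanlog = mean(lv),
       sdlog = sqrt(mean((lv - mean(lv))^2)),   # MLE (n denominator)
       n = length(v))
}

#' Cross-section profile analysis
#'
#' Samples the map along a line segment, averaging over a perpendicular
#' band (default 0.5 mm wide), normalizes to the profile maximum, and
#' reports peak positions, per-peak FWHM, and centre-to-centre separations.
#' Peaks are local maxima above 0.3 of the profile maximum separated by at
#' least 2 cells.
#'
#' @param map matrix on an [sr_grid()]. @param grid the grid.
#' @param p0_um,p1_um segment endpoints, (x, z) um.
#' @param avg_width_um width of the averaging band.
#' @return list: `s_um` (distance along the line), `profile` (normalized),
#'   `peaks_um`, `fwhm_um`, `separations_um`.
#' @export
cross_section <- function(map, grid, p0_um, p1_um, avg_width_um = 500) {
  cell <- grid$cell_um
  d <- c(p1_um[1] - p0_um[1], p1_um[2] - p0_um[2])
  L <- sqrt(sum(d^2))
  if (L <= 0) stopf("degenerate segment")
  d <- d / L
  nvec <- c(-d[2], d[1])
  s <- seq(0, L, by = cell)
  off <- seq(-avg_width_um / 2, avg_width_um / 2, by = cell)
  prof <- numeric(length(s))
  for (i in seq_along(s)) {
    px <- p0_um[1] + s[i] * d[1] + off * nvec[1]
    pz <- p0_um[2] + s[i] * d[2] + off * nvec[2]
    ri <- (pz - grid$z_um[1]) / cell + 1
    ci <- (px - grid$x_um[1]) / cell + 1
    prof[i] <- mean(interp_bilinear(map, ri, ci))
  }
  m <- max(prof)
  if (m <= 0)
    return(list(s_um = s, profile = prof, peaks_um = numeric(),
                fwhm_um = numeric(), separations_um = numeric()))
  prof <- prof / m
  n <- length(prof)
  is_pk <- which(prof > 0.3 &
                   prof >= c(-Inf, prof[-n]) & prof >= c(prof[-1], -Inf))
  # enforce the minimum separation, keeping the taller peak
  if (length(is_pk) > 1L) {
    keep <- logical(length(is_pk))
    ord <- order(prof[is_pk], decreasing = TRUE)
    sel <- integer()
    for (i in ord) {
      if (all(abs(is_pk[i] - is_pk[sel]) > 2L)) sel <- c(sel, i)
    }
    is_pk <- sort(is_pk[sel])
  }
  fw <- vapply(is_pk, function(i) {
    half <- prof[i] / 2
    l <- i; while (l > 1L && prof[l] > half) l <- l - 1L
    r <- i; while (r < n && prof[r] > half) r <- r + 1L
    if (prof[l] > half || prof[r] > half) return(NA_real_)
    sl <- s[l] + (s[l + 1] - s[l]) * (half - prof[l]) / (prof[l + 1] - prof[l])
    sr <- s[r - 1] + (s[r] - s[r - 1]) * (prof[r - 1] - half) /
      (prof[r - 1] - prof[r])
    sr - sl
  }, 0)
  pk_um <- s[is_pk]
  list(s_um = s, profile = prof, peaks_um = pk_um, fwhm_um = fw,
       separations_um = if (length(pk_um) > 1L) diff(pk_um) else numeric())
}
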