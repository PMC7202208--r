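# Fourier-grid helpers shared by the wedge, bandpass and FSC code.
# Frequencies are kept in voxel units (cycles per box): index i along an axis
# of length n maps to integer frequency (i-1), wrapped to -n/2 .. n/2-1.

freq_axis <- function(n) {
  k <- 0:(n - 1)
  k[k >= n / 2] <- k[k >= n / 2] - n
  k
}

# List of kx, ky, kz arrays (n^3 each, fft layout) and the radial frequency.
.freq_cache <- new.env(parent = emptyenv())
freq_grids <- function(n) {
  key <- sprintf("%d", n)
  g <- .freq_cache[[key]]
  if (is.null(g)) {
    k <- freq_axis(n)
    kx <- array(rep(k, times = n * n), c(n, n, n))
    ky <- array(rep(rep(k, each = n), times = n), c(n, n, n))
    kz <- array(rep(k, each = n * n), c(n, n, n))
    g <- list(kx = kx, ky = ky, kz = kz,
              r = sqrt(kx^2 + ky^2 + kz^2))
    .freq_cache[[key]] <- g
  }
  g
}

fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Missing-wedge Fourier mask
#'
#' Builds the Fourier-space mask describing the sampling of a single-axis
#' tilt series: with the tilt axis along y and the beam along z, a Fourier
#' voxel is sampled when the angle of its (kx, kz) line from the kx axis lies
#' inside the collected tilt range. Voxels outside form the missing wedge.
#' A Gaussian soft edge of width `softness` (Fourier voxels) can be applied;
#' `softness = 0` gives a hard binary mask. The mask is Hermitian-symmetric
#' by construction.
#'
#' @param box Box size in voxels (even, >= 8).
#' @param tilt_min,tilt_max Collected tilt range in degrees,
#'   `-90 <= tilt_min < tilt_max <= 90`.
#' @param softness Gaussian edge width in Fourier voxels (default 1).
#' @return An object of class `wedge_mask` with elements `mask` (array in
#'   fft layout, values in `[0, 1]`), `box`, `tilt_min`, `tilt_max`,
#'   `softness`.
#' @examples
#' w <- wedge_mask(32, -60, 60, softness = 0)
#' retained_fraction(w)   # ~ 2/3
#' @export
wedge_mask <- function(box, tilt_min = -60, tilt_max = 60, softness = 1) {
  if (tilt_min < -90 || tilt_max > 90)
    stop("tilt range must lie within [-90, 90] degrees", call. = FALSE)
  if (tilt_min >= tilt_max)
    stop("`tilt_min` must be below `tilt_max`", call. = FALSE)
  g <- freq_grids(box)
  # line angle of (kx, kz) folded into (-90, 90]
  alpha <- atan2(g$kz, g$kx) * 180 / pi
  alpha[alpha > 90] <- alpha[alpha > 90] - 180
  alpha[alpha <= -90] <- alpha[alpha <= -90] + 180
  # half-open at the lower boundary: voxels exactly on a boundary line
  # (a lattice resonance at e.g. +-45 degrees) are counted once, not twice
  inside <- alpha > tilt_min & alpha <= tilt_max
  rxz <- sqrt(g$kx^2 + g$kz^2)
  inside[rxz == 0] <- TRUE   # the tilt axis is present in every projection
  if (softness <= 0) {
    m <- array(as.numeric(inside), dim(alpha))
  } else {
    # angular distance to the nearest wedge boundary, converted to voxels
    dmin <- pmin(pmin(abs(alpha - tilt_min), 180 - abs(alpha - tilt_min)),
                 pmin(abs(alpha - tilt_max), 180 - abs(alpha - tilt_max)))
    dvox <- rxz * sin(pmin(dmin, 90) * pi / 180)
    m <- ifelse(inside, 1, exp(-dvox^2 / (2 * softness^2)))
    m[rxz == 0] <- 1
  }
  # enforce Hermitian symmetry exactly: on the Nyquist planes of an even
  # grid, -k wraps onto the same plane and the line angle is ambiguous
  rev_idx <- c(1L, box:2L)
  m <- pmax(m, m[rev_idx, rev_idx, rev_idx])
  structure(list(mask = m, box = as.integer(box), tilt_min = tilt_min,
                 tilt_max = tilt_max, softness = softness),
            class = "wedge_mask")
}

#' @export
print.wedge_mask <- function(x, ...) {
  cat(sprintf(
    "<wedge_mask> box %d, tilts %+.0f..%+.0f deg, softness %g, retained %.1f%%\n",
    x$box, x$tilt_min, x$tilt_max, x$softness, 100 * retained_fraction(x)))
  invisible(x)
}

#' Retained Fourier fraction of a wedge mask
#'
#' Mean mask value over the Fourier voxels inside the Nyquist sphere, where
#' the line-angle distribution is uniform so a hard mask retains exactly
#' `span / 180` of the voxels (the cube corners beyond Nyquist are excluded
#' because they bias the angular distribution).
#'
#' @param wedge A `wedge_mask`.
#' @return Retained fraction in `[0, 1]`.
#' @export
retained_fraction <- function(wedge) {
  g <- freq_grids(wedge$box)
  sel <- g$r <= wedge$box / 2
  mean(wedge$mask[sel])
}

#' Apply a wedge mask to a volume
#'
#' Multiplies the volume's Fourier transform by the mask and transforms back.
#' This is the forward model of the tomographic sampling used by the phantom
#' renderer, and is idempotent for a hard mask.
#'
#' @param vol A `density_volume`.
#' @param wedge A `wedge_mask` with the same box size.
#' @return The wedge-filtered `density_volume`.
#' @export
apply_wedge <- function(vol, wedge) {
  if (box_size(vol) != wedge$box)
    stop("box sizes of volume and wedge differ", call. = FALSE)
  f <- fft3(vol$data) * wedge$mask
  density_volume(Re(ifft3(f)), vol$voxel_size, vol$origin)
}

# Radial band filter in fft layout: raised-cosine edge of width `edge`
# Fourier voxels lying entirely inside the band, so amplitudes outside the
# band are exactly zero. high_res at (or below) 2*voxel is a vacuous cut.
band_filter <- function(box, voxel_size, low_res = NULL, high_res = NULL,
                        edge = 1) {
  g <- freq_grids(box)
  m <- array(1, dim(g$r))
  cos_fall <- function(d) 0.5 * (1 + cos(pi * pmin(pmax(d, 0), edge) / edge))
  if (!is.null(high_res) && high_res > 2 * voxel_size) {
    r_hi <- box * voxel_size / high_res
    m <- m * ifelse(g$r <= r_hi - edge, 1,
                    ifelse(g$r >= r_hi, 0, cos_fall(g$r - (r_hi - edge))))
  }
  if (!is.null(low_res)) {
    r_lo <- box * voxel_size / low_res
    m <- m * ifelse(g$r >= r_lo + edge, 1,
                    ifelse(g$r <= r_lo, 0, cos_fall((r_lo + edge) - g$r)))
  }
  m[1, 1, 1] <- if (is.null(low_res)) 1 else 0
  m
}

#' Band-pass filter a volume
#'
#' Attenuates Fourier amplitudes outside the resolution band
#' `[low_res, high_res]` (Angstrom) to zero with a raised-cosine edge lying
#' inside the band, so total Fourier power never increases and no power
#' remains beyond the stated cutoff. `high_res` equal to `2 * voxel_size`
#' (Nyquist) imposes no high-frequency cut.
#'
#' @param vol A `density_volume`.
#' @param low_res Low-resolution (high-pass) cutoff in Angstrom, or `NULL`
#'   for none. Must exceed `high_res` when both are given.
#' @param high_res High-resolution (low-pass) cutoff in Angstrom; must be at
#'   least `2 * voxel_size`.
#' @param edge Soft-edge width in Fourier voxels (default 1).
#' @return The filtered `density_volume`.
#' @export
bandpass <- function(vol, low_res = NULL, high_res = NULL, edge = 1) {
  v <- vol$voxel_size
  if (!is.null(high_res) && high_res < 2 * v - 1e-9)
    stop("`high_res` is finer than the Nyquist limit of ", 2 * v, " A",
         call. = FALSE)
  if (!is.null(low_res) && !is.null(high_res) && low_res <= high_res)
    stop("`low_res` must be coarser (larger) than `high_res`", call. = FALSE)
  m <- band_filter(box_size(vol), v, low_res, high_res, edge)
  density_volume(Re(ifft3(fft3(vol$data) * m)), v, vol$origin)
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients of two
#' volumes on the same grid, the standard agreement measure between
#' independently refined half-maps. Shells are 1 Fourier voxel wide (bin
#' centers at integer radii); all-zero shells report a correlation of 0.
#'
#' @param a,b `density_volume`s with equal box and voxel size.
#' @param shell_width Shell width in Fourier voxels (default 1).
#' @return An object of class `fsc_curve`: a data frame with columns `shell`,
#'   `freq` (1/Angstrom), `fsc`, `n_voxels`, and attributes `voxel_size`,
#'   `box`.
#' @export
fsc_curve <- function(a, b, shell_width = 1) {
  check_same_grid(a, b)
  n <- box_size(a)
  fa <- fft3(a$data)
  fb <- fft3(b$data)
  g <- freq_grids(n)
  shell <- as.integer(floor(g$r / shell_width + 0.5))
  keep <- shell >= 1L & shell <= as.integer(n / 2 / shell_width)
  sh <- shell[keep]
  num <- Re(fa * Conj(fb))[keep]
  pa <- (Mod(fa)^2)[keep]
  pb <- (Mod(fb)^2)[keep]
  s_num <- rowsum(num, sh)
  s_pa <- rowsum(pa, sh)
  s_pb <- rowsum(pb, sh)
  cnt <- as.vector(table(sh))
  den <- sqrt(s_pa * s_pb)
  fsc <- ifelse(den > 0, s_num / den, 0)
  shells <- sort(unique(sh))
  out <- data.frame(shell = shells,
                    freq = shells * shell_width / (n * a$voxel_size),
                    fsc = as.numeric(fsc),
                    n_voxels = cnt)
  structure(out, class = c("fsc_curve", "data.frame"),
            voxel_size = a$voxel_size, box = n)
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.143, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Reads the resolution from an FSC curve as the reciprocal of the first
#' frequency at which the curve crosses below the threshold, linearly
#' interpolated between shells. A curve that never crosses reports the
#' Nyquist resolution `2 * voxel_size`; a curve already below the threshold
#' at its first shell is worse than the lowest measured shell and reports
#' `Inf` with a warning.
#'
#' @param curve An `fsc_curve`.
#' @param threshold FSC threshold; 0.143 is the convention for independent
#'   half-sets, 0.5 for maps refined against a common reference.
#' @return Resolution in Angstrom.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  if (nrow(curve) == 0L) stop("empty FSC curve", call. = FALSE)
  f <- curve$fsc
  if (f[1] < threshold) {
    warning("FSC starts below threshold: resolution worse than the lowest ",
            "measured shell", call. = FALSE)
    return(Inf)
  }
  below <- which(f < threshold)
  if (length(below) == 0L) return(2 * attr(curve, "voxel_size"))
  i <- below[1]
  # linear interpolation in frequency between shells i-1 and i
  f0 <- curve$freq[i - 1]; f1 <- curve$freq[i]
  y0 <- f[i - 1]; y1 <- f[i]
  fc <- f0 + (y0 - threshold) / (y0 - y1) * (f1 - f0)
  1 / fc
}
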