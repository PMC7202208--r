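#' Cubic density volume
#'
#' The universal data container of the pipeline: a real-valued cubic voxel
#' grid with a physical voxel size in Angstrom and the physical coordinate of
#' voxel (0,0,0). All geometric operations (rotation, symmetrization,
#' averaging, curvature fitting) share one convention: the rotation center is
#' the voxel with 0-based index N/2 along each axis, and physical coordinates
#' are measured in Angstrom from that center unless stated otherwise.
#'
#' @param data Numeric N x N x N array, N even and >= 8, all values finite.
#' @param voxel_size Voxel edge length in Angstrom (> 0).
#' @param origin Physical coordinate of voxel (0,0,0) in Angstrom, length 3.
#' @return An object of class `density_volume`.
#' @examples
#' v <- density_volume(array(0, c(16, 16, 16)), voxel_size = 5.4)
#' box_size(v)
#' @export
density_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  d <- dim(data)
  if (d[1] != d[2] || d[1] != d[3])
    stop("volume must be cubic; got ", paste(d, collapse = "x"), call. = FALSE)
  if (d[1] < 8L || d[1] %% 2L != 0L)
    stop("box size must be even and >= 8", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a positive scalar (Angstrom)", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<density_volume> %d^3 voxels, %.3f A/voxel (%.1f A box)\n",
              n, x$voxel_size, n * x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @rdname density_volume
#' @param vol A `density_volume`.
#' @export
box_size <- function(vol) dim(vol$data)[1]

is_density_volume <- function(x) inherits(x, "density_volume")

check_same_grid <- function(a, b) {
  if (box_size(a) != box_size(b))
    stop("box sizes differ: ", box_size(a), " vs ", box_size(b), call. = FALSE)
  if (abs(a$voxel_size - b$voxel_size) > 1e-6)
    stop("voxel sizes differ", call. = FALSE)
  invisible(TRUE)
}

# Vectorized trilinear interpolation. `coords` is a 3 x M matrix of 1-based
# fractional voxel indices; out-of-grid points take `fill`.
trilinear_interp <- function(arr, coords, fill) {
  n <- dim(arr)[1]
  x <- coords[1, ]; y <- coords[2, ]; z <- coords[3, ]
  ok <- x >= 1 & x <= n & y >= 1 & y <= n & z >= 1 & z <= n
  x0 <- pmin(pmax(floor(x), 1), n - 1)
  y0 <- pmin(pmax(floor(y), 1), n - 1)
  z0 <- pmin(pmax(floor(z), 1), n - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n2 <- n * n
  i000 <- (z0 - 1) * n2 + (y0 - 1) * n + x0
  v <- (1 - fx) * (1 - fy) * (1 - fz) * arr[i000] +
    fx * (1 - fy) * (1 - fz) * arr[i000 + 1] +
    (1 - fx) * fy * (1 - fz) * arr[i000 + n] +
    fx * fy * (1 - fz) * arr[i000 + n + 1] +
    (1 - fx) * (1 - fy) * fz * arr[i000 + n2] +
    fx * (1 - fy) * fz * arr[i000 + n2 + 1] +
    (1 - fx) * fy * fz * arr[i000 + n2 + n] +
    fx * fy * fz * arr[i000 + n2 + n + 1]
  v[!ok] <- fill
  v
}

# 3 x N^3 matrix of physical coordinates (Angstrom) relative to the box
# center (0-based voxel N/2); column order matches R's array linearization.
.coord_grid_cache <- new.env(parent = emptyenv())
coord_grid <- function(n, voxel_size) {
  key <- sprintf("%d", n)
  g <- .coord_grid_cache[[key]]
  if (is.null(g)) {
    ax <- seq_len(n) - 1 - n / 2
    g <- rbind(rep(ax, times = n * n),
               rep(rep(ax, each = n), times = n),
               rep(ax, each = n * n))
    .coord_grid_cache[[key]] <- g
  }
  g * voxel_size
}

# Generic inverse-mapped resample: output(y) = vol(map(y)) where
# map(y) = A %*% y + b in Angstrom relative to the box center.
affine_resample <- function(vol, A, b = c(0, 0, 0), fill = mean(vol$data)) {
  n <- box_size(vol)
  g <- coord_grid(n, vol$voxel_size)
  src <- A %*% g + as.numeric(b)
  idx <- src / vol$voxel_size + n / 2 + 1
  out <- trilinear_interp(vol$data, idx, fill)
  density_volume(array(out, dim(vol$data)), vol$voxel_size, vol$origin)
}

#' Rotate and shift a volume
#'
#' Applies a pose (Z-X-Z Euler triplet, degrees) and then a translation
#' (Angstrom) to a volume. The rotation center is the geometric box center
#' (0-based voxel N/2); resampling is trilinear and points mapped from
#' outside the source grid are filled with the volume mean, which avoids
#' spurious low-frequency edges. Formally, the output satisfies
#' `out(y) = vol(R^-1 (y - shift))` with `R = euler_matrix(pose)`.
#'
#' @param vol A `density_volume`.
#' @param pose Length-3 Euler triplet `(tdrot, tilt, narot)` in degrees.
#' @param shift Length-3 translation in Angstrom. Its magnitude must be below
#'   half the physical box width.
#' @return The resampled `density_volume`.
#' @export
rotate_shift <- function(vol, pose = c(0, 0, 0), shift = c(0, 0, 0)) {
  if (!is_density_volume(vol)) stop("`vol` must be a density_volume",
                                    call. = FALSE)
  if (sqrt(sum(shift^2)) >= box_size(vol) * vol$voxel_size / 2)
    stop("shift magnitude exceeds half the box width", call. = FALSE)
  R <- euler_matrix(pose)
  if (all(pose == 0) && all(shift == 0)) return(vol)
  affine_resample(vol, t(R), -t(R) %*% shift)
}

#' Undo a particle's pose
#'
#' Inverse of [rotate_shift()]: brings a particle rendered at
#' `(pose, shift)` back into the reference frame,
#' `out(x) = vol(R x + shift)`. Used by the averaging and classification
#' stages to accumulate particles in a common frame.
#'
#' @inheritParams rotate_shift
#' @return The resampled `density_volume`.
#' @export
backtransform <- function(vol, pose, shift = c(0, 0, 0)) {
  R <- euler_matrix(pose)
  affine_resample(vol, R, as.numeric(shift))
}

# Exact rotation of a cubic array by k*90 degrees about the z axis through
# the box center (0-based voxel N/2). Pure index permutation: the row at
# coordinate -N/2 wraps, consistent with the periodic Fourier convention.
# new(x, y) = old(y, -x) for +90 degrees.
rot90_z_array <- function(arr, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(arr)
  n <- dim(arr)[1]
  neg <- c(1L, n:2L)   # index of coordinate -c for each index of c
  out <- arr
  for (i in seq_len(k)) {
    out <- aperm(out, c(2L, 1L, 3L))[neg, , , drop = FALSE]
  }
  out
}

#' Four-fold symmetrization about the z axis
#'
#' Averages a volume over rotations by 0, 90, 180 and 270 degrees about the
#' box-center z axis. The 90-degree rotations are exact index permutations,
#' so the result is invariant under a further 90-degree rotation to machine
#' precision and the operation is idempotent.
#'
#' @param vol A `density_volume`.
#' @return The C4-symmetrized `density_volume`.
#' @export
symmetrize_c4 <- function(vol) {
  if (!is_density_volume(vol)) stop("`vol` must be a density_volume",
                                    call. = FALSE)
  a <- vol$data
  s <- (a + rot90_z_array(a, 1L) + rot90_z_array(a, 2L) +
          rot90_z_array(a, 3L)) / 4
  density_volume(s, vol$voxel_size, vol$origin)
}

# Mirror a volume through the horizontal plane z = 0 (box center), exact
# index permutation with periodic wrap.
flip_z <- function(vol) {
  n <- box_size(vol)
  density_volume(vol$data[, , c(1L, n:2L)], vol$voxel_size, vol$origin)
}
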