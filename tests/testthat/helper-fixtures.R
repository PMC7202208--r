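# Shared fixtures: small phantoms at binned voxel sizes that keep the same
# physical 345.6 A box as the full-scale 64 x 5.4 A geometry.

spec32 <- function(...) phantom_spec(box = 32, voxel_size = 10.8, ...)
spec48 <- function(...) phantom_spec(box = 48, voxel_size = 7.2, ...)

# a smooth off-axis Gaussian blob, useful for rotation/shift oracles
blob_volume <- function(n = 32, vs = 10.8, center = c(50, 30, 0),
                        sigma2 = 900) {
  g <- tomosta:::coord_grid(n, vs)
  d <- exp(-((g[1, ] - center[1])^2 + (g[2, ] - center[2])^2 +
               (g[3, ] - center[3])^2) / (2 * sigma2))
  density_volume(array(d, c(n, n, n)), vs)
}

noise_volume <- function(n = 32, vs = 10.8, seed = 1, sd = 1) {
  set.seed(seed)
  density_volume(array(rnorm(n^3, 0, sd), c(n, n, n)), vs)
}

rot90z <- function(arr, k = 1) tomosta:::rot90_z_array(arr, k)

# C4-symmetric unit-norm bump field orthogonalized against `against`
c4_bump <- function(n, vs, center, against = list(), sigma2 = 3000) {
  g <- tomosta:::coord_grid(n, vs)
  v <- array(exp(-((g[1, ] - center[1])^2 + (g[2, ] - center[2])^2 +
                     (g[3, ] - center[3])^2) / sigma2), c(n, n, n))
  v <- v + rot90z(v, 1) + rot90z(v, 2) + rot90z(v, 3)
  for (a in against) v <- v - sum(v * a) / sum(a * a) * a
  v / sqrt(sum(v^2))
}

# center a vector and make it sample-orthogonal to the given ones
sample_orth <- function(x, others = list()) {
  x <- x - mean(x)
  for (y in others) x <- x - sum(x * y) / sum(y * y) * y
  x - mean(x)
}
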