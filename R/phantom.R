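#' Phantom specification
#'
#' Geometry and imaging parameters of the synthetic receptor/membrane
#' phantom: a C4-symmetric ~2 MDa "mushroom" (square cytoplasmic slab,
#' cylindrical transmembrane stem, four ~40 A lumenal extension rods)
#' sitting on a spherical membrane patch. Defaults describe the package's
#' standard desk-scale phantom: box 64 at 5.4 A/voxel (a 2x-binned version
#' of the 200^3 / 2.7 A acquisition geometry), a 50 nm membrane radius and
#' a ~40 A bilayer.
#'
#' All lengths are Angstrom unless noted; `membrane_R` is in nm, or the
#' string `"flat"` for a planar membrane. `membrane_z` is the height of the
#' membrane midplane relative to the box center (the receptor's cytoplasmic
#' domain extends to +z, the SR lumen to -z).
#'
#' @param box Box size in voxels.
#' @param voxel_size Voxel size in Angstrom.
#' @param slab_width,slab_height Cytoplasmic slab footprint and height (A).
#' @param stem_radius Transmembrane stem radius (A).
#' @param stem_gap Gap between the membrane's cytoplasmic face and the
#'   bottom of the cytoplasmic slab (A); the stem spans it, mimicking the
#'   receptor body floating above the bilayer.
#' @param ext_length,ext_radius,ext_offset Lumenal extension rod length,
#'   radius, and distance of each rod axis from the symmetry axis (A).
#' @param membrane_R Membrane sphere radius in nm, or `"flat"`.
#' @param membrane_thickness Bilayer thickness (A).
#' @param membrane_z Membrane midplane height relative to box center (A).
#' @param snr Signal-to-noise power ratio used when rendering particles.
#' @param tilt_scheme A [tilt_scheme()], or `NULL` for no exposure filter.
#' @param density Global density scale of the receptor and membrane.
#' @param edge Soft edge width of all shapes (A).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(box = 64, voxel_size = 5.4,
                         slab_width = 220, slab_height = 60,
                         stem_radius = 40, stem_gap = 45,
                         ext_length = 40, ext_radius = 14, ext_offset = 50,
                         membrane_R = 50, membrane_thickness = 40,
                         membrane_z = -70,
                         snr = 1, tilt_scheme = default_tilt_scheme(),
                         density = 1, edge = NULL) {
  if (is.null(edge)) edge <- voxel_size
  half <- box * voxel_size / 2
  if (slab_width / 2 > half - 4 * voxel_size)
    stop("receptor slab does not fit in the box with a 4-voxel margin",
         call. = FALSE)
  top <- membrane_z + membrane_thickness / 2 + stem_gap + slab_height
  if (top > half - 4 * voxel_size)
    stop("receptor height does not fit in the box with a 4-voxel margin",
         call. = FALSE)
  if (!identical(membrane_R, "flat")) {
    if (!is.numeric(membrane_R) || membrane_R < 10)
      stop("`membrane_R` must be >= 10 nm or \"flat\"", call. = FALSE)
  }
  if (membrane_thickness < 2 * voxel_size)
    stop("membrane thinner than 2 voxels cannot be resolved", call. = FALSE)
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  structure(as.list(environment())[c(
    "box", "voxel_size", "slab_width", "slab_height", "stem_radius",
    "stem_gap", "ext_length", "ext_radius", "ext_offset", "membrane_R",
    "membrane_thickness", "membrane_z", "snr", "tilt_scheme", "density",
    "edge")], class = "phantom_spec")
}

# smooth step: 0 -> 1 over an edge of width w around d = 0 (d > 0 inside)
soft_in <- function(d, w) stats::pnorm(d / (w / 2))

#' Build the C4 receptor phantom
#'
#' Renders the receptor density of a [phantom_spec()]: square cytoplasmic
#' slab + transmembrane stem + four lumenal extension rods at 45, 135, 225
#' and 315 degrees. Every component is an analytic function invariant under
#' 90-degree rotation about z, so the phantom is exactly C4-symmetric (to
#' floating-point precision) and bit-reproducible for equal specs.
#'
#' @param spec A `phantom_spec`.
#' @return A `density_volume` with positive density.
#' @export
make_receptor_phantom <- function(spec) {
  n <- spec$box; vs <- spec$voxel_size; w <- spec$edge
  g <- coord_grid(n, vs)
  x <- g[1, ]; y <- g[2, ]; z <- g[3, ]
  zm <- spec$membrane_z; th <- spec$membrane_thickness
  # cytoplasmic slab floats above the membrane, carried by the stem
  z0 <- zm + th / 2 + spec$stem_gap
  slab <- soft_in(spec$slab_width / 2 - abs(x), w) *
    soft_in(spec$slab_width / 2 - abs(y), w) *
    soft_in(z - z0, w) * soft_in(z0 + spec$slab_height - z, w)
  rho <- sqrt(x^2 + y^2)
  stem <- soft_in(spec$stem_radius - rho, w) *
    soft_in(z - (zm - th / 2 - 5), w) * soft_in(z0 + 5 - z, w)
  # four lumenal rods, axes vertical, below the membrane
  zr_hi <- zm - th / 2
  zr_lo <- zr_hi - spec$ext_length
  ang <- (c(45, 135, 225, 315)) * pi / 180
  ext <- 0
  for (a in ang) {
    cx <- spec$ext_offset * cos(a); cy <- spec$ext_offset * sin(a)
    dr <- sqrt((x - cx)^2 + (y - cy)^2)
    ext <- ext + soft_in(spec$ext_radius - dr, w) *
      soft_in(z - zr_lo, w) * soft_in(zr_hi - z, w)
  }
  d <- spec$density * (slab + stem + pmin(ext, 1))
  density_volume(array(d, c(n, n, n)), vs)
}

#' Build a membrane patch
#'
#' Renders a spherical-shell membrane cap of the given thickness whose
#' sphere passes through the box's membrane plane at the symmetry axis (the
#' sphere center lies on the axis at `membrane_z - R`, on the lumenal side),
#' or a flat sheet when `membrane_R = "flat"`.
#'
#' @param spec A `phantom_spec` (fields `membrane_R`, `membrane_thickness`,
#'   `membrane_z`, `box`, `voxel_size`, `density`, `edge` are used).
#' @return A `density_volume`.
#' @export
make_membrane_patch <- function(spec) {
  n <- spec$box; vs <- spec$voxel_size; w <- spec$edge
  g <- coord_grid(n, vs)
  x <- g[1, ]; y <- g[2, ]; z <- g[3, ]
  th <- spec$membrane_thickness; zm <- spec$membrane_z
  if (identical(spec$membrane_R, "flat")) {
    d <- soft_in(th / 2 - abs(z - zm), w)
  } else {
    R <- spec$membrane_R * 10   # nm -> A
    cz <- zm - R
    dist <- sqrt(x^2 + y^2 + (z - cz)^2)
    d <- soft_in(th / 2 - abs(dist - R), w)
  }
  density_volume(array(spec$density * d, c(n, n, n)), vs)
}

#' Full phantom: receptor plus membrane
#'
#' @param spec A `phantom_spec`.
#' @return A `density_volume`.
#' @export
make_phantom <- function(spec) {
  r <- make_receptor_phantom(spec)
  m <- make_membrane_patch(spec)
  density_volume(r$data + m$data, spec$voxel_size)
}

#' Dose-symmetric tilt scheme
#'
#' Describes the tilt-series acquisition: a single-axis dose-symmetric
#' scheme over `tilt_min..tilt_max` in steps of `step` degrees, with
#' `dose_per_tilt` e/A^2 per image and optionally a larger dose on the
#' untilted image. The acquisition order is dose-symmetric (0, +step,
#' -step, -2 step, +2 step, ...), so the 0-degree tilt carries the lowest
#' cumulative prior dose. The total dose is the sum of the per-tilt doses.
#'
#' @param tilt_min,tilt_max Tilt range in degrees.
#' @param step Tilt increment in degrees.
#' @param dose_per_tilt Dose per tilt image, e/A^2.
#' @param zero_tilt_dose Dose of the untilted image, e/A^2 (default 18).
#' @return An object of class `tilt_scheme` with fields `tilts` (in
#'   acquisition order), `dose` (per tilt), `cum_dose` (dose accumulated
#'   before the midpoint of each tilt) and `total_dose`.
#' @export
tilt_scheme <- function(tilt_min = -60, tilt_max = 60, step = 3,
                        dose_per_tilt = 1.1, zero_tilt_dose = 18) {
  tilts_sorted <- seq(tilt_min, tilt_max, by = step)
  # dose-symmetric ordering: by |tilt|, alternating the side in pairs
  ord <- order(abs(tilts_sorted), -sign(tilts_sorted))
  by_mag <- tilts_sorted[ord]
  tilts <- numeric(0)
  i <- 1; side <- 1
  while (i <= length(by_mag)) {
    grp <- by_mag[abs(by_mag) == abs(by_mag[i])]
    if (length(grp) == 2L && side < 0) grp <- rev(grp)
    tilts <- c(tilts, grp)
    i <- i + length(grp)
    side <- -side
  }
  dose <- rep(dose_per_tilt, length(tilts))
  if (!is.null(zero_tilt_dose)) dose[abs(tilts) < step / 2] <- zero_tilt_dose
  cum <- cumsum(dose) - dose / 2
  structure(list(tilts = tilts, dose = dose, cum_dose = cum,
                 total_dose = sum(dose), step = step,
                 tilt_min = tilt_min, tilt_max = tilt_max),
            class = "tilt_scheme")
}

#' @rdname tilt_scheme
#' @export
default_tilt_scheme <- function() tilt_scheme()

#' @export
print.tilt_scheme <- function(x, ...) {
  cat(sprintf(
    "<tilt_scheme> %d tilts %+.0f..%+.0f deg step %g, total dose %.1f e/A^2\n",
    length(x$tilts), x$tilt_min, x$tilt_max, x$step, x$total_dose))
  invisible(x)
}

# Critical exposure (e/A^2) as a function of spatial frequency (1/A):
# the standard empirical radiation-damage curve.
critical_exposure <- function(freq) {
  0.245 * pmax(freq, 1e-6)^(-1.665) + 2.81
}

#' Aggregate exposure filter of a tilt scheme
#'
#' Per-tilt amplitude attenuation `exp(-cum_dose / (2 Nc(f)))` with the
#' standard critical-exposure curve `Nc(f)`, averaged over the tilts of the
#' dose-symmetric scheme weighted by per-tilt dose. Returns one radial
#' attenuation profile applied to each particle's Fourier transform.
#'
#' @param scheme A [tilt_scheme()].
#' @param box Box size in voxels.
#' @param voxel_size Voxel size in Angstrom.
#' @return A `box^3` array (fft layout) of attenuation factors in `(0, 1]`.
#' @export
dose_filter <- function(scheme, box, voxel_size) {
  key <- sprintf("%d_%.6g_%.6g_%.6g_%d", box, voxel_size, scheme$total_dose,
                 scheme$step, length(scheme$tilts))
  cached <- .dose_cache[[key]]
  if (!is.null(cached)) return(cached)
  g <- freq_grids(box)
  freq <- g$r / (box * voxel_size)      # 1/A
  nc <- critical_exposure(freq)
  w <- array(0, dim(nc))
  for (i in seq_along(scheme$tilts)) {
    w <- w + scheme$dose[i] * exp(-scheme$cum_dose[i] / (2 * nc))
  }
  w <- w / sum(scheme$dose)
  .dose_cache[[key]] <- w
  w
}
.dose_cache <- new.env(parent = emptyenv())

#' Render one noisy missing-wedge particle
#'
#' Forward model of a subtomogram: the ground-truth map is rotated and
#' shifted to the particle's pose, attenuated by the aggregate exposure
#' filter of the tilt scheme, masked by the missing wedge, and white
#' Gaussian noise is added so that signal power / noise power equals `snr`
#' (no noise for infinite `snr`). The returned record stores the true pose
#' and shift.
#'
#' @param ground_truth A `density_volume`.
#' @param pose Euler triplet (degrees).
#' @param shift Shift in Angstrom.
#' @param wedge A `wedge_mask`, or `NULL` for full sampling.
#' @param snr Signal-to-noise power ratio (> 0, may be `Inf`).
#' @param scheme A [tilt_scheme()] or `NULL` for no exposure filter.
#' @param seed Integer seed for the noise draw.
#' @return `list(volume = density_volume, record = one-row data.frame)`.
#' @export
render_particle <- function(ground_truth, pose = c(0, 0, 0),
                            shift = c(0, 0, 0), wedge = NULL, snr = Inf,
                            scheme = NULL, seed = 1) {
  if (snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  v <- rotate_shift(ground_truth, pose, shift)
  filtered <- !is.null(scheme) || !is.null(wedge)
  if (filtered) {
    f <- fft3(v$data)
    if (!is.null(scheme))
      f <- f * dose_filter(scheme, box_size(v), v$voxel_size)
    if (!is.null(wedge)) {
      if (wedge$box != box_size(v)) stop("wedge box mismatch", call. = FALSE)
      f <- f * wedge$mask
    }
    v <- density_volume(Re(ifft3(f)), v$voxel_size, v$origin)
  }
  if (is.finite(snr)) {
    sig_power <- stats::var(as.vector(v$data))
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    noise <- stats::rnorm(length(v$data), sd = sqrt(sig_power / snr))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    v <- density_volume(v$data + array(noise, dim(v$data)),
                        v$voxel_size, v$origin)
  }
  rec <- data.frame(id = NA_integer_, x = 0, y = 0, z = 0,
                    tdrot = pose[1], tilt = pose[2], narot = pose[3],
                    dx = shift[1], dy = shift[2], dz = shift[3],
                    cc = NA_real_, class = NA_integer_,
                    halfset = NA_character_)
  list(volume = v, record = rec)
}

#' Ensemble specification
#'
#' Describes a synthetic particle population: number of particles, class
#' occupancies, the deformation applied to each class, and the pose/shift
#' distribution. Deformations act on the phantom geometry: `radial_scale`
#' scales the cytoplasmic slab footprint (peripheral-domain breathing),
#' `vertical_scale` scales the slab height (vertical stretch), and
#' `membrane_R` overrides the membrane radius in nm (curvature jitter).
#' Poses emulate membrane-bound particles: uniform in-plane rotation,
#' tilt from the membrane normal folded from a centered normal with spread
#' `tilt_spread`, uniform azimuth.
#'
#' @param n_particles Number of particles (>= 1).
#' @param occupancies Class fractions, summing to 1 (tolerance 1e-6).
#' @param deformations List (one element per class) of lists with any of
#'   `radial_scale`, `vertical_scale`, `membrane_R`.
#' @param tilt_spread SD (degrees) of the tilt-from-normal distribution.
#' @param shift_sd SD (Angstrom) of the random particle shifts per axis.
#' @param seed Integer seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_particles, occupancies = 1,
                          deformations = NULL, tilt_spread = 10,
                          shift_sd = 6, seed = 1) {
  if (n_particles < 1) stop("`n_particles` must be >= 1", call. = FALSE)
  if (any(occupancies <= 0) || any(occupancies > 1) ||
      abs(sum(occupancies) - 1) > 1e-6)
    stop("`occupancies` must lie in (0, 1] and sum to 1", call. = FALSE)
  k <- length(occupancies)
  if (is.null(deformations)) deformations <- rep(list(list()), k)
  if (length(deformations) != k)
    stop("need one deformation entry per class", call. = FALSE)
  stopifnot(all(vapply(deformations, function(d)
    all(vapply(d, function(x) is.numeric(x) && all(is.finite(x)), TRUE)),
    TRUE)))
  structure(list(n_particles = as.integer(n_particles),
                 occupancies = occupancies, deformations = deformations,
                 tilt_spread = tilt_spread, shift_sd = shift_sd,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Apply a class deformation to a phantom_spec and build the class map.
class_phantom <- function(pspec, deformation) {
  s <- pspec
  if (!is.null(deformation$radial_scale)) {
    s$slab_width <- s$slab_width * deformation$radial_scale
    s$ext_offset <- s$ext_offset * deformation$radial_scale
  }
  if (!is.null(deformation$vertical_scale))
    s$slab_height <- s$slab_height * deformation$vertical_scale
  if (!is.null(deformation$membrane_R))
    s$membrane_R <- deformation$membrane_R
  make_phantom(s)
}

#' Region affected by the planted class deformations
#'
#' Binary mask of voxels where the noise-free class maps differ from their
#' mean by more than `tol` times the maximum deviation, i.e. the planted
#' deformation footprint used to validate mode half-maps.
#'
#' @param espec An `ensemble_spec`.
#' @param pspec A `phantom_spec`.
#' @param tol Relative threshold (default 0.05).
#' @return A logical array of the phantom's dimensions.
#' @export
deformation_mask <- function(espec, pspec, tol = 0.05) {
  maps <- lapply(espec$deformations, function(d) class_phantom(pspec, d)$data)
  m <- Reduce(`+`, maps) / length(maps)
  dev <- Reduce(pmax, lapply(maps, function(a) abs(a - m)))
  dev > tol * max(dev)
}

#' Simulate a particle ensemble
#'
#' Draws class labels from the occupancies, builds the deformed phantom per
#' class, draws poses and shifts, and renders each particle through the
#' exposure filter, missing wedge and noise model of the phantom spec. Two
#' tables are returned: `truth` (true pose, shift and class) and `records`
#' (the working table the pipeline operates on: zero pose/shift, unknown
#' class, half-sets pre-assigned at random). When `dir` is given, volumes
#' (MRC) and both tables (TSV) are also written there.
#'
#' @param espec An [ensemble_spec()].
#' @param pspec A [phantom_spec()].
#' @param wedge A `wedge_mask`, or `NULL` to build the default +-60 degree
#'   mask for the phantom box.
#' @param dir Optional output directory.
#' @return `list(particles, records, truth, class_maps, wedge)` where
#'   `particles` is a list of `density_volume`s.
#' @export
simulate_ensemble <- function(espec, pspec, wedge = NULL, dir = NULL) {
  if (is.null(wedge)) wedge <- wedge_mask(pspec$box)
  k <- length(espec$occupancies)
  class_maps <- lapply(espec$deformations, function(d) class_phantom(pspec, d))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(espec$seed)
  n <- espec$n_particles
  labels <- sample.int(k, n, replace = TRUE, prob = espec$occupancies)
  tdrot <- stats::runif(n, 0, 360)
  tilt <- abs(stats::rnorm(n, 0, espec$tilt_spread))
  narot <- stats::runif(n, 0, 360)
  shifts <- matrix(stats::rnorm(3 * n, 0, espec$shift_sd), n, 3)
  halfset <- sample(rep(c("A", "B"), length.out = n))
  seeds <- sample.int(2^30, n)
  # particles scattered in a synthetic 1 x 1 x 0.2 um tomogram slab
  pos <- cbind(stats::runif(n, 0, 1e4), stats::runif(n, 0, 1e4),
               stats::runif(n, 0, 2e3))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  particles <- vector("list", n)
  for (i in seq_len(n)) {
    r <- render_particle(class_maps[[labels[i]]],
                         pose = c(tdrot[i], tilt[i], narot[i]),
                         shift = shifts[i, ], wedge = wedge,
                         snr = pspec$snr, scheme = pspec$tilt_scheme,
                         seed = seeds[i])
    particles[[i]] <- r$volume
  }
  truth <- particle_set(data.frame(
    id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
    tdrot = tdrot, tilt = tilt, narot = narot,
    dx = shifts[, 1], dy = shifts[, 2], dz = shifts[, 3],
    cc = NA_real_, class = labels, halfset = halfset))
  records <- truth
  records$tdrot <- 0; records$tilt <- 0; records$narot <- 0
  records$dx <- 0; records$dy <- 0; records$dz <- 0
  records$class <- 0L
  out <- list(particles = particles, records = records, truth = truth,
              class_maps = class_maps, wedge = wedge)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_mrc(particles[[i]], file.path(dir, sprintf("particle_%04d.mrc", i)))
    write_particle_table(truth, file.path(dir, "truth.tsv"))
    write_particle_table(records, file.path(dir, "particles.tsv"))
  }
  out
}
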