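#' Resample a volume onto spherical shells
#'
#' Samples the density on spheres centered on the particle's symmetry axis
#' at distance `R` below the membrane midplane (on the lumenal side), so a
#' membrane lying on the sphere of radius `R` maps to a constant-radius
#' sheet. The sampling grid covers radii `R +- r_window` at half-voxel
#' spacing and a polar/azimuthal angle grid whose arc spacing is about one
#' voxel at the membrane.
#'
#' @param vol A `density_volume`.
#' @param R Candidate sphere radius in nm.
#' @param membrane_z Height of the membrane midplane relative to the box
#'   center (Angstrom).
#' @param r_window Radial window half-width (Angstrom, default 60).
#' @param r_exclude Central exclusion radius (Angstrom): angular columns
#'   whose lateral distance from the symmetry axis is below this (the
#'   receptor stem footprint) are omitted. Default 100 A (10 nm).
#' @param lateral_max Maximum lateral distance sampled (Angstrom); default
#'   leaves a 2-voxel margin to the box edge.
#' @return An object of class `spherical_grid`: `values` (radius x column
#'   matrix), `r` (radii, Angstrom), `theta`, `phi` (per column, radians),
#'   `R`, `origin_z`.
#' @export
spherical_resample <- function(vol, R, membrane_z = 0, r_window = 60,
                               r_exclude = 100, lateral_max = NULL) {
  n <- box_size(vol)
  vs <- vol$voxel_size
  half <- n * vs / 2
  if (is.null(lateral_max)) lateral_max <- half - 2 * vs
  R_A <- R * 10
  if (R_A < lateral_max)
    warning("R smaller than the sampled lateral reach: partial coverage",
            call. = FALSE)
  oz <- membrane_z - R_A
  rr <- seq(R_A - r_window, R_A + r_window, by = vs / 2)
  th_max <- asin(min(1, lateral_max / R_A))
  th_min <- asin(min(1, r_exclude / R_A))
  dth <- vs / R_A
  theta <- seq(th_min, th_max, by = dth)
  cols <- list()
  for (t in theta) {
    nphi <- max(8L, ceiling(2 * pi * R_A * sin(t) / vs))
    phi <- seq(0, 2 * pi - 2 * pi / nphi, by = 2 * pi / nphi)
    cols[[length(cols) + 1L]] <- cbind(t, phi)
  }
  ang <- do.call(rbind, cols)
  st <- sin(ang[, 1]); ct <- cos(ang[, 1])
  dirs <- rbind(st * cos(ang[, 2]), st * sin(ang[, 2]), ct)
  # sample points: origin + r * direction, in Angstrom about the box center
  pts_x <- outer(dirs[1, ], rr)               # col x radius
  pts_y <- outer(dirs[2, ], rr)
  pts_z <- oz + outer(dirs[3, ], rr)
  coords <- rbind(as.vector(pts_x), as.vector(pts_y), as.vector(pts_z))
  idx <- coords / vs + n / 2 + 1
  vals <- trilinear_interp(vol$data, idx, NA_real_)
  values <- t(matrix(vals, nrow(ang), length(rr)))   # radius x column
  zmat <- t(pts_z)
  structure(list(values = values, z = zmat, r = rr, theta = ang[, 1],
                 phi = ang[, 2], R = R, origin_z = oz,
                 membrane_z = membrane_z, voxel_size = vs),
            class = "spherical_grid")
}

#' Flatness score of a spherically resampled membrane
#'
#' Locates the membrane in each angular column as the density-weighted
#' radial centroid around the column's density peak and scores flatness as
#' the variance of those centroids across columns, in voxels squared: a
#' membrane lying exactly on the candidate sphere gives a near-zero score.
#' Columns without a detectable membrane peak (below `min_peak` times the
#' strongest column) are skipped; if more than half the columns are
#' undetectable, a detection error is raised.
#'
#' @param grid A `spherical_grid`.
#' @param min_peak Relative peak threshold for a column to count as
#'   detected (default 0.3).
#' @param z_band Membrane-height band half-width (Angstrom): samples
#'   farther than this from the nominal membrane midplane are ignored, so
#'   the receptor body above the bilayer cannot masquerade as membrane.
#' @return Scalar score (voxels^2), with attributes `centroids`, `valid`.
#' @export
flatness_score <- function(grid, min_peak = 0.3, z_band = 60) {
  v <- grid$values
  v[abs(grid$z - grid$membrane_z) > z_band] <- NA_real_
  ncol_ang <- ncol(v)
  peak <- suppressWarnings(apply(v, 2, max, na.rm = TRUE))
  base <- suppressWarnings(apply(v, 2, min, na.rm = TRUE))
  peak[!is.finite(peak)] <- 0; base[!is.finite(base)] <- 0
  contrast <- peak - base
  ref <- max(contrast)
  scale <- max(abs(v), na.rm = TRUE)
  detectable <- is.finite(scale) && ref > 1e-6 * max(scale, 1e-12)
  valid <- detectable & contrast > min_peak * ref
  if (mean(valid) < 0.5)
    stop("no detectable membrane peak in more than half of the angular ",
         "columns", call. = FALSE)
  cent <- rep(NA_real_, ncol_ang)
  rv <- grid$r / grid$voxel_size
  for (j in which(valid)) {
    col <- v[, j]
    col[is.na(col)] <- base[j]
    w <- pmax(col - (base[j] + 0.5 * contrast[j]), 0)
    cent[j] <- sum(w * rv) / sum(w)
  }
  score <- stats::var(cent[valid])
  attr(score, "centroids") <- cent
  attr(score, "valid") <- valid
  score
}

# Flatness of the membrane in plain Cartesian columns: the flat-membrane
# sentinel. Columns are (x, y) positions; the per-column z centroid is
# scored exactly like the spherical case.
flatness_score_flat <- function(vol, membrane_z, z_window = 60,
                                r_exclude = 100, min_peak = 0.3) {
  n <- box_size(vol); vs <- vol$voxel_size
  ax <- (seq_len(n) - 1 - n / 2) * vs
  zi <- which(abs(ax - membrane_z) <= z_window)
  lat_max <- n * vs / 2 - 2 * vs
  rho <- sqrt(outer(ax^2, ax^2, `+`))
  sel <- which(rho >= r_exclude & rho <= lat_max, arr.ind = TRUE)
  vals <- vol$data[, , zi]
  cent <- rep(NA_real_, nrow(sel))
  peaks <- numeric(nrow(sel))
  prof <- matrix(vals[cbind(rep(sel[, 1], length(zi)),
                            rep(sel[, 2], length(zi)),
                            rep(seq_along(zi), each = nrow(sel)))],
                 nrow(sel), length(zi))
  peaks <- apply(prof, 1, max)
  bases <- apply(prof, 1, min)
  contrast <- peaks - bases
  ref <- max(contrast)
  scale <- max(abs(prof))
  detectable <- is.finite(scale) && ref > 1e-6 * max(scale, 1e-12)
  valid <- detectable & contrast > min_peak * ref
  if (mean(valid) < 0.5)
    stop("no detectable membrane peak in more than half of the columns",
         call. = FALSE)
  zv <- ax[zi] / vs
  for (j in which(valid)) {
    w <- pmax(prof[j, ] - (bases[j] + 0.5 * contrast[j]), 0)
    cent[j] <- sum(w * zv) / sum(w)
  }
  score <- stats::var(cent[valid])
  attr(score, "centroids") <- cent
  attr(score, "valid") <- valid
  score
}

#' Fit the membrane radius of curvature
#'
#' Scans candidate sphere radii, scoring the flatness of the membrane in
#' spherical coordinates at each, refines around the best grid point by
#' golden-section search to 1 nm, and optionally compares against the flat
#' (infinite-radius) sentinel. The optimal radius and its curvature `1/R`
#' are returned together with the full score profile.
#'
#' @param vol A `density_volume` (an average map containing a membrane).
#' @param R_grid Candidate radii in nm (default `seq(20, 200, by = 10)`).
#' @param membrane_z Membrane midplane height (Angstrom from box center).
#' @param include_flat Also score the flat sentinel (default `TRUE`).
#' @param r_exclude,r_window,min_peak,z_band Passed to the
#'   resampler/scorer.
#' @return An object of class `curvature_fit`: `R` (nm; `Inf` when flat
#'   wins), `curvature` (1/nm; 0 when flat), `score`, `profile` (data frame
#'   of radius and score), `flat_score`, `boundary` (logical: best at grid
#'   edge).
#' @export
fit_membrane_radius <- function(vol, R_grid = seq(20, 200, by = 10),
                                membrane_z = 0, include_flat = TRUE,
                                r_exclude = 100, r_window = 60,
                                min_peak = 0.3, z_band = 60) {
  score_R <- function(R) {
    g <- suppressWarnings(
      spherical_resample(vol, R, membrane_z, r_window, r_exclude))
    as.numeric(flatness_score(g, min_peak, z_band))
  }
  # a candidate sphere that cannot see the membrane scores Inf
  score_R_safe <- function(R)
    tryCatch(score_R(R), error = function(e) Inf)
  scores <- vapply(R_grid, score_R_safe, numeric(1))
  if (all(!is.finite(scores)))
    stop("no detectable membrane at any candidate radius", call. = FALSE)
  i <- which.min(scores)
  boundary <- i == 1L || i == length(R_grid)
  if (boundary)
    warning("best flatness score at the edge of the radius grid",
            call. = FALSE)
  lo <- R_grid[max(1L, i - 1L)]
  hi <- R_grid[min(length(R_grid), i + 1L)]
  opt <- stats::optimize(score_R_safe, c(lo, hi), tol = 1)
  best_R <- opt$minimum
  best_score <- opt$objective
  if (best_score > scores[i]) { best_R <- R_grid[i]; best_score <- scores[i] }
  flat_score <- if (include_flat)
    tryCatch(as.numeric(flatness_score_flat(vol, membrane_z, z_band,
                                            r_exclude, min_peak)),
             error = function(e) Inf)
  else Inf
  if (flat_score < best_score) {
    out <- list(R = Inf, curvature = 0, score = flat_score)
  } else {
    out <- list(R = best_R, curvature = 1 / best_R, score = best_score)
  }
  structure(c(out, list(
    profile = data.frame(R = R_grid, score = scores),
    flat_score = flat_score, boundary = boundary,
    membrane_z = membrane_z)), class = "curvature_fit")
}

#' @export
print.curvature_fit <- function(x, ...) {
  if (is.finite(x$R))
    cat(sprintf(
      "<curvature_fit> R = %.1f nm (curvature %.4f 1/nm), score %.3g vox^2\n",
      x$R, x$curvature, x$score))
  else
    cat(sprintf("<curvature_fit> flat membrane (curvature 0), score %.3g\n",
                x$score))
  invisible(x)
}

#' @export
plot.curvature_fit <- function(x, ...) {
  graphics::plot(x$profile$R, x$profile$score, type = "b", log = "y",
                 xlab = "candidate radius R (nm)",
                 ylab = "flatness score (voxel^2)", ...)
  if (is.finite(x$R)) graphics::abline(v = x$R, lty = 2, col = "red3")
  invisible(x)
}

#' Classify membrane patches by curvature
#'
#' Fits each receptor-free membrane patch with the sphere center on either
#' side of the membrane plus the flat sentinel, and reports a signed
#' curvature per patch (positive = concave toward the cytoplasm, i.e. the
#' sphere center on the lumenal side) and the population fractions over
#' concave / near-flat / convex, where near-flat means the flat sentinel
#' wins or `|R| > flat_R` nm.
#'
#' @param volumes List of membrane-patch `density_volume`s.
#' @param membrane_z Membrane midplane height (Angstrom).
#' @param R_grid Candidate radii (nm).
#' @param flat_R Radius beyond which a patch counts as near-flat (nm).
#' @param r_exclude Central exclusion radius (Angstrom); patches have no
#'   receptor stem, so the default is 0.
#' @param ... Passed to [fit_membrane_radius()].
#' @return `list(patches = data.frame(R, curvature, category), fractions)`.
#' @export
classify_membrane_patches <- function(volumes, membrane_z = 0,
                                      R_grid = seq(20, 200, by = 10),
                                      flat_R = 150, r_exclude = 0, ...) {
  if (length(volumes) < 1) stop("need at least one patch", call. = FALSE)
  no_fit <- list(R = Inf, curvature = 0, score = Inf)
  rows <- lapply(volumes, function(v) {
    # a side whose sphere family cannot see the membrane simply loses
    fit_up <- tryCatch(
      fit_membrane_radius(v, R_grid, membrane_z, r_exclude = r_exclude, ...),
      error = function(e) no_fit)
    fit_dn <- tryCatch(
      fit_membrane_radius(flip_z(v), R_grid, -membrane_z,
                          r_exclude = r_exclude, ...),
      error = function(e) no_fit)
    if (!is.finite(fit_up$score) && !is.finite(fit_dn$score))
      stop("no detectable membrane in patch", call. = FALSE)
    if (!is.finite(fit_up$R) && !is.finite(fit_dn$R)) {
      data.frame(R = Inf, curvature = 0, category = "near-flat")
    } else if (fit_up$score <= fit_dn$score) {
      data.frame(R = fit_up$R, curvature = fit_up$curvature,
                 category = if (!is.finite(fit_up$R) || fit_up$R > flat_R)
                   "near-flat" else "concave")
    } else {
      data.frame(R = -fit_dn$R, curvature = -fit_dn$curvature,
                 category = if (!is.finite(fit_dn$R) || fit_dn$R > flat_R)
                   "near-flat" else "convex")
    }
  })
  patches <- do.call(rbind, rows)
  fractions <- prop.table(table(factor(patches$category,
                                       c("concave", "near-flat", "convex"))))
  list(patches = patches, fractions = fractions)
}
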