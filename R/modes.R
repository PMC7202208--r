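#' Align class averages to a common average
#'
#' Iteratively aligns each (fully sampled) class-average volume to the
#' evolving mean with a translation search plus a small in-plane rotation
#' search, C4-constrained and full-band: class averages carry no missing
#' wedge, so no wedge constraint is needed. Stops when the largest pose
#' update falls below a tenth of a voxel, or proceeds with a warning after
#' `max_rounds` rounds.
#'
#' @param volumes List of at least 3 `density_volume`s on a common grid.
#' @param max_rounds Maximum alignment rounds (default 5).
#' @param inplane_range,inplane_step Local in-plane search (degrees); the
#'   default searches -6..6 in steps of 2.
#' @param shift_limit Translation limit (Angstrom, default 30).
#' @param symmetry Symmetrize the common average with C4.
#' @return `list(aligned, mean, shifts, angles, rounds, converged)`.
#' @export
align_class_averages <- function(volumes, max_rounds = 5,
                                 inplane_range = 6, inplane_step = 2,
                                 shift_limit = 30, symmetry = TRUE) {
  n <- length(volumes)
  if (n < 3) stop("need at least 3 volumes", call. = FALSE)
  vs <- volumes[[1]]$voxel_size
  box <- box_size(volumes[[1]])
  for (v in volumes) check_same_grid(v, volumes[[1]])
  sub <- band_subset(box, vs, NULL)
  nus <- seq(-inplane_range, inplane_range, by = inplane_step)
  g <- freq_grids(box)
  ok <- sqrt(g$kx^2 + g$ky^2 + g$kz^2) * vs <= shift_limit
  shifts <- matrix(0, n, 3)
  angles <- numeric(n)
  aligned <- volumes
  mean_vol <- function(vols) {
    m <- Reduce(`+`, lapply(vols, `[[`, "data")) / length(vols)
    mv <- density_volume(m, vs)
    if (symmetry) mv <- symmetrize_c4(mv) else mv
  }
  converged <- FALSE
  rounds <- 0L
  for (round in seq_len(max_rounds)) {
    rounds <- round
    max_update <- 0
    total <- Reduce(`+`, lapply(aligned, `[[`, "data"))
    for (i in seq_len(n)) {
      # leave-one-out target avoids aligning a volume against itself
      tgt <- density_volume((total - aligned[[i]]$data) / (n - 1), vs)
      if (symmetry) tgt <- symmetrize_c4(tgt)
      fm <- Conj(fft3(tgt$data))
      best <- list(score = -Inf)
      for (nu in nus) {
        v <- if (nu == 0) volumes[[i]]
        else rotate_shift(volumes[[i]], c(0, 0, nu))
        cc <- Re(stats::fft(fft3(v$data) * fm, inverse = TRUE))
        cc[!ok] <- -Inf
        pk <- arrayInd(which.max(cc), dim(cc))
        if (cc[pk] > best$score)
          best <- list(score = cc[pk], nu = nu, cc = cc, pk = pk)
      }
      pk <- best$pk
      delta <- numeric(3)
      for (ax in 1:3) {
        im <- pk; ip <- pk
        im[ax] <- ((pk[ax] - 2) %% box) + 1
        ip[ax] <- (pk[ax] %% box) + 1
        c0 <- best$cc[pk]; cm <- best$cc[im]; cp <- best$cc[ip]
        if (is.finite(cm) && is.finite(cp) && (cm - 2 * c0 + cp) < 0)
          delta[ax] <- 0.5 * (cm - cp) / (cm - 2 * c0 + cp)
      }
      u <- (freq_axis(box)[pk] + delta) * vs
      # the volume is displaced by +u relative to the target: undo it
      new_shift <- -u
      upd <- sqrt(sum((new_shift - shifts[i, ])^2)) / vs +
        abs(best$nu - angles[i]) / 10
      max_update <- max(max_update, upd)
      shifts[i, ] <- new_shift
      angles[i] <- best$nu
      old_data <- aligned[[i]]$data
      aligned[[i]] <- rotate_shift(volumes[[i]], c(0, 0, best$nu), new_shift)
      total <- total - old_data + aligned[[i]]$data
    }
    if (max_update < 0.1) { converged <- TRUE; break }
  }
  mv <- mean_vol(aligned)
  if (!converged)
    warning("class-average alignment did not converge after ", max_rounds,
            " rounds; proceeding", call. = FALSE)
  list(aligned = aligned, mean = mv, shifts = shifts, angles = angles,
       rounds = rounds, converged = converged)
}

#' Eigenvolume decomposition of class averages
#'
#' Voxel-wise principal component analysis over a set of aligned class
#' averages, computed on the class-count-sized Gram matrix (the number of
#' classes is far below the voxel count). The first raw principal component
#' is conventionally trivial -- it tracks the overall density amplitude of
#' each class -- and is dropped, with the reported modes renumbered from
#' the second raw component; a diagnostic records the dropped component's
#' correlation with the per-class total intensity so its triviality can be
#' verified. Informativity is the variance along each mode divided by the
#' variance of mode 1 (and is therefore 1 for mode 1 and non-increasing).
#'
#' @param volumes List of >= 3 aligned `density_volume`s.
#' @param drop_first Drop the trivial first raw component (default `TRUE`).
#' @return An object of class `mode_decomposition`: `mean_volume`,
#'   `eigenvolumes` (list, mode order), `coefficients` (class x mode),
#'   `variances`, `informativity`, `trivial` (the dropped component:
#'   coefficients, variance, intensity correlation), `volumes` (the
#'   inputs), `n_classes`.
#' @export
eigenvolume_decompose <- function(volumes, drop_first = TRUE) {
  n <- length(volumes)
  if (n < 3) stop("need at least 3 volumes", call. = FALSE)
  vs <- volumes[[1]]$voxel_size
  dims <- dim(volumes[[1]]$data)
  X <- vapply(volumes, function(v) as.vector(v$data),
              numeric(prod(dims)))            # voxels x classes
  mu <- rowMeans(X)
  Xc <- X - mu
  G <- crossprod(Xc)                           # classes x classes
  if (max(abs(G)) < 1e-12 * prod(dims)) {
    warning("identical input volumes: zero variance, no modes",
            call. = FALSE)
    return(structure(list(
      mean_volume = density_volume(array(mu, dims), vs),
      eigenvolumes = list(), coefficients = matrix(0, n, 0),
      variances = numeric(0), informativity = numeric(0),
      trivial = NULL, volumes = volumes, n_classes = n),
      class = "mode_decomposition"))
  }
  e <- eigen(G, symmetric = TRUE)
  keep <- which(e$values > 1e-10 * max(e$values))
  U <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  # eigenvolumes (unit norm in voxel space) and coefficients
  V <- Xc %*% U %*% diag(1 / sqrt(lam), length(lam))
  coeff <- U %*% diag(sqrt(lam), length(lam))  # class x component
  variances <- lam / (n - 1)
  trivial <- NULL
  if (drop_first && length(lam) >= 1) {
    totals <- colSums(X)
    trivial <- list(coefficients = coeff[, 1], variance = variances[1],
                    intensity_correlation =
                      if (stats::sd(totals) > 0)
                        stats::cor(coeff[, 1], totals) else NA_real_)
    V <- V[, -1, drop = FALSE]
    coeff <- coeff[, -1, drop = FALSE]
    variances <- variances[-1]
  }
  informativity <- if (length(variances)) variances / variances[1]
  else numeric(0)
  eigenvolumes <- lapply(seq_len(ncol(V)), function(j)
    density_volume(array(V[, j], dims), vs))
  structure(list(mean_volume = density_volume(array(mu, dims), vs),
                 eigenvolumes = eigenvolumes, coefficients = coeff,
                 variances = variances, informativity = informativity,
                 trivial = trivial, volumes = volumes, n_classes = n),
            class = "mode_decomposition")
}

#' @export
print.mode_decomposition <- function(x, ...) {
  cat(sprintf("<mode_decomposition> %d classes, %d modes\n",
              x$n_classes, length(x$variances)))
  if (length(x$informativity))
    cat("  informativity:",
        paste(sprintf("%.0f%%", 100 * x$informativity), collapse = " "),
        "\n")
  if (!is.null(x$trivial) && is.finite(x$trivial$intensity_correlation))
    cat(sprintf(
      "  dropped trivial component: |cor| with total intensity %.2f\n",
      abs(x$trivial$intensity_correlation)))
  invisible(x)
}

#' Per-mode half-maps
#'
#' Splits the class averages into two equal-sized groups by their
#' eigencoefficients along one mode and averages each group, visualizing
#' the motion the mode encodes. With an odd class count the
#' median-coefficient volume is excluded to keep the groups equal.
#'
#' @param decomposition A `mode_decomposition`.
#' @param mode Mode index (1-based, after trivial-component removal).
#' @return `list(low, high)` of `density_volume`s.
#' @export
mode_halfmaps <- function(decomposition, mode = 1) {
  m <- length(decomposition$variances)
  if (mode < 1 || mode > m) stop("no such mode: ", mode, call. = FALSE)
  n <- decomposition$n_classes
  if (n < 4) stop("need at least 4 volumes for half-maps", call. = FALSE)
  co <- decomposition$coefficients[, mode]
  ord <- order(co)
  if (n %% 2 == 1) ord <- ord[-((n + 1) / 2)]
  half <- length(ord) / 2
  avg <- function(ix) {
    d <- Reduce(`+`, lapply(decomposition$volumes[ix], `[[`, "data")) /
      length(ix)
    density_volume(d, decomposition$volumes[[1]]$voxel_size)
  }
  list(low = avg(ord[seq_len(half)]), high = avg(ord[half + seq_len(half)]))
}

#' Spatial autocorrelation of mode eigencoefficients
#'
#' Moran's I of per-particle eigencoefficients over a k-nearest-neighbour
#' graph of tomogram positions, with a seeded permutation null and a
#' one-sided p-value: detects whether particles of similar conformation sit
#' near each other in the tomograms.
#'
#' @param coefficients Numeric vector, one eigencoefficient per particle.
#' @param positions n x 3 matrix of tomogram positions (Angstrom).
#' @param k Number of nearest neighbours (default 6).
#' @param n_perm Number of permutations for the null (default 999).
#' @param seed Integer seed.
#' @return `list(statistic, expected, p_value, null, degenerate)`.
#' @export
mode_spatial_correlation <- function(coefficients, positions, k = 6,
                                     n_perm = 999, seed = 1) {
  n <- length(coefficients)
  positions <- as.matrix(positions)
  if (n < 10) stop("need at least 10 positioned particles", call. = FALSE)
  stopifnot(nrow(positions) == n, ncol(positions) == 3)
  if (stats::sd(coefficients) == 0) {
    return(list(statistic = NA_real_, expected = -1 / (n - 1),
                p_value = NA_real_, null = numeric(0), degenerate = TRUE))
  }
  d2 <- as.matrix(stats::dist(positions))^2
  diag(d2) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(d2[i, ])[seq_len(k)]] <- 1
  moran <- function(z) {
    zc <- z - mean(z)
    (n / sum(W)) * sum(W * outer(zc, zc)) / sum(zc^2)
  }
  obs <- moran(coefficients)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(stage_seed(seed, "moran"))
  null <- vapply(seq_len(n_perm), function(i) moran(sample(coefficients)),
                 numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  list(statistic = obs, expected = -1 / (n - 1), p_value = p, null = null,
       degenerate = FALSE)
}
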