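#' Classification configuration
#'
#' @param band_limit Resolution band for classification scoring (Angstrom);
#'   22 is the package default for conformational classification.
#' @param symmetry Apply C4 symmetry to class references (logical).
#' @param max_iter Maximum assignment/averaging iterations.
#' @param converge_frac Stop when the fraction of particles changing class
#'   drops below this (default 1%).
#' @param jitter Phase-jitter SD (radians) used to seed the K references
#'   from the global average.
#' @param n_start Number of seeded restarts; the run with the best final
#'   objective (mean best-class correlation) is kept. Restarts share the
#'   particle preprocessing, so they are cheap.
#' @param weight_floor Per-voxel Fourier weight floor (relative).
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(band_limit = 22, symmetry = TRUE, max_iter = 10,
                            converge_frac = 0.01, jitter = 0.5,
                            n_start = 5, weight_floor = 1e-3) {
  structure(list(band_limit = band_limit, symmetry = symmetry,
                 max_iter = max_iter, converge_frac = converge_frac,
                 jitter = jitter, n_start = n_start,
                 weight_floor = weight_floor),
            class = "classify_config")
}

# Per-particle aligned Fourier subsets: each particle back-rotated to the
# reference frame, plus its rotated wedge on the same subset. Poses are
# taken from the records and stay fixed during classification.
particle_subsets <- function(particles, records, wedge, sub) {
  n <- length(particles)
  box <- box_size(particles[[1]])
  sh <- fftshift_idx(box)
  wedge_c <- if (!is.null(wedge)) wedge$mask[sh, sh, sh] else NULL
  q <- matrix(complex(1), length(sub$idx), n)
  m <- matrix(1, length(sub$idx), n)
  for (i in seq_len(n)) {
    pose <- c(records$tdrot[i], records$tilt[i], records$narot[i])
    shift <- c(records$dx[i], records$dy[i], records$dz[i])
    bt <- backtransform(particles[[i]], pose, shift)
    q[, i] <- fft3(bt$data)[sub$idx]
    if (!is.null(wedge_c)) {
      mrot <- rotate_mask_centered(wedge_c, euler_matrix(pose))
      m[, i] <- mrot[sh, sh, sh][sub$idx]
    }
  }
  list(q = q, m = m)
}

# C4-symmetrize a Fourier subset by embedding in the full cube (rotation
# about z commutes with the Fourier transform, so the exact 90-degree
# index permutation applies unchanged).
symmetrize_subset_c4 <- function(vals, sub) {
  box <- sub$box
  full <- array(complex(1), c(box, box, box))
  full[sub$idx] <- vals
  s <- (full + rot90_z_array(full, 1L) + rot90_z_array(full, 2L) +
          rot90_z_array(full, 3L)) / 4
  s[sub$idx]
}

subset_to_volume <- function(vals, sub, voxel_size, band_limit) {
  box <- sub$box
  full <- array(complex(1), c(box, box, box))
  full[sub$idx] <- vals
  full <- full * band_filter(box, voxel_size, high_res = band_limit)
  density_volume(Re(ifft3(full)), voxel_size)
}

#' Multireference classification
#'
#' Classifies particles into `K` classes by alternating
#' assignment-by-best-constrained-correlation with per-class weighted
#' averaging at the configured band limit. The `K` references are seeded by
#' random phase jitter of the global average (seeded, so the run is
#' deterministic); particle poses are taken from the records and kept
#' fixed. A class that empties mid-run is reseeded once from the
#' worst-scoring members of the largest class, then allowed to die.
#' Iteration stops when fewer than `converge_frac` of the particles change
#' class or after `max_iter` rounds. `config$n_start` independent seeded
#' restarts are run and the solution with the best objective kept, which
#' protects against starts where two references collapse onto one class.
#'
#' @param particles List of `density_volume`s.
#' @param records A `particle_set` with the particles' poses.
#' @param K Number of classes (`2 <= K <= n/2`); `K = 1` reproduces the
#'   plain weighted average.
#' @param wedge The shared `wedge_mask` (or `NULL`).
#' @param config A [classify_config()].
#' @param seed Integer seed for reference seeding.
#' @return An object of class `classification_result`: `assignments`
#'   (integer vector named by particle id), `class_averages` (list of
#'   `density_volume`), `counts`, `occupancies`, `cc` (per-particle best
#'   score), `objective_trace`, `n_iter`, `converged`, `retained`,
#'   `excluded`.
#' @export
multireference_classify <- function(particles, records, K, wedge = NULL,
                                    config = classify_config(), seed = 1) {
  n <- length(particles)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > 1 && K > n / 2) stop("K must be at most n/2", call. = FALSE)
  vs <- particles[[1]]$voxel_size
  sub <- band_subset(box_size(particles[[1]]), vs, config$band_limit)
  ps <- particle_subsets(particles, records, wedge, sub)
  w <- pmax(records$cc, 0); w[is.na(w)] <- 1
  class_avg <- function(sel) {
    num <- (ps$m * ps$q)[, sel, drop = FALSE] %*% w[sel]
    den <- ps$m[, sel, drop = FALSE] %*% w[sel]
    eps <- config$weight_floor * max(den)
    v <- num * den / (den^2 + eps^2)   # same compensation as weighted_average
    if (config$symmetry) v <- symmetrize_subset_c4(v, sub)
    v
  }
  global <- class_avg(seq_len(n))
  if (K == 1L) {
    refs <- matrix(global, ncol = 1)
    assign_new <- rep(1L, n)
    cc_best <- rep(NA_real_, n)
    trace <- numeric(0)
    n_iter <- 0L
    converged <- TRUE
  } else {
    qn <- sqrt(colSums(ps$m * Mod(ps$q)^2))
    one_run <- function(run_seed) {
      set.seed(run_seed)
      refs <- vapply(seq_len(K), function(k)
        global * exp(1i * stats::rnorm(length(global), 0, config$jitter)),
        complex(length(global)))
      assign_cur <- rep(0L, n)
      assign_new <- rep(1L, n)
      cc_best <- rep(NA_real_, n)
      reseeded <- logical(K)
      trace <- numeric(0)
      converged <- FALSE
      n_iter <- 0L
      for (it in seq_len(config$max_iter)) {
        n_iter <- it
        # scores: n x K constrained correlations
        sc <- matrix(0, n, K)
        for (k in seq_len(K)) {
          rk <- Conj(refs[, k])          # recycles down the columns
          num <- colSums(ps$m * Re(ps$q * rk))
          rn <- sqrt(colSums(ps$m * Mod(rk)^2))
          sc[, k] <- num / (qn * rn)
        }
        assign_new <- max.col(sc, ties.method = "first")
        cc_best <- sc[cbind(seq_len(n), assign_new)]
        trace <- c(trace, mean(cc_best))
        # reseed an emptied or collapsed class once from the largest
        # class's worst members, then allow it to die
        counts_it <- tabulate(assign_new, K)
        dup <- logical(K)
        if (it > 1) {
          for (k1 in seq_len(K - 1)) for (k2 in (k1 + 1):K) {
            r1 <- refs[, k1]; r2 <- refs[, k2]
            cc12 <- Re(sum(r1 * Conj(r2))) /
              sqrt(sum(Mod(r1)^2) * sum(Mod(r2)^2))
            if (is.finite(cc12) && cc12 > 0.995) {
              weaker <- if (counts_it[k1] <= counts_it[k2]) k1 else k2
              dup[weaker] <- TRUE
            }
          }
        }
        for (k in seq_len(K)) {
          if ((counts_it[k] == 0L || dup[k]) && !reseeded[k]) {
            big <- which.max(tabulate(assign_new, K))
            if (big == k) next
            members <- which(assign_new == big)
            worst <- members[order(cc_best[members])]
            take <- worst[seq_len(max(1L, length(worst) %/% 10L))]
            assign_new[take] <- k
            reseeded[k] <- TRUE
          }
        }
        changed <- mean(assign_new != assign_cur)
        assign_cur <- assign_new
        for (k in seq_len(K)) {
          selk <- which(assign_new == k)
          if (length(selk)) refs[, k] <- class_avg(selk)
        }
        if (changed < config$converge_frac) { converged <- TRUE; break }
      }
      list(refs = refs, assign = assign_new, cc_best = cc_best,
           trace = trace, n_iter = n_iter, converged = converged,
           objective = mean(cc_best))
    }
    # split-and-merge refinement: merge the most similar pair of
    # references and split the largest class in two, keep if the
    # objective improves (rescues runs where two planted classes
    # collapsed into one while another was split by noise)
    score_against <- function(refs) {
      sc <- matrix(0, n, ncol(refs))
      for (k in seq_len(ncol(refs))) {
        rk <- Conj(refs[, k])
        num <- colSums(ps$m * Re(ps$q * rk))
        rn <- sqrt(colSums(ps$m * Mod(rk)^2))
        sc[, k] <- num / (qn * rn)
      }
      sc
    }
    iterate_from <- function(refs, rounds) {
      assign_cur <- rep(0L, n)
      cc_best <- rep(NA_real_, n)
      for (it in seq_len(rounds)) {
        sc <- score_against(refs)
        assign_new <- max.col(sc, ties.method = "first")
        cc_best <- sc[cbind(seq_len(n), assign_new)]
        changed <- mean(assign_new != assign_cur)
        assign_cur <- assign_new
        for (k in seq_len(K)) {
          selk <- which(assign_new == k)
          if (length(selk)) refs[, k] <- class_avg(selk)
        }
        if (changed < config$converge_frac) break
      }
      list(refs = refs, assign = assign_cur, cc_best = cc_best,
           objective = mean(cc_best))
    }
    split_merge <- function(run, attempt_seed) {
      counts <- tabulate(run$assign, K)
      if (any(counts == 0L)) return(run)
      sim_best <- -Inf; pair <- c(1L, 2L)
      for (k1 in seq_len(K - 1)) for (k2 in (k1 + 1):K) {
        r1 <- run$refs[, k1]; r2 <- run$refs[, k2]
        s <- Re(sum(r1 * Conj(r2))) /
          sqrt(sum(Mod(r1)^2) * sum(Mod(r2)^2))
        if (s > sim_best) { sim_best <- s; pair <- c(k1, k2) }
      }
      big <- which.max(counts)
      if (big %in% pair) return(run)
      refs <- run$refs
      # merge the similar pair into its first member ...
      merged_members <- which(run$assign %in% pair)
      refs[, pair[1]] <- class_avg(merged_members)
      # ... and split the largest class along its own internal structure:
      # a local two-class run restricted to its members
      set.seed(attempt_seed)
      members <- which(run$assign == big)
      r2 <- vapply(1:2, function(k)
        refs[, big] * exp(1i * stats::rnorm(nrow(refs), 0,
                                            config$jitter)),
        complex(nrow(refs)))
      for (it in 1:5) {
        scl <- matrix(0, length(members), 2)
        for (k in 1:2) {
          rk <- Conj(r2[, k])
          num <- colSums(ps$m[, members, drop = FALSE] *
                           Re(ps$q[, members, drop = FALSE] * rk))
          rn <- sqrt(colSums(ps$m[, members, drop = FALSE] * Mod(rk)^2))
          scl[, k] <- num / (qn[members] * rn)
        }
        al <- max.col(scl, ties.method = "first")
        for (k in 1:2) {
          selk <- members[al == k]
          if (length(selk)) r2[, k] <- class_avg(selk)
        }
      }
      refs[, big] <- r2[, 1]
      refs[, pair[2]] <- r2[, 2]
      out <- iterate_from(refs, config$max_iter)
      if (out$objective > run$objective) {
        out$trace <- c(run$trace, out$objective)
        out$n_iter <- run$n_iter
        out$converged <- run$converged
        out
      } else run
    }
    old <- get0(".Random.seed", envir = globalenv())
    best <- NULL
    for (r in seq_len(max(1L, config$n_start))) {
      run <- one_run(stage_seed(seed, paste0("classify", r)))
      run <- split_merge(run, stage_seed(seed, paste0("splitmerge", r)))
      if (is.null(best) || run$objective > best$objective) best <- run
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    refs <- best$refs
    assign_new <- best$assign
    cc_best <- best$cc_best
    trace <- c(best$trace, best$objective)
    n_iter <- best$n_iter
    converged <- best$converged
  }
  counts <- tabulate(assign_new, nbins = K)
  averages <- lapply(seq_len(K), function(k)
    subset_to_volume(refs[, k], sub, vs, config$band_limit))
  names(assign_new) <- records$id
  structure(list(assignments = assign_new, class_averages = averages,
                 counts = counts, occupancies = counts / n, cc = cc_best,
                 objective_trace = trace, n_iter = n_iter,
                 converged = converged,
                 retained = seq_len(K), excluded = integer(0),
                 excluded_reasons = character(0)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %d particles in %d classes (%s)\n",
              length(x$assignments), length(x$counts),
              if (x$converged) sprintf("converged, %d iterations", x$n_iter)
              else "not converged"))
  print(occupancy_table(x))
  invisible(x)
}

#' Prune low-abundance or flagged classes
#'
#' Moves classes whose occupancy is strictly below `min_fraction`, or whose
#' id is in `exclude` (the manual artifact list, e.g. classes dominated by
#' gold beads), to the excluded set. Occupancies over retained + excluded
#' classes still sum to 1; `n_retained_particles` counts the survivors.
#'
#' @param result A `classification_result`.
#' @param min_fraction Minimum occupancy to retain (strict less-than
#'   pruning: a class at exactly `min_fraction` is retained).
#' @param exclude Integer vector of class ids to exclude manually.
#' @return The updated `classification_result`.
#' @export
prune_classes <- function(result, min_fraction = 0.01, exclude = integer(0)) {
  K <- length(result$counts)
  low <- which(result$occupancies < min_fraction)
  excl <- sort(union(low, intersect(exclude, seq_len(K))))
  if (length(excl) == K) stop("all classes pruned: empty result",
                              call. = FALSE)
  reasons <- ifelse(excl %in% low, "low abundance", "flagged")
  result$retained <- setdiff(seq_len(K), excl)
  result$excluded <- excl
  result$excluded_reasons <- reasons
  result$n_retained_particles <-
    sum(result$assignments %in% result$retained)
  result
}

#' Class occupancy table
#'
#' @param result A `classification_result`.
#' @return A data frame with columns `class`, `count`, `fraction`,
#'   `retained`, sorted by descending count; fractions sum to 1.
#' @export
occupancy_table <- function(result) {
  K <- length(result$counts)
  df <- data.frame(class = seq_len(K), count = result$counts,
                   fraction = result$counts / sum(result$counts),
                   retained = seq_len(K) %in% result$retained)
  df[order(-df$count, df$class), , drop = FALSE]
}
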