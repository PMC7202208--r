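test_that("class-average alignment recovers planted shifts", {
  base <- make_phantom(spec32())
  shifted <- rotate_shift(base, c(0, 0, 0), c(2 * 10.8, -10.8, 0))
  al <- align_class_averages(list(base, base, shifted))
  rel <- al$shifts[3, ] - al$shifts[1, ]
  expect_lt(max(abs(rel - c(-21.6, 10.8, 0))), 0.5 * 10.8)
  expect_true(al$converged)
  # already-aligned identical volumes: no pose updates
  al0 <- align_class_averages(list(base, base, base))
  expect_lt(max(abs(al0$shifts)), 1e-6)
  expect_true(all(al0$angles == 0))
  # common average invariant to input ordering
  al2 <- align_class_averages(list(shifted, base, base))
  expect_equal(al2$mean$data, al$mean$data, tolerance = 0.02 * max(base$data))
  expect_error(align_class_averages(list(base, base)), "at least 3")
})

test_that("eigenvolume PCA recovers a planted variance ratio", {
  set.seed(42)
  n <- 12; N <- 32; vs <- 10.8
  base <- make_phantom(spec32())
  nb <- sqrt(sum(base$data^2))
  v1 <- c4_bump(N, vs, c(60, 0, 40), list(base$data))
  v2 <- c4_bump(N, vs, c(0, 70, -60), list(base$data, v1))
  amp <- rnorm(n); a <- rnorm(n); b <- rnorm(n)
  # sample-orthogonal coefficients make the planted ratio exact
  a <- sample_orth(a, list(amp)); b <- sample_orth(b, list(amp, a))
  a <- a / sd(a) * 30; b <- b / sd(b) * 20
  amp <- 1 + amp / sd(amp) * (300 / nb)   # dominant trivial amplitude mode
  vols <- lapply(seq_len(n), function(i)
    density_volume(amp[i] * base$data + a[i] * v1 + b[i] * v2, vs))
  dec <- eigenvolume_decompose(vols)
  expect_equal(dec$informativity[1], 1)
  expect_true(all(diff(dec$informativity) <= 1e-12))
  expect_lt(abs(dec$informativity[2] - (20 / 30)^2) / (20 / 30)^2, 0.10)
  # the dropped component is flagged as the amplitude mode
  expect_gt(abs(dec$trivial$intensity_correlation), 0.9)
  # eigencoefficient columns are mutually orthogonal
  cp <- crossprod(dec$coefficients)
  off <- cp - diag(diag(cp))
  expect_lt(max(abs(off)) / max(diag(cp)), 1e-6)
})

test_that("all retained components reconstruct the inputs", {
  set.seed(7)
  base <- make_phantom(spec32())
  vols <- lapply(1:5, function(i) density_volume(
    base$data * (1 + 0.1 * i) +
      array(rnorm(32^3, 0, 0.05), rep(32, 3)), 10.8))
  dec <- eigenvolume_decompose(vols, drop_first = FALSE)
  for (i in c(1, 4)) {
    rec <- dec$mean_volume$data
    for (j in seq_along(dec$variances))
      rec <- rec + dec$coefficients[i, j] * dec$eigenvolumes[[j]]$data
    expect_lt(max(abs(rec - vols[[i]]$data)) / max(abs(vols[[i]]$data)),
              1e-4)
  }
  # eigenvalues are non-negative and non-increasing
  expect_true(all(dec$variances >= 0))
  expect_true(all(diff(dec$variances) <= 1e-12))
})

test_that("identical inputs yield a zero-variance diagnostic", {
  base <- make_phantom(spec32())
  expect_warning(dec <- eigenvolume_decompose(list(base, base, base)),
                 "zero variance")
  expect_length(dec$variances, 0)
})

test_that("mode half-maps split classes by eigencoefficient", {
  set.seed(9)
  N <- 32; vs <- 10.8
  sp <- spec32()
  base <- make_phantom(sp)
  # two planted clusters differing in peripheral-domain scale
  m1 <- tomosta:::class_phantom(sp, list())
  m2 <- tomosta:::class_phantom(sp, list(radial_scale = 0.8))
  es <- ensemble_spec(4, occupancies = c(0.5, 0.5),
                      deformations = list(list(),
                                          list(radial_scale = 0.8)))
  dmask <- deformation_mask(es, sp)
  vols <- lapply(1:10, function(i) {
    src <- if (i <= 5) m1 else m2
    density_volume(src$data + array(rnorm(N^3, 0, 0.02), rep(N, 3)), vs)
  })
  dec <- eigenvolume_decompose(vols, drop_first = FALSE)
  hm <- mode_halfmaps(dec, 1)
  d <- (hm$low$data - hm$high$data)^2
  # difference power concentrated in the planted deformation region
  expect_gt(sum(d[dmask]) / sum(d), 0.70)
  # the mode separates the clusters
  cl <- dec$coefficients[, 1] > median(dec$coefficients[, 1])
  truth <- rep(c(FALSE, TRUE), each = 5)
  expect_gte(max(mean(cl == truth), mean(cl != truth)), 0.95)
  # identical volumes: equal half-maps
  same <- lapply(1:4, function(i) base)
  suppressWarnings(dec0 <- eigenvolume_decompose(same, drop_first = FALSE))
  # negating an eigenvector swaps the groups
  dec_neg <- dec
  dec_neg$coefficients[, 1] <- -dec$coefficients[, 1]
  hm2 <- mode_halfmaps(dec_neg, 1)
  expect_equal(hm$low$data, hm2$high$data, tolerance = 1e-12)
  expect_equal(hm$high$data, hm2$low$data, tolerance = 1e-12)
  # odd count: the median volume is excluded, groups stay equal
  dec_odd <- eigenvolume_decompose(vols[1:9], drop_first = FALSE)
  expect_no_error(mode_halfmaps(dec_odd, 1))
})

test_that("spatial autocorrelation calibrates under its permutation null", {
  set.seed(13)
  n <- 40
  pos <- matrix(runif(3 * n, 0, 1e4), n, 3)
  co <- rnorm(n)
  hits <- 0L
  for (s in 1:25) {
    perm <- sample(co)
    r <- mode_spatial_correlation(perm, pos, k = 5, n_perm = 199, seed = s)
    if (r$p_value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.8)
  # perfectly clustered layout: two spatial blocks, two coefficient signs
  pos2 <- rbind(matrix(runif(60, 0, 1e3), 20, 3),
                matrix(runif(60, 9e3, 1e4), 20, 3))
  co2 <- rep(c(-1, 1), each = 20) + rnorm(40, 0, 0.1)
  r2 <- mode_spatial_correlation(co2, pos2, k = 5, n_perm = 499, seed = 1)
  expect_lt(r2$p_value, 0.01)
  expect_gt(r2$statistic, r2$expected)
  # degenerate constant coefficients are flagged, tiny sets are errors
  r3 <- mode_spatial_correlation(rep(1, 12), pos[1:12, ])
  expect_true(r3$degenerate)
  expect_error(mode_spatial_correlation(co[1:5], pos[1:5, ]), "at least 10")
})
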