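test_that("spherical resampling maps an on-sphere membrane to a sheet", {
  sp <- phantom_spec(membrane_R = 50)
  mem <- make_membrane_patch(sp)
  g <- spherical_resample(mem, 50, membrane_z = sp$membrane_z)
  sc <- flatness_score(g)
  cent <- attr(sc, "centroids")
  valid <- attr(sc, "valid")
  # membrane confined to <= 2 radial bins (bins are half a voxel wide)
  expect_lt(max(cent[valid]) - min(cent[valid]), 2)
  # a constant volume resamples to a constant
  const <- density_volume(array(3, rep(32, 3)), 10.8)
  gc <- suppressWarnings(spherical_resample(const, 50, 0))
  vals <- gc$values[!is.na(gc$values)]
  expect_lt(diff(range(vals)), 1e-9)
  # and raises a detection error (no membrane peak anywhere)
  expect_error(flatness_score(gc), "detectable")
})

test_that("a flat membrane maps to the closed-form sagitta profile", {
  sp <- phantom_spec(membrane_R = "flat")
  mem <- make_membrane_patch(sp)
  R <- 50
  g <- spherical_resample(mem, R, membrane_z = sp$membrane_z)
  sc <- flatness_score(g)
  cent <- attr(sc, "centroids"); valid <- attr(sc, "valid")
  # flat membrane at height zm seen from origin at zm - R: radial position
  # of the membrane along polar angle theta is R / cos(theta)
  expected_vox <- (R * 10 / cos(g$theta)) / sp$voxel_size
  err <- abs(cent[valid] - expected_vox[valid])
  expect_lt(stats::median(err), 1)
})

test_that("flatness score is minimized at the true radius", {
  sp <- phantom_spec(membrane_R = 50)
  ph <- make_phantom(sp)
  s_true <- as.numeric(flatness_score(
    spherical_resample(ph, 50, sp$membrane_z)))
  s_half <- as.numeric(flatness_score(
    spherical_resample(ph, 25, sp$membrane_z)))
  s_p20 <- as.numeric(flatness_score(
    spherical_resample(ph, 60, sp$membrane_z)))
  s_m20 <- as.numeric(flatness_score(
    spherical_resample(ph, 40, sp$membrane_z)))
  expect_lt(s_true, s_half)
  expect_lt(s_true, s_p20)
  expect_lt(s_true, s_m20)
})

test_that("membrane radius is recovered within 10% over the study range", {
  for (R0 in c(35, 55, 100)) {
    sp <- phantom_spec(membrane_R = R0)
    fit <- suppressWarnings(
      fit_membrane_radius(make_phantom(sp), membrane_z = sp$membrane_z))
    expect_lt(abs(fit$R - R0) / R0, 0.10)
    expect_equal(fit$curvature, 1 / fit$R)
    expect_true(all(c("R", "score") %in% names(fit$profile)))
  }
  # flat phantom: the flat sentinel wins and curvature is zero
  spf <- phantom_spec(membrane_R = "flat")
  fitf <- suppressWarnings(
    fit_membrane_radius(make_phantom(spf), membrane_z = spf$membrane_z))
  expect_identical(fitf$curvature, 0)
  expect_identical(fitf$R, Inf)
})

test_that("curvature estimate survives noise and in-plane rotation", {
  sp <- phantom_spec(membrane_R = 50, snr = 1)
  ph <- make_phantom(sp)
  noisy <- render_particle(ph, wedge = NULL, snr = 1, scheme = NULL,
                           seed = 3)$volume
  # average-map stand-in: mild smoothing via the 36 A band
  avg <- bandpass(noisy, high_res = 36)
  fit <- suppressWarnings(
    fit_membrane_radius(avg, membrane_z = sp$membrane_z))
  expect_lt(abs(fit$R - 50) / 50, 0.10)
  rot <- rotate_shift(avg, c(0, 0, 35))
  fit_rot <- suppressWarnings(
    fit_membrane_radius(rot, membrane_z = sp$membrane_z))
  expect_lt(abs(fit_rot$R - fit$R) / fit$R, 0.05)
})

test_that("membrane patches classify into concave, flat and convex", {
  mkp <- function(R) make_membrane_patch(
    phantom_spec(membrane_R = R, membrane_z = 0))
  conc <- mkp(50)
  flat <- mkp("flat")
  conv <- tomosta:::flip_z(conc)   # mirror through the membrane plane
  res <- suppressWarnings(
    classify_membrane_patches(list(conc, flat, conv), membrane_z = 0))
  expect_identical(as.character(res$patches$category),
                   c("concave", "near-flat", "convex"))
  # sign flips under mirroring, magnitudes agree
  expect_gt(res$patches$curvature[1], 0)
  expect_lt(res$patches$curvature[3], 0)
  expect_equal(res$patches$curvature[1], -res$patches$curvature[3],
               tolerance = 0.10 * res$patches$curvature[1])
  expect_equal(as.numeric(res$fractions), c(1, 1, 1) / 3)
  # an all-flat set is 100% near-flat
  res_f <- suppressWarnings(
    classify_membrane_patches(list(flat, flat), membrane_z = 0))
  expect_equal(as.numeric(res_f$fractions["near-flat"]), 1)
})
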