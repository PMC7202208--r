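test_that("constrained correlation removes missing-wedge bias", {
  ph <- make_phantom(spec32())
  expect_equal(constrained_cc(ph, ph), 1, tolerance = 1e-12)
  neg <- density_volume(-ph$data, ph$voxel_size)
  expect_equal(constrained_cc(ph, neg), -1, tolerance = 1e-12)
  # wedge-filtered phantom vs the unfiltered phantom: restricting the
  # normalization to the wedge region recovers a perfect score
  hard <- wedge_mask(32, softness = 0)
  pw <- apply_wedge(ph, hard)
  expect_equal(constrained_cc(pw, ph, hard, 36), 1, tolerance = 1e-3)
  # while the unconstrained score is visibly biased down
  expect_lt(constrained_cc(pw, ph, NULL, 36), 0.9)
  z <- density_volume(array(0, rep(32, 3)), 10.8)
  expect_error(constrained_cc(z, z), "undefined")
})

test_that("a reference aligns to itself at the identity pose", {
  ph <- make_phantom(spec32())
  rec <- particle_set(data.frame(
    id = 1L, x = 0, y = 0, z = 0, tdrot = 0, tilt = 0, narot = 0,
    dx = 0, dy = 0, dz = 0, cc = NA_real_, class = 0L,
    halfset = NA_character_))
  cfg <- align_config(cone_range = 8, cone_step = 8, inplane_step = 15,
                      band_limit = 36, shift_limit = 20)
  out <- align_particles(list(ph), rec, ph, NULL, cfg)
  expect_equal(geodesic_angle(c(out$tdrot, out$tilt, out$narot),
                              c(0, 0, 0), "C4"), 0, tolerance = 1e-6)
  expect_lt(sqrt(out$dx^2 + out$dy^2 + out$dz^2), 1e-6)
  expect_equal(out$cc, 1, tolerance = 1e-9)
  expect_false(out$boundary)
})

test_that("alignment recovers planted poses and canonicalizes in-plane", {
  sp <- spec32(snr = 10)
  ph <- make_phantom(sp)
  w <- wedge_mask(32)
  es <- ensemble_spec(10, tilt_spread = 8, shift_sd = 5, seed = 3)
  sim <- simulate_ensemble(es, sp, w)
  cfg <- align_config(cone_range = 16, cone_step = 8, inplane_step = 8,
                      band_limit = 36, shift_limit = 20)
  rec <- align_particles(sim$particles, sim$records, ph, w, cfg)
  errs <- vapply(seq_len(10), function(i) geodesic_angle(
    c(rec$tdrot[i], rec$tilt[i], rec$narot[i]),
    c(sim$truth$tdrot[i], sim$truth$tilt[i], sim$truth$narot[i]), "C4"),
    numeric(1))
  expect_lt(median(errs), 8)
  # C4 canonical sector for the reported in-plane angle
  expect_true(all(rec$narot >= 0 & rec$narot < 90))
  # shifts recovered within ~1 voxel at this band limit
  sh_err <- sqrt((rec$dx - sim$truth$dx)^2 + (rec$dy - sim$truth$dy)^2 +
                   (rec$dz - sim$truth$dz)^2)
  expect_lt(median(sh_err), 1.5 * sp$voxel_size)
})

test_that("weighted average: clamped weights and copy identity", {
  ph <- make_phantom(spec32())
  hard <- wedge_mask(32, softness = 0)
  pose <- c(20, 10, 30)
  p <- apply_wedge(rotate_shift(ph, pose), hard)
  mk_rec <- function(cc) particle_set(data.frame(
    id = seq_along(cc), x = 0, y = 0, z = 0,
    tdrot = pose[1], tilt = pose[2], narot = pose[3],
    dx = 0, dy = 0, dz = 0, cc = cc, class = 0L,
    halfset = NA_character_))
  cfg <- align_config(symmetry = FALSE, band_limit = NULL)
  # identical copies with equal scores give the single-copy average
  a1 <- weighted_average(list(p), mk_rec(0.8), hard, cfg)
  a3 <- weighted_average(list(p, p, p), mk_rec(rep(0.8, 3)), hard, cfg)
  expect_equal(a3$data, a1$data, tolerance = 1e-9)
  # and reproduce the aligned particle on its sampled region
  bt <- backtransform(p, pose)
  expect_gt(cor(as.vector(a3$data), as.vector(bt$data)), 0.95)
  # a non-positive score excludes the particle entirely
  junk <- density_volume(array(rnorm(32^3), rep(32, 3)), 10.8)
  a_with <- weighted_average(list(p, p, junk), mk_rec(c(0.8, 0.8, -0.2)),
                             hard, cfg)
  expect_equal(a_with$data, a3$data, tolerance = 1e-9)
  expect_error(weighted_average(list(p), mk_rec(-1), hard, cfg), "weight")
})

test_that("averaging beats single particles and improves with n", {
  sp <- spec48(snr = 0.5)
  ph <- make_phantom(sp)
  w <- wedge_mask(48)
  es <- ensemble_spec(30, tilt_spread = 8, shift_sd = 5, seed = 4)
  sim <- simulate_ensemble(es, sp, w)
  cfg <- align_config(cone_range = 16, cone_step = 8, inplane_step = 10,
                      band_limit = 36, shift_limit = 15)
  rec <- align_particles(sim$particles, sim$records, ph, w, cfg)
  score <- function(ix) {
    avg <- weighted_average(sim$particles[ix], rec[ix, ], w, cfg,
                            sp$tilt_scheme)
    constrained_cc(avg, ph, NULL, 36)
  }
  cc10 <- score(1:10); cc30 <- score(1:30)
  singles <- vapply(1:10, function(i) {
    bt <- backtransform(sim$particles[[i]],
                        c(rec$tdrot[i], rec$tilt[i], rec$narot[i]),
                        c(rec$dx[i], rec$dy[i], rec$dz[i]))
    constrained_cc(bt, ph, NULL, 36)
  }, numeric(1))
  expect_gt(cc10, max(singles))
  expect_gt(cc30, cc10)
})

test_that("alignment is equivariant under a global rotation", {
  # rotating all particles by a fixed in-plane rotation leaves the
  # C4-symmetrized average unchanged within interpolation tolerance
  sp <- spec32(snr = 1e6)
  ph <- make_phantom(sp)
  w <- wedge_mask(32)
  es <- ensemble_spec(6, tilt_spread = 5, shift_sd = 3, seed = 8)
  sim <- simulate_ensemble(es, sp, w)
  cfg <- align_config(cone_range = 8, cone_step = 8, inplane_step = 10,
                      band_limit = 36, shift_limit = 15)
  rec1 <- align_particles(sim$particles, sim$records, ph, w, cfg)
  avg1 <- weighted_average(sim$particles, rec1, w, cfg)
  rot_particles <- lapply(sim$particles, rotate_shift, pose = c(0, 0, 40))
  rec2 <- align_particles(rot_particles, sim$records, ph, w, cfg)
  avg2 <- weighted_average(rot_particles, rec2, w, cfg)
  expect_gt(cor(as.vector(avg1$data), as.vector(avg2$data)), 0.95)
})

test_that("complementary wedges combine into union Fourier coverage", {
  ph <- make_phantom(spec32())
  wa <- wedge_mask(32, -60, 60, softness = 0)
  wb_mask <- wedge_mask(32, -60, 60, softness = 0)
  # second particle rotated 90 deg in-plane: its wedge covers the
  # complementary x-z directions in the reference frame
  pa <- apply_wedge(ph, wa)
  pb <- apply_wedge(rotate_shift(ph, c(0, 0, 90)), wb_mask)
  rec <- particle_set(data.frame(
    id = 1:2, x = 0, y = 0, z = 0, tdrot = 0, tilt = 0,
    narot = c(0, 90), dx = 0, dy = 0, dz = 0, cc = c(0.9, 0.9),
    class = 0L, halfset = NA_character_))
  cfg <- align_config(symmetry = FALSE, band_limit = NULL)
  avg <- weighted_average(list(pa, pb), rec, wa, cfg)
  f_avg <- Mod(fft(avg$data))
  f_ph <- Mod(fft(ph$data))
  m_union <- pmax(wa$mask, tomosta:::rot90_z_array(wa$mask, 1))
  strong <- f_ph > stats::quantile(f_ph, 0.98)
  covered <- m_union > 0.5
  # amplitudes recovered over the union, including each lone wedge's part
  expect_gt(cor(f_avg[strong & covered], f_ph[strong & covered]), 0.9)
  only_b <- covered & wa$mask < 0.5
  expect_gt(sum(f_avg[strong & only_b]) / sum(f_ph[strong & only_b]), 0.5)
})

test_that("half-set refinement takes the documented branches", {
  sp <- spec32(snr = 1)
  ph <- make_phantom(sp)
  w <- wedge_mask(32)
  es <- ensemble_spec(12, tilt_spread = 5, shift_sd = 4, seed = 6)
  sim <- simulate_ensemble(es, sp, w)
  cfg <- align_config(cone_range = 8, cone_step = 8, inplane_step = 15,
                      band_limit = 36, iterations = 1)
  hr <- halfset_refine(sim$particles, sim$records, ph, w, cfg,
                       sp$tilt_scheme)
  expect_s3_class(hr, "sta_refine")
  expect_identical(hr$branch, "small")
  expect_identical(hr$resolution, 36)
  expect_null(hr$fsc)
  # the small-set map carries no power beyond the 36 A restriction
  f <- Mod(fft(hr$map$data))^2
  beyond <- tomosta:::freq_grids(32)$r > 32 * 10.8 / 36
  expect_lt(sum(f[beyond]) / sum(f), 0.01)
  # half-set labels persist and are never swapped
  expect_identical(hr$records$halfset, sim$records$halfset)
})

test_that("identical noise-free half-sets give FSC 1 at Nyquist", {
  # the >500 branch measured on its own machinery: two identical half-maps
  v <- make_phantom(spec32())
  f <- fsc_curve(v, v)
  expect_true(all(f$fsc > 0.999))
  expect_equal(resolution_at_threshold(f, 0.143), 2 * v$voxel_size)
})
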