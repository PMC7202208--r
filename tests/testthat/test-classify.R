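# planted two-class ensemble shared across the classification tests
two_class_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- spec32(snr = 0.5)
      es <- ensemble_spec(
        60, occupancies = c(0.5, 0.5),
        deformations = list(list(radial_scale = 1),
                            list(radial_scale = 0.78)),
        tilt_spread = 8, shift_sd = 5, seed = 11)
      cache <<- c(simulate_ensemble(es, sp, wedge_mask(32)), list(sp = sp))
    }
    cache
  }
})

test_that("two planted classes are recovered almost perfectly", {
  sim <- two_class_sim()
  res <- multireference_classify(sim$particles, sim$truth, 2, sim$wedge,
                                 classify_config(band_limit = 24), seed = 5)
  tab <- table(res$assignments, sim$truth$class)
  acc <- max(sum(diag(tab)), sum(tab[1, 2] + tab[2, 1])) / sum(tab)
  expect_gte(acc, 0.95)
  expect_true(res$converged)
  # objective (mean best score) is non-decreasing over iterations
  expect_true(all(diff(res$objective_trace) > -1e-8))
  # occupancies sum to one and match counts
  expect_equal(sum(res$occupancies), 1)
  expect_equal(res$counts, as.vector(table(res$assignments)))
})

test_that("classification is deterministic given its seed", {
  sim <- two_class_sim()
  r1 <- multireference_classify(sim$particles, sim$truth, 2, sim$wedge,
                                classify_config(band_limit = 24), seed = 9)
  r2 <- multireference_classify(sim$particles, sim$truth, 2, sim$wedge,
                                classify_config(band_limit = 24), seed = 9)
  expect_identical(r1$assignments, r2$assignments)
  expect_equal(r1$class_averages[[1]]$data, r2$class_averages[[1]]$data)
})

test_that("K = 1 reproduces the plain weighted average", {
  sim <- two_class_sim()
  ix <- 1:20
  res <- multireference_classify(sim$particles[ix], sim$truth[ix, ], 1,
                                 sim$wedge,
                                 classify_config(band_limit = 24))
  cfg <- align_config(band_limit = 24, symmetry = TRUE)
  wa <- weighted_average(sim$particles[ix], sim$truth[ix, ], sim$wedge, cfg)
  expect_equal(res$class_averages[[1]]$data, wa$data, tolerance = 1e-9)
})

test_that("class pruning follows the strict-less-than rule", {
  res <- structure(list(
    assignments = setNames(rep(1:4, c(50, 30, 15, 5)), 1:100),
    counts = c(50L, 30L, 15L, 5L),
    occupancies = c(0.50, 0.30, 0.15, 0.05),
    class_averages = vector("list", 4),
    retained = 1:4, excluded = integer(0)), class = "classification_result")
  # min_fraction exactly at a class's occupancy retains it
  p1 <- prune_classes(res, min_fraction = 0.05)
  expect_identical(p1$retained, 1:4)
  p2 <- prune_classes(res, min_fraction = 0.10)
  expect_identical(p2$excluded, 4L)
  expect_identical(p2$n_retained_particles, 95L)
  # manual artifact flag, e.g. a gold-bead class
  p3 <- prune_classes(res, min_fraction = 0, exclude = 2L)
  expect_identical(p3$excluded, 2L)
  expect_identical(p3$excluded_reasons, "flagged")
  # identity when nothing is pruned
  p0 <- prune_classes(res, min_fraction = 0)
  expect_identical(p0$retained, 1:4)
  expect_error(prune_classes(res, min_fraction = 0.9), "all classes")
})

test_that("occupancy table re-derives printed fractions exactly", {
  res <- structure(list(
    counts = c(45L, 27L, 19L, 10L), retained = 1:4,
    assignments = setNames(rep(1:4, c(45, 27, 19, 10)), 1:101)),
    class = "classification_result")
  tab <- occupancy_table(res)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  expect_equal(tab$fraction, c(45, 27, 19, 10) / 101)
  expect_true(all(diff(tab$count) <= 0))
  # invariance under label permutation
  res2 <- res; res2$counts <- res$counts[c(3, 1, 4, 2)]
  expect_equal(sort(occupancy_table(res2)$fraction),
               sort(tab$fraction))
})
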