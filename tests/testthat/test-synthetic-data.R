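test_that("noiseless simulation equals the forward model and is seed-pure", {
  p <- default_protocol()
  np <- neurite_params(0.5, 1.1, 0.6, s0 = 10)
  expect_identical(simulate_voxel(np, p), neurite_forward(np, p))
  s1 <- simulate_voxel(np, p, snr_b0 = 30, seed = 5)
  s2 <- simulate_voxel(np, p, snr_b0 = 30, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_voxel(np, p, snr_b0 = 30, seed = 6)))
  expect_error(simulate_voxel(np, p, snr_b0 = -1), "positive")
  # the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_voxel(np, p, snr_b0 = 30, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("Rician noise has the contracted magnitude moments", {
  p0 <- diffusion_protocol(c(0, 1), matrix(c(0, 0, 1), 1), n_b0 = 1)
  s0 <- 1; snr <- 50; sigma <- s0 / snr
  reps <- vapply(1:10000, function(i) {
    simulate_voxel(list(d6 = c(0, 0, 0, 0, 0, 0), s0 = s0), p0,
                   snr_b0 = snr, seed = i)[1]
  }, numeric(1))
  # mean exceeds s0 by the Rician bias sigma^2 / (2 s0) at high SNR
  expect_gt(mean(reps), s0)
  expect_equal(mean(reps) - s0, sigma^2 / (2 * s0), tolerance = 0.5)
  # magnitude SD approaches the per-channel Gaussian SD within 3%
  expect_equal(sd(reps), sigma, tolerance = 0.03)
})

test_that("cohort draws follow the declared hierarchy", {
  # zero effects, zero variance: every value equals the global mean
  eff <- data.frame(metric = "m", roi = "AC",
                    group = c("control", "anhedonic", "resilient"),
                    mean = 0.5, between_sd = 0, within_sd = 0)
  sim <- simulate_cohort(cohort_effect_spec(eff, seed = 1))
  expect_true(all(sim$table$value == 0.5))
  # determinism
  s1 <- simulate_cohort(cohort_effect_spec(seed = 4))
  s2 <- simulate_cohort(cohort_effect_spec(seed = 4))
  expect_identical(s1$table, s2$table)
  # post-exclusion group sizes
  n <- table(unique(as.data.frame(s1$table)[, c("animal_id", "group")])$group)
  expect_equal(as.integer(n[c("control", "anhedonic", "resilient")]),
               c(7L, 6L, 8L))
  expect_error(simulate_cohort(cohort_effect_spec(
    within(eff, between_sd <- -1))), "non-negative")
})

test_that("map-mode cohorts carry truth usable by the full fitting chain", {
  eff <- data.frame(metric = "D_eff", roi = "AC",
                    group = c("control", "anhedonic", "resilient"),
                    mean = c(0.60, 0.48, 0.48),
                    between_sd = 0.03, within_sd = 0.03)
  spec <- cohort_effect_spec(eff, groups = c(control = 2L, anhedonic = 2L,
                                             resilient = 2L),
                             mode = "maps", seed = 2,
                             n_voxels_per_slice = 1L, n_replicates = 2L)
  sim <- simulate_cohort(spec)
  expect_length(sim$datasets, 6L)
  expect_s3_class(sim$datasets[[1]], "dwi_dataset")
  fit <- fit_neurite(sim$datasets[[1]],
                     options = neurite_fit_options(sh_order = 2,
                                                   refine_top = 2))
  tr <- sim$truth[sim$truth$animal_id == names(sim$datasets)[1], ]
  est <- fit$estimates[, "d_eff"]
  expect_lt(max(abs(sort(est) - sort(tr$value))), 0.15)
})

test_that("micrograph truth equals a brute-force pixel count", {
  sm <- synth_micrograph(micrograph_spec(seed = 13))
  expect_equal(sm$truth$process_fraction,
               sum(sm$process_mask) / prod(dim(sm$process_mask)))
  expect_equal(sm$truth$body_fraction,
               sum(sm$body_mask) / prod(dim(sm$body_mask)))
  expect_equal(sm$truth$n_bodies, nrow(sm$body_inventory))
  expect_false(any(sm$process_mask & sm$body_mask))   # disjoint classes
  # zero planted process fraction: the chain (which removes the somata)
  # reports near-zero density
  blank <- synth_micrograph(micrograph_spec(process_area_fraction = 0,
                                            seed = 2))
  expect_equal(blank$truth$process_fraction, 0)
  expect_lt(stain_density(blank$image)$density_pct, 0.5)
  expect_error(micrograph_spec(process_area_fraction = 0.7), "0, 0.5")
})

test_that("planted somata are detected by the shape filter", {
  sm <- synth_micrograph(micrograph_spec(n_cell_bodies = 10L,
                                         body_diameter_um = c(12, 18),
                                         seed = 17))
  dens <- stain_density(sm$image)
  expect_lte(abs(dens$body_components - 10L), 1L)
})

test_that("cortex montages measure back their planted thickness", {
  flat <- synth_cortex_montage(c(MC = 1500), um_per_px = 5, seed = 1)
  th <- suppressWarnings(cortical_thickness(flat$lines, 5))
  expect_equal(th$thickness_um, rep(1500, 5), tolerance = 1e-8)
  und <- synth_cortex_montage(c(MC = 1800), um_per_px = 5, seed = 2,
                              undulation_frac = 0.05)
  thu <- suppressWarnings(cortical_thickness(und$lines, 5))
  expect_true(all(abs(thu$thickness_um - 1800) / 1800 < 0.05))
  a <- synth_cortex_montage(c(MC = 1500), um_per_px = 5, seed = 3,
                            undulation_frac = 0.03)
  b <- synth_cortex_montage(c(MC = 1500), um_per_px = 5, seed = 3,
                            undulation_frac = 0.03)
  expect_identical(a$lines, b$lines)
  expect_error(synth_cortex_montage(c(MC = -5), 5), "positive")
  expect_error(synth_cortex_montage(c(MC = 1500), um_per_px = 5, seed = 1,
                                    height_px = 100L),
               "extent")
})
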