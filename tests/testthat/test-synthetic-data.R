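# The synthetic generator is the ground-truth source for every downstream
# stage; these tests pin its geometry, photon budget and determinism.

test_that("noiseless render puts the brightest locus voxel at the spot voxel and reports analytic truth", {
  sc <- aligned_scene(noiseless = TRUE)
  r <- render_nucleus_stack(sc)
  am <- arrayInd(which.max(r$stack$channels$locus), dim(r$stack$channels$locus))
  expect_equal(as.integer(am), c(32L + 7L, 32L, 20L))
  expect_equal(r$truth$true_volume, 4 / 3 * pi * 1.4^3, tolerance = 1e-12)
  expect_equal(r$truth$true_volume, 11.494, tolerance = 1e-4)
  expect_equal(r$truth$true_effective_radius, 1.4, tolerance = 1e-12)
  expect_equal(r$truth$true_scaled_depth, sc$spot_scaled_depth, tolerance = 1e-9)
})

test_that("rendering is bitwise deterministic under a fixed seed", {
  sc <- synthetic_scene(seed = 7)
  r1 <- render_nucleus_stack(sc)
  r2 <- render_nucleus_stack(sc)
  expect_identical(r1$stack$channels, r2$stack$channels)
  expect_identical(r1$truth, r2$truth)
})

test_that("locus channel photon mass above background matches the discretized Gaussian integral", {
  sc <- aligned_scene(noiseless = TRUE)
  r <- render_nucleus_stack(sc)
  mass <- sum(r$stack$channels$locus - sc$background)
  vox <- sc$voxel_size
  expected <- sc$spot_amplitude * (2 * pi)^1.5 * sc$psf_sigma_xy^2 *
    sc$psf_sigma_z / prod(vox)
  expect_equal(mass, expected, tolerance = 0.02)
})

test_that("scenes violating geometry or sign constraints are rejected", {
  expect_error(synthetic_scene(nucleus_center = c(0.5, 3.4, 5.2)), "clipped")
  expect_error(synthetic_scene(nucleus_radii = c(3.5, 3.5, 3.5)), "clipped")
  expect_error(synthetic_scene(spot_amplitude = -5), "non-negative")
  expect_error(synthetic_scene(spot_scaled_depth = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_scene(nucleus_radii = c(-1, 1, 1)), "> 0")
})

test_that("ground-truth scaled depth agrees with mesh distance on a finely subdivided true surface", {
  radii <- c(1.5, 1.2, 1.0)
  sc <- synthetic_scene(nucleus_radii = radii, spot_scaled_depth = 0.3,
                        spot_direction = c(1, 1, 0.5), poisson_noise = FALSE,
                        read_noise_sd = 0)
  r <- render_nucleus_stack(sc)
  fine <- icosphere(4L, 1)
  fine$vertices <- sweep(sweep(fine$vertices, 2, radii, `*`), 2,
                         sc$nucleus_center, `+`)
  d <- nearest_surface_distance(r$truth$spot_position, fine)
  s_mesh <- d$distance / r$truth$true_effective_radius
  expect_true(d$inside)
  expect_equal(s_mesh, r$truth$true_scaled_depth, tolerance = 0.01)
})

test_that("uniform-ball sampler has mean radius 3/4 and all depths in [0,1]", {
  p <- sample_locus_positions(1e5, "uniform_volume", seed = 42)
  se <- sd(p$r) / sqrt(nrow(p))
  expect_lt(abs(mean(p$r) - 3 / 4), 3 * se)
  expect_true(all(p$s >= 0 & p$s <= 1))
})

test_that("periphery-biased sampler concentrates depths near the envelope", {
  p <- sample_locus_positions(1e4, "periphery_biased", depth_scale = 0.05,
                              seed = 9)
  expect_true(all(p$s >= 0 & p$s <= 1))
  expect_gt(mean(p$s < 0.15), 0.8)
  expect_error(sample_locus_positions(10, "periphery_biased", depth_scale = 0),
               "depth_scale")
})

test_that("interval fixture plants exactly the requested near fraction, verified by brute force", {
  chr <- c(chrI = 3e5, chrII = 3e5)
  fx <- make_interval_fixture(n_features = 40, n_peaks = 30,
                              chrom_lengths = chr, planted_fraction = 0.5,
                              threshold_bp = 600, seed = 3)
  expect_equal(sum(fx$truth$near), 20L)
  d <- oracle_nearest_gap(fx$features, fx$peaks)
  expect_identical(d <= 600, fx$truth$near)
  expect_true(all(d[!fx$truth$near] >= 1200))

  fx1 <- make_interval_fixture(10, 10, chr, planted_fraction = 1,
                               threshold_bp = 600, seed = 4)
  expect_true(all(oracle_nearest_gap(fx1$features, fx1$peaks) <= 600))
  expect_error(make_interval_fixture(50, 50, c(chrI = 1e4), 0.5, 600, 1),
               "too short")
})

test_that("colony fixture draws Poisson counts around the planted rate and is seed-stable", {
  z <- make_colony_fixture(true_rate = 0, n_cultures = 20, seed = 1)
  expect_true(all(z$colonies_selective == 0))

  cf <- make_colony_fixture(true_rate = 1.5e-5, cells_plated_selective = 1e6,
                            n_cultures = 200, seed = 2)
  se <- sqrt(15 / 200)
  expect_lt(abs(mean(cf$colonies_selective) - 15), 3 * se)
  cf2 <- make_colony_fixture(true_rate = 1.5e-5, cells_plated_selective = 1e6,
                             n_cultures = 200, seed = 2)
  expect_identical(cf, cf2)
})
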