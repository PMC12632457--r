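test_that("scaled depth follows the sign convention: 1 at the center, 0 on the surface, negative outside", {
  nuc <- sphere_nucleus(R = 1.4, center = c(3, 3, 3))
  ctr <- scaled_depth(fake_spot(c(3, 3, 3)), nuc)
  expect_false(ctr$exterior)
  expect_equal(ctr$s, 1, tolerance = 0.02)

  on_surf <- scaled_depth(fake_spot(nuc$mesh$vertices[5, ]), nuc)
  expect_equal(on_surf$s, 0, tolerance = 1e-12)

  outside <- scaled_depth(fake_spot(c(3 + 1.1 * 1.4, 3, 3)), nuc)
  expect_true(outside$exterior)
  expect_equal(outside$s, -0.1, tolerance = 0.03)

  bad <- nuc
  bad$converged <- FALSE
  expect_error(scaled_depth(fake_spot(c(3, 3, 3)), bad), "not converged")
})

test_that("an all-first-shell sample gives the closed-form density and zeros elsewhere", {
  rd <- radial_density(withr::with_seed(1, runif(100, 0, 0.0999)))
  expect_equal(rd$bins$p[1], 1)
  expect_equal(rd$bins$f[1], 1 / (4 * pi * 0.95^2 * 0.1), tolerance = 1e-12)
  expect_equal(rd$bins$f[1], 0.8818, tolerance = 1e-4)
  expect_true(all(rd$bins$f[-1] == 0))
})

test_that("probabilities always sum to one and s = 1 lands in the innermost shell", {
  for (seed in 1:5) {
    s <- sample_locus_positions(200, seed = seed)$s
    rd <- radial_density(s)
    expect_equal(sum(rd$bins$p), 1, tolerance = 1e-15)
    expect_identical(sum(rd$bins$c), rd$N)
  }
  rd1 <- radial_density(c(1, 1, 0.5))
  expect_equal(rd1$bins$c[10], 2L)
  expect_error(radial_density(numeric()), "empty")
  expect_error(radial_density(0.5, w = 0.3), "integer number of shells")
  expect_error(radial_density(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("uniform-in-volume depths reproduce the uniform-ball shell densities", {
  s <- sample_locus_positions(1e5, "uniform_volume", seed = 8)$s
  rd <- radial_density(s)
  # exact uniform expectation through the midpoint-rule density: the
  # midpoint shell area under-represents the true shell volume, noticeably
  # so for the innermost shell (0.318 vs the continuum 3/4pi = 0.2387)
  r_hi <- 1 - rd$bins$s_lo
  r_lo <- 1 - rd$bins$s_hi
  f_exp <- (r_hi^3 - r_lo^3) / (4 * pi * rd$bins$r_mid^2 * rd$w)
  dev <- abs(rd$bins$f - f_exp)
  expect_true(all(dev <= 3 * rd$bins$sigma_f))
  # away from the center the continuum value is an excellent approximation
  expect_true(all(abs(f_exp[1:8] - 3 / (4 * pi)) < 0.012))
})

test_that("sigma_f is the Poisson propagation: sqrt(c)/f ratio and the worked value", {
  expect_equal(density_uncertainty(0, 50, 0.05, 0.1), 0)
  expect_equal(density_uncertainty(25, 100, 0.05, 0.1),
               5 / (100 * 4 * pi * 0.9025 * 0.1), tolerance = 1e-12)
  expect_equal(density_uncertainty(25, 100, 0.05, 0.1), 0.04409, tolerance = 1e-4)

  s <- sample_locus_positions(5000, seed = 2)$s
  rd <- radial_density(s)
  occ <- rd$bins$c > 0
  expect_equal(rd$bins$sigma_f[occ] / rd$bins$f[occ], 1 / sqrt(rd$bins$c[occ]),
               tolerance = 1e-12)
})

test_that("analytic sigma_f agrees with a cell-level bootstrap for well-populated shells", {
  s <- sample_locus_positions(2000, "uniform_volume", seed = 31)$s
  bt <- bootstrap_density_uncertainty(s, n_boot = 2000, seed = 32)
  ok <- bt$c >= 10
  expect_true(all(abs(bt$sigma_boot[ok] - bt$sigma_f[ok]) / bt$sigma_f[ok] < 0.25))
})

test_that("cohort pooling excludes exterior spots and handles the degenerate single cell", {
  nuc <- sphere_nucleus(R = 1.4, center = c(3.4, 3.4, 5.2))
  pos <- sample_locus_positions(300, "periphery_biased", depth_scale = 0.05,
                                seed = 41)
  # keep spots a hair inside the faceted surface: the icosphere dips ~1%
  # below the true sphere, so depths below ~0.02 would land outside it
  rr <- (1 - (0.03 + 0.97 * pos$s)) / pos$r
  spots <- lapply(seq_len(nrow(pos)), function(i)
    fake_spot(c(3.4, 3.4, 5.2) + as.numeric(pos[i, c("x", "y", "z")]) * rr[i] * 1.4))
  spots[[1]] <- fake_spot(c(3.4 + 2.0, 3.4, 5.2)) # planted exterior
  rd <- cohort_density(spots, rep(list(nuc), length(spots)))
  expect_equal(rd$n_excluded, 1L)
  expect_equal(attr(rd, "cells")$reason[1], "exterior spot")
  expect_true(all(rd$bins$f[1] > rd$bins$f[rd$bins$s_mid > 0.3]))

  single <- cohort_density(spots[2], list(nuc))
  expect_equal(single$N, 1L)
  expect_equal(sum(single$bins$p), 1)
  expect_equal(max(single$bins$p), 1)

  expect_error(cohort_density(list(NULL), list(nuc)), "zero usable")
})
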