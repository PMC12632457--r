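test_that("initial mesh estimates radius and center from the membrane projection", {
  sc <- synthetic_scene(seed = 17, nucleus_radii = rep(1.4, 3),
                        poisson_noise = FALSE, read_noise_sd = 0)
  r <- render_nucleus_stack(sc)
  m0 <- initial_mesh(r$stack)
  expect_equal(attr(m0, "r0"), 1.4, tolerance = 0.10)
  expect_lt(max(abs(attr(m0, "center") - sc$nucleus_center)), 0.3)

  blank <- image_stack(list(membrane = array(5, c(32, 32, 8))), c(0.1, 0.1, 0.3))
  expect_error(initial_mesh(blank), "no nucleus found")
})

test_that("with two nuclei in the field the largest component is used", {
  mk <- function(center, R, seed) {
    render_nucleus_stack(synthetic_scene(
      nucleus_center = center, nucleus_radii = rep(R, 3), seed = seed,
      poisson_noise = FALSE, read_noise_sd = 0))$stack$channels$membrane
  }
  a <- mk(c(2.1, 2.1, 5.2), 1.2, 1)
  b <- mk(c(4.9, 4.9, 5.2), 0.8, 2)
  st <- image_stack(list(membrane = pmax(a, b)), c(0.1065, 0.1065, 0.26))
  m0 <- initial_mesh(st)
  expect_equal(attr(m0, "n_components"), 2L)
  expect_equal(attr(m0, "r0"), 1.2, tolerance = 0.12)
  expect_lt(max(abs(attr(m0, "center")[1:2] - c(2.1, 2.1))), 0.3)
})

test_that("bending energy penalizes a displaced vertex and matches an R-side umbrella computation", {
  sc <- synthetic_scene(seed = 19)
  st <- render_nucleus_stack(sc)$stack
  cfg_b <- energy_config(lambda_bend = 2.5, lambda_image = 0)
  m <- icosphere(2L, 1.2, center = sc$nucleus_center)
  e_sphere <- total_energy(m, st, cfg_b)

  m_pert <- m
  i <- 11L
  vv <- m_pert$vertices[i, ] - sc$nucleus_center
  m_pert$vertices[i, ] <- sc$nucleus_center + vv * (1 + 0.2 / sqrt(sum(vv^2)))
  expect_lt(e_sphere, total_energy(m_pert, st, cfg_b))

  # independent umbrella evaluation in R
  umbrella <- function(mesh) {
    f <- mesh$faces
    e <- unique(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])))
    e <- unique(rbind(e, cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                      cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))))
    h <- mean(sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2)))
    s <- 0
    for (v in seq_len(nrow(mesh$vertices))) {
      nb <- unique(c(e[e[, 1] == v, 2], e[e[, 2] == v, 1]))
      u <- mesh$vertices[v, ] - colMeans(mesh$vertices[nb, , drop = FALSE])
      s <- s + sum(u^2)
    }
    s / h^2
  }
  expect_equal(e_sphere, 2.5 * umbrella(m), tolerance = 1e-10)
})

test_that("image energy is lower for a mesh on the rendered shell than for a shrunken copy", {
  sc <- synthetic_scene(seed = 23, nucleus_radii = rep(1.4, 3),
                        poisson_noise = FALSE, read_noise_sd = 0)
  st <- render_nucleus_stack(sc)$stack
  cfg_i <- energy_config(lambda_bend = 0, lambda_image = 1)
  on_shell <- icosphere(3L, 1.4, center = sc$nucleus_center)
  shrunk <- icosphere(3L, 0.98, center = sc$nucleus_center)
  expect_lt(total_energy(on_shell, st, cfg_i), total_energy(shrunk, st, cfg_i))
})

test_that("reconstruction recovers sphere and ellipsoid volumes and is deterministic", {
  sc <- synthetic_scene(seed = 29, nucleus_radii = rep(1.4, 3),
                        poisson_noise = FALSE, read_noise_sd = 0)
  r <- render_nucleus_stack(sc)
  nm <- reconstruct_nucleus(r$stack)
  expect_true(nm$converged)
  expect_equal(nm$volume, r$truth$true_volume, tolerance = 0.08)
  expect_equal(nm$effective_radius, 1.4, tolerance = 0.03)

  sc2 <- synthetic_scene(seed = 29, nucleus_radii = c(1.6, 1.2, 1.2),
                         poisson_noise = FALSE, read_noise_sd = 0)
  r2 <- render_nucleus_stack(sc2)
  nm2 <- reconstruct_nucleus(r2$stack)
  expect_equal(nm2$volume, 4 / 3 * pi * 1.6 * 1.2^2, tolerance = 0.10)

  nm_b <- reconstruct_nucleus(r$stack)
  expect_identical(nm$mesh$vertices, nm_b$mesh$vertices)
})

test_that("energy is non-increasing across accepted descent iterations", {
  sc <- synthetic_scene(seed = 37)
  nm <- reconstruct_nucleus(render_nucleus_stack(sc)$stack)
  expect_true(all(diff(nm$energy_path) <= 1e-12))
  expect_equal(nm$final_energy, tail(nm$energy_path, 1))
})
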