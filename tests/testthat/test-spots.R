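test_that("maximum projection reduces to the slice for single-slice and constant stacks", {
  one <- image_stack(list(locus = array(runif(64), c(8, 8, 1))), c(0.1, 0.1, 0.3))
  expect_equal(max_project(one), one$channels$locus[, , 1])
  const <- image_stack(list(locus = array(3, c(6, 6, 5))), c(0.1, 0.1, 0.3))
  expect_true(all(max_project(const) == 3))
  sc <- aligned_scene(noiseless = TRUE)
  r <- render_nucleus_stack(sc)
  expect_equal(max(max_project(r$stack, "locus")), max(r$stack$channels$locus))
})

test_that("candidate detection finds the single spot, honors the tie rule and the threshold", {
  sc <- aligned_scene(noiseless = TRUE)
  proj <- max_project(render_nucleus_stack(sc)$stack, "locus")
  cand <- detect_candidates(proj)
  expect_equal(nrow(cand), 1L)
  expect_equal(as.integer(cand[1, ]), c(39L, 32L))

  img <- matrix(0, 12, 12)
  img[5, 5] <- 10; img[6, 5] <- 10 # equal maxima 1 px apart
  cand2 <- detect_candidates(img, threshold = 1)
  expect_equal(nrow(cand2), 1L)
  expect_equal(as.integer(cand2[1, ]), c(5L, 5L)) # lowest linear index wins

  expect_equal(nrow(detect_candidates(img, threshold = 50)), 0L)
  expect_equal(nrow(detect_candidates(matrix(1, 10, 10))), 0L) # flat image
})

test_that("3D Gaussian fit recovers exact and sub-voxel spot centers", {
  vox <- c(0.1065, 0.1065, 0.26)
  c_exact <- c((24 - 0.5) * vox[1], (24 - 0.5) * vox[2], (12 - 0.5) * vox[3])
  st <- gaussian_spot_stack(c_exact)
  f <- fit_gaussian_3d(st, c(24L, 24L), channel = "locus")
  expect_true(f$converged)
  expect_lt(max(abs(f$center - c_exact) / vox), 1e-3)

  c_off <- c_exact + c(0.3, -0.2, 0.4) * vox
  f2 <- fit_gaussian_3d(gaussian_spot_stack(c_off), c(24L, 24L))
  expect_lt(max(abs(f2$center - c_off) / vox), 0.02)
})

test_that("a fit window clipped by the stack boundary is an error", {
  st <- gaussian_spot_stack(c(0.2, 0.2, 0.5))
  expect_error(fit_gaussian_3d(st, c(2L, 2L)), "window out of bounds")
})

test_that("the fitted objective never exceeds the objective at the initialization", {
  sc <- aligned_scene(noiseless = FALSE, seed = 21)
  r <- render_nucleus_stack(sc)
  cand <- detect_candidates(max_project(r$stack, "locus"))
  f <- fit_gaussian_3d(r$stack, cand[1, ])
  expect_lte(f$residual_ss, f$objective_init)
})

test_that("fitting is equivariant under integer-voxel translation", {
  vox <- c(0.1065, 0.1065, 0.26)
  c0 <- c(24.3 - 0.5, 23.7 - 0.5, 12.4 - 0.5) * vox
  shift <- c(2L, 3L, -1L)
  f1 <- fit_gaussian_3d(gaussian_spot_stack(c0), c(24L, 24L))
  f2 <- fit_gaussian_3d(gaussian_spot_stack(c0 + shift * vox),
                        c(24L + shift[1], 24L + shift[2]))
  expect_equal(f2$center - f1$center, shift * vox, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("localize returns one converged fit for a single-spot stack and nothing for a blank one", {
  sc <- aligned_scene(noiseless = FALSE, seed = 31)
  r <- render_nucleus_stack(sc)
  fits <- localize_spots(r$stack)
  expect_equal(length(fits), 1L)
  expect_true(fits[[1]]$converged)
  expect_lt(sqrt(sum((fits[[1]]$center - r$truth$spot_position)^2)), 0.05)

  blank <- image_stack(list(locus = array(100, c(32, 32, 8))), c(0.1, 0.1, 0.3))
  expect_warning(none <- localize_spots(blank), "no candidates")
  expect_equal(length(none), 0L)
})

test_that("batch localization is reproducible across runs", {
  centers <- function() {
    out <- list()
    for (seed in 41:50) {
      r <- render_nucleus_stack(synthetic_scene(seed = seed))
      fits <- suppressWarnings(localize_spots(r$stack))
      out[[length(out) + 1L]] <- fits[[1]]$center
    }
    out
  }
  expect_identical(centers(), centers())
})
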