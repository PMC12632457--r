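# Shared fixture builders; everything is generated in code under fixed seeds.

# A scene whose nucleus center and spot both sit exactly on voxel centers
# (direction +x), for argmax / sub-voxel fitting tests.
aligned_scene <- function(noiseless = TRUE, seed = 1L, m_voxels = 7L) {
  vox <- c(0.1065, 0.1065, 0.26)
  center <- c((32 - 0.5) * vox[1], (32 - 0.5) * vox[2], (20 - 0.5) * vox[3])
  R <- 1.4
  kk <- m_voxels * vox[1]
  synthetic_scene(nucleus_center = center, nucleus_radii = rep(R, 3),
                  spot_scaled_depth = 1 - kk / R, spot_direction = c(1, 0, 0),
                  poisson_noise = !noiseless,
                  read_noise_sd = if (noiseless) 0 else 2,
                  seed = seed)
}

# Locus-channel-only stack with a Gaussian spot at an arbitrary continuous
# position (um); exercises the fitter independently of the renderer.
gaussian_spot_stack <- function(center_um, amplitude = 500, background = 100,
                                sigma_xy = 0.13, sigma_z = 0.3,
                                dims = c(48L, 48L, 24L),
                                vox = c(0.1065, 0.1065, 0.26)) {
  cx <- (seq_len(dims[1]) - 0.5) * vox[1]
  cy <- (seq_len(dims[2]) - 0.5) * vox[2]
  cz <- (seq_len(dims[3]) - 0.5) * vox[3]
  gx <- exp(-(cx - center_um[1])^2 / (2 * sigma_xy^2))
  gy <- exp(-(cy - center_um[2])^2 / (2 * sigma_xy^2))
  gz <- exp(-(cz - center_um[3])^2 / (2 * sigma_z^2))
  a <- amplitude * outer(outer(gx, gy), gz) + background
  image_stack(list(locus = a), vox)
}

# Nucleus model wrapping an exact icosphere (no reconstruction), for
# scaled-depth and density tests.
sphere_nucleus <- function(R = 1.4, center = c(0, 0, 0), subdivision = 3L) {
  mesh <- icosphere(subdivision, R, center)
  vol <- mesh_volume(mesh)
  structure(list(mesh = mesh, volume = vol,
                 effective_radius = (3 * vol / (4 * pi))^(1 / 3),
                 center = center, converged = TRUE, final_energy = NA_real_,
                 iterations = 0L, energy_path = numeric()),
            class = "nucleus_model")
}

fake_spot <- function(pos) {
  structure(list(center = as.numeric(pos), sigma_xy = 0.13, sigma_z = 0.3,
                 amplitude = 500, offset = 100, residual_ss = 0,
                 converged = TRUE), class = "spot_fit")
}

# Independent point-to-triangle distance oracle: projection onto the
# triangle plane with barycentric clamping to edges (a different formulation
# from the implementation).
oracle_point_tri <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * d))^2))
  }
  u <- b - a; w <- c - a
  n <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-300) return(min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, a, c)))
  n <- n / nn
  q <- p - sum((p - a) * n) * n
  # barycentric coords of q
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(sqrt(sum((p - q)^2)))
  min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, a, c))
}

oracle_mesh_dist <- function(p, mesh) {
  min(vapply(seq_len(nrow(mesh$faces)), function(f) {
    i <- mesh$faces[f, ]
    oracle_point_tri(p, mesh$vertices[i[1], ], mesh$vertices[i[2], ],
                     mesh$vertices[i[3], ])
  }, 0))
}

# Brute-force nearest-gap oracle on raw coordinates (no package code).
oracle_nearest_gap <- function(features, peaks) {
  vapply(seq_len(nrow(features)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(peaks))) {
      if (features$chrom[i] != peaks$chrom[j]) next
      g <- max(0, max(features$start[i], peaks$start[j]) -
                  min(features$end[i], peaks$end[j]))
      best <- min(best, g)
    }
    best
  }, 0)
}

# Random interval sets (not separation-constrained) for sweep-vs-brute tests.
random_interval_set <- function(n, chroms = c("chrI", "chrII", "chrIII"),
                                max_pos = 5e4, seed = 1L) {
  withr::with_seed(seed, {
    chrom <- sample(chroms, n, replace = TRUE)
    start <- sample.int(max_pos, n, replace = TRUE)
    len <- sample.int(2000, n, replace = TRUE)
    intervals(data.frame(chrom = chrom, start = start, end = start + len,
                         name = sprintf("iv%03d", seq_len(n)),
                         stringsAsFactors = FALSE))
  })
}
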