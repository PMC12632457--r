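# Shared numeric helpers. Voxel-center convention: voxel i (1-based) along an
# axis with pitch d has its center at (i - 0.5) * d micrometres.

# Physical coordinates (um) of all voxel centers along one axis.
axis_centers <- function(n, d) (seq_len(n) - 0.5) * d

# 1D Gaussian kernel on the voxel lattice, truncated at 4 sigma, sum 1.
gauss_kernel <- function(sigma_um, d_um) {
  sv <- sigma_um / d_um
  r <- max(1L, ceiling(4 * sv))
  k <- exp(-((-r:r)^2) / (2 * sv^2))
  k / sum(k)
}

# Convolve a 3D array with a 1D kernel along one axis (zero-padded edges),
# via a dense band matrix; grids here are small (<= a few hundred per axis).
conv_axis <- function(arr, kernel, axis) {
  dm <- dim(arr)
  n <- dm[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  out <- K %*% matrix(a, da[1], da[2] * da[3])
  dim(out) <- da
  aperm(out, order(perm))
}

# Separable anisotropic Gaussian blur in physical units.
blur3d <- function(arr, sigma_xy, sigma_z, voxel) {
  arr <- conv_axis(arr, gauss_kernel(sigma_xy, voxel[1]), 1L)
  arr <- conv_axis(arr, gauss_kernel(sigma_xy, voxel[2]), 2L)
  conv_axis(arr, gauss_kernel(sigma_z, voxel[3]), 3L)
}

# Signed distance from points to an ellipsoid surface (exact, via the
# standard one-parameter root for the foot point). `pts` n x 3, centered
# coordinates already subtracted. Negative inside.
ellipsoid_signed_distance <- function(pts, radii) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  r2 <- radii^2
  apply(pts, 1, function(p) {
    rho2 <- sum((p / radii)^2)
    if (all(p == 0)) return(-min(radii))
    f <- function(t) sum((radii * p / (r2 + t))^2) - 1
    lo <- -min(r2) + 1e-12
    hi <- max(radii) * (sqrt(rho2) + 1) * max(radii)
    while (f(hi) > 0) hi <- hi * 2
    t0 <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
    q <- r2 * p / (r2 + t0)
    d <- sqrt(sum((p - q)^2))
    if (rho2 < 1) -d else d
  })
}

# Deterministic per-stage seed derived from a global seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
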