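#' Maximum-intensity projection over z
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @return A 2D matrix `[x, y]`, the pixelwise maximum over z.
#' @export
max_project <- function(stack, channel = "locus") {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[channel]]
  if (is.null(a)) stop("no channel '", channel, "' in stack")
  Reduce(pmax, lapply(seq_len(dim(a)[3]), function(k) a[, , k]))
}

#' Detect spot candidates on a projected image
#'
#' Keeps pixels above threshold that are local maxima within
#' `min_separation_px`; when two above-threshold maxima fall within that
#' radius only the brighter survives, ties broken by the lower linear index
#' (column-major over `[x, y]`, the package's row-major order). The default
#' threshold is robust: median + 7 * 1.4826 * MAD of the projection. The
#' factor 7 clears the extreme-value tail of a maximum projection: the max
#' over ~40 slices concentrates the background median while its upper tail
#' still spans several MAD across ~4000 pixels, so a 5-MAD cut admits a few
#' noise maxima per stack.
#'
#' @param image2d numeric matrix `[x, y]`.
#' @param threshold absolute intensity threshold, or `NULL` for the robust
#'   default.
#' @param min_separation_px suppression radius in pixels.
#' @return Integer matrix with columns `x`, `y` (1-based pixel coordinates),
#'   zero rows if nothing is above threshold.
#' @export
detect_candidates <- function(image2d, threshold = NULL,
                              min_separation_px = 1.5) {
  stopifnot(is.matrix(image2d), all(is.finite(image2d)))
  if (is.null(threshold))
    threshold <- median(image2d) + 7 * mad(image2d)
  nx <- nrow(image2d); ny <- ncol(image2d)
  r <- floor(min_separation_px)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= min_separation_px^2 &
                 !(offs$dx == 0 & offs$dy == 0), ]
  pad <- matrix(-Inf, nx + 2 * r, ny + 2 * r)
  pad[r + seq_len(nx), r + seq_len(ny)] <- image2d
  is_max <- image2d > threshold
  for (i in seq_len(nrow(offs))) {
    nb <- pad[r + seq_len(nx) + offs$dx[i], r + seq_len(ny) + offs$dy[i]]
    is_max <- is_max & (image2d >= nb)
  }
  idx <- which(is_max)
  if (length(idx) == 0) return(cbind(x = integer(), y = integer()))
  ord <- order(-image2d[idx], idx)
  idx <- idx[ord]
  xs <- ((idx - 1L) %% nx) + 1L
  ys <- ((idx - 1L) %/% nx) + 1L
  keep <- logical(length(idx))
  for (i in seq_along(idx)) {
    if (!any(keep) ||
        all((xs[i] - xs[keep])^2 + (ys[i] - ys[keep])^2 > min_separation_px^2))
      keep[i] <- TRUE
  }
  cbind(x = xs[keep], y = ys[keep]) # brightest first
}

#' Fit a 3D Gaussian to one locus
#'
#' Least-squares fit of
#' `B + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 s_xy^2) - (z-z0)^2 / (2 s_z^2))`
#' over a voxel window centered on the candidate, by Levenberg-Marquardt
#' with an analytic Jacobian. Initialization: center at the
#' intensity-weighted centroid of the window, `B` the window minimum, `A`
#' the window range, widths at the configured PSF priors. Bounds keep the
#' widths within `[0.5, 4]` times the priors and the center inside the
#' window. Convergence at relative objective decrease `< 1e-10` or 500
#' iterations.
#'
#' @param stack an [image_stack()].
#' @param candidate_px integer `(x, y)` pixel from [detect_candidates()].
#' @param channel locus channel name.
#' @param window odd integer length-3 window in voxels `(wx, wy, wz)`.
#' @param psf_prior numeric length-2, prior `(sigma_xy, sigma_z)` in um.
#' @return A `spot_fit` object: `center` (um), `sigma_xy`, `sigma_z`,
#'   `amplitude`, `offset`, `residual_ss`, `converged`, `window`,
#'   `objective_init`.
#' @export
fit_gaussian_3d <- function(stack, candidate_px, channel = "locus",
                            window = c(7L, 7L, 9L),
                            psf_prior = c(0.13, 0.3)) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[channel]]
  d <- dim(a)
  vox <- stack$voxel_size
  hw <- (as.integer(window) - 1L) %/% 2L
  cz <- which.max(a[candidate_px[1], candidate_px[2], ])
  c0 <- c(candidate_px[1], candidate_px[2], cz)
  lo <- c0 - hw; hi <- c0 + hw
  if (any(lo < 1) || any(hi > d)) stop("window out of bounds")
  sub <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  xs <- axis_centers(d[1], vox[1])[lo[1]:hi[1]]
  ys <- axis_centers(d[2], vox[2])[lo[2]:hi[2]]
  zs <- axis_centers(d[3], vox[3])[lo[3]:hi[3]]
  G <- expand.grid(x = xs, y = ys, z = zs)
  I <- as.numeric(sub)

  B0 <- min(I); A0 <- max(I) - B0
  wgt <- pmax(I - B0, 0)
  if (sum(wgt) == 0) wgt <- rep(1, length(I))
  p0 <- c(x0 = sum(G$x * wgt) / sum(wgt),
          y0 = sum(G$y * wgt) / sum(wgt),
          z0 = sum(G$z * wgt) / sum(wgt),
          sxy = psf_prior[1], sz = psf_prior[2], A = A0, B = B0)
  lower <- c(min(xs), min(ys), min(zs), 0.5 * psf_prior, 1e-6, -Inf)
  upper <- c(max(xs), max(ys), max(zs), 4 * psf_prior, Inf, Inf)

  model <- function(p) {
    p[6] * exp(-((G$x - p[1])^2 + (G$y - p[2])^2) / (2 * p[4]^2) -
                 (G$z - p[3])^2 / (2 * p[5]^2)) + p[7]
  }
  resid_fn <- function(p) model(p) - I
  jac_fn <- function(p) {
    e <- exp(-((G$x - p[1])^2 + (G$y - p[2])^2) / (2 * p[4]^2) -
               (G$z - p[3])^2 / (2 * p[5]^2))
    Ae <- p[6] * e
    cbind(Ae * (G$x - p[1]) / p[4]^2,
          Ae * (G$y - p[2]) / p[4]^2,
          Ae * (G$z - p[3]) / p[5]^2,
          Ae * ((G$x - p[1])^2 + (G$y - p[2])^2) / p[4]^3,
          Ae * (G$z - p[3])^2 / p[5]^3,
          e,
          rep(1, length(e)))
  }
  obj_init <- sum(resid_fn(p0)^2)
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 500))
  p <- fit$par
  converged <- fit$info %in% c(1, 2, 3, 4) && p[["A"]] > 0
  structure(list(center = c(x = p[["x0"]], y = p[["y0"]], z = p[["z0"]]),
                 sigma_xy = p[["sxy"]], sigma_z = p[["sz"]],
                 amplitude = p[["A"]], offset = p[["B"]],
                 residual_ss = fit$deviance, converged = converged,
                 window = list(lo = lo, hi = hi),
                 objective_init = obj_init,
                 candidate_px = c0),
            class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf("spot_fit: center (%.4f, %.4f, %.4f) um, sigma_xy %.3f, sigma_z %.3f\n",
              x$center[1], x$center[2], x$center[3], x$sigma_xy, x$sigma_z))
  cat(sprintf("  amplitude %.1f, offset %.1f, SS %.3g, converged: %s\n",
              x$amplitude, x$offset, x$residual_ss, x$converged))
  invisible(x)
}

#' Localize all loci in a stack
#'
#' Projection, candidate detection and per-candidate 3D Gaussian fit;
#' candidates whose window is clipped by the stack boundary or whose fit
#' fails to converge are dropped, with reasons recorded in the `exclusions`
#' attribute.
#'
#' @param stack an [image_stack()].
#' @param channel locus channel name.
#' @param threshold detection threshold, `NULL` for the robust default.
#' @param window fit window in voxels.
#' @param psf_prior prior `(sigma_xy, sigma_z)` um.
#' @return List of converged `spot_fit` objects (possibly empty), with an
#'   `exclusions` attribute (data frame: x, y, reason).
#' @export
localize_spots <- function(stack, channel = "locus", threshold = NULL,
                           window = c(7L, 7L, 9L), psf_prior = c(0.13, 0.3)) {
  proj <- max_project(stack, channel)
  cand <- detect_candidates(proj, threshold)
  fits <- list()
  excl <- data.frame(x = integer(), y = integer(), reason = character())
  if (nrow(cand) == 0) {
    warning("no candidates above threshold")
  }
  for (i in seq_len(nrow(cand))) {
    f <- tryCatch(fit_gaussian_3d(stack, cand[i, ], channel, window, psf_prior),
                  error = function(e) e)
    if (inherits(f, "error")) {
      excl <- rbind(excl, data.frame(x = cand[i, 1], y = cand[i, 2],
                                     reason = conditionMessage(f)))
    } else if (!f$converged) {
      warning("fit at (", cand[i, 1], ",", cand[i, 2], ") did not converge; dropped")
      excl <- rbind(excl, data.frame(x = cand[i, 1], y = cand[i, 2],
                                     reason = "not converged"))
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  attr(fits, "exclusions") <- excl
  fits
}

#' Tabulate spot fits
#'
#' @param fits list of `spot_fit` objects.
#' @param sample_ids optional ids, recycled.
#' @return A data frame, one row per fit.
#' @export
spot_table <- function(fits, sample_ids = seq_along(fits)) {
  if (length(fits) == 0)
    return(data.frame(sample_id = character(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(), sigma_xy = numeric(),
                      sigma_z = numeric(), amplitude = numeric(),
                      offset = numeric(), residual_ss = numeric(),
                      converged = logical()))
  data.frame(
    sample_id = rep_len(sample_ids, length(fits)),
    x_um = vapply(fits, function(f) f$center[[1]], 0),
    y_um = vapply(fits, function(f) f$center[[2]], 0),
    z_um = vapply(fits, function(f) f$center[[3]], 0),
    sigma_xy = vapply(fits, function(f) f$sigma_xy, 0),
    sigma_z = vapply(fits, function(f) f$sigma_z, 0),
    amplitude = vapply(fits, function(f) f$amplitude, 0),
    offset = vapply(fits, function(f) f$offset, 0),
    residual_ss = vapply(fits, function(f) f$residual_ss, 0),
    converged = vapply(fits, function(f) f$converged, TRUE))
}
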