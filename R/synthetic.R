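#' Describe a synthetic nucleus scene
#'
#' Parameters of one simulated two-channel acquisition: an ellipsoidal
#' nucleus rendered as a thin bright shell in the membrane channel (the
#' nuclear envelope marker) and a single diffraction-limited spot in the
#' locus channel (the lacO/lacI-GFP dot). Geometry defaults mirror a typical
#' wide-field acquisition: 40 z-sections at 0.26 um spacing, ~0.1 um xy
#' pixels (100x objective on an EMCCD), a nucleus of radius ~1.4 um.
#'
#' `spot_scaled_depth` is the scaled depth s in `[0, 1]`: the distance from
#' the spot to the nearest point of the nuclear surface divided by the
#' effective nuclear radius; s = 0 is on the envelope, s = 1 the center.
#'
#' @param grid_shape integer length-3, voxels `(nx, ny, nz)`.
#' @param voxel_size um `(dx, dy, dz)`.
#' @param nucleus_center um triple; default the grid center.
#' @param nucleus_radii um triple `(a, b, c)`; a sphere when equal.
#' @param shell_thickness um; envelope shell thickness (sub-resolution).
#' @param membrane_amplitude peak membrane photons above background.
#' @param spot_scaled_depth scaled depth s in `[0, 1]`.
#' @param spot_direction unit direction from the center towards the surface,
#'   or `"random"`.
#' @param spot_amplitude peak spot photons above background.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF widths, um.
#' @param background photons per voxel.
#' @param read_noise_sd Gaussian read noise SD, photons; 0 disables.
#' @param poisson_noise logical; draw Poisson shot noise.
#' @param seed integer; fixes all randomness of the render.
#' @return A `synthetic_scene` list.
#' @export
synthetic_scene <- function(grid_shape = c(64L, 64L, 40L),
                            voxel_size = c(0.1065, 0.1065, 0.26),
                            nucleus_center = NULL,
                            nucleus_radii = c(1.4, 1.4, 1.4),
                            shell_thickness = 0.1,
                            membrane_amplitude = 800,
                            spot_scaled_depth = 0.5,
                            spot_direction = "random",
                            spot_amplitude = 500,
                            psf_sigma_xy = 0.13,
                            psf_sigma_z = 0.3,
                            background = 100,
                            read_noise_sd = 2,
                            poisson_noise = TRUE,
                            seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_size <- as.numeric(voxel_size)
  extent <- grid_shape * voxel_size
  if (is.null(nucleus_center)) nucleus_center <- extent / 2
  sc <- list(grid_shape = grid_shape, voxel_size = voxel_size,
             nucleus_center = as.numeric(nucleus_center),
             nucleus_radii = as.numeric(nucleus_radii),
             shell_thickness = shell_thickness,
             membrane_amplitude = membrane_amplitude,
             spot_scaled_depth = spot_scaled_depth,
             spot_direction = spot_direction,
             spot_amplitude = spot_amplitude,
             psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
             background = background, read_noise_sd = read_noise_sd,
             poisson_noise = poisson_noise, seed = as.integer(seed))
  class(sc) <- "synthetic_scene"
  validate_scene(sc)
  sc
}

validate_scene <- function(sc) {
  if (any(sc$nucleus_radii <= 0)) stop("all nucleus radii must be > 0")
  if (sc$spot_scaled_depth < 0 || sc$spot_scaled_depth > 1)
    stop("spot_scaled_depth must lie in [0, 1]")
  if (sc$membrane_amplitude < 0 || sc$spot_amplitude < 0 ||
      sc$background < 0 || sc$read_noise_sd < 0)
    stop("amplitudes, background and noise must be non-negative")
  if (sc$shell_thickness <= 0) stop("shell_thickness must be > 0")
  extent <- sc$grid_shape * sc$voxel_size
  margin <- 3 * c(sc$psf_sigma_xy, sc$psf_sigma_xy, sc$psf_sigma_z)
  lo <- sc$nucleus_center - sc$nucleus_radii - sc$shell_thickness / 2 - margin
  hi <- sc$nucleus_center + sc$nucleus_radii + sc$shell_thickness / 2 + margin
  if (any(lo < 0) || any(hi > extent))
    stop("nucleus clipped by grid: needs >= 3 sigma PSF margin inside the stack")
  invisible(sc)
}

#' Render a synthetic two-channel nucleus stack with ground truth
#'
#' The membrane channel is the indicator of a thin shell around the
#' ellipsoid surface convolved with the anisotropic Gaussian PSF, peak-scaled
#' to `membrane_amplitude` plus background. The locus channel is a single 3D
#' Gaussian of the PSF widths at the spot position. Per-voxel Poisson shot
#' noise is applied to expected photons, then additive Gaussian read noise;
#' the result is rounded to integer camera counts (clamped at zero). With
#' `poisson_noise = FALSE` and `read_noise_sd = 0` the render is the exact
#' noiseless expectation (unrounded).
#'
#' @param scene a [synthetic_scene()].
#' @return A list with `stack` (an [image_stack()] with channels `membrane`
#'   and `locus`) and `truth` (spot position um, true volume um^3, true
#'   effective radius um, true scaled depth).
#' @export
render_nucleus_stack <- function(scene) {
  validate_scene(scene)
  withr::with_seed(scene$seed, {
    d <- scene$grid_shape
    vox <- scene$voxel_size
    cx <- axis_centers(d[1], vox[1])
    cy <- axis_centers(d[2], vox[2])
    cz <- axis_centers(d[3], vox[3])

    # signed distance to the ellipsoid surface on the voxel grid; first-order
    # estimate d ~ (rho - 1)/|grad rho| (exact for spheres, tight for the
    # thin shells rendered here)
    X <- (cx - scene$nucleus_center[1]) / scene$nucleus_radii[1]
    Y <- (cy - scene$nucleus_center[2]) / scene$nucleus_radii[2]
    Z <- (cz - scene$nucleus_center[3]) / scene$nucleus_radii[3]
    rho <- sqrt(outer(outer(X^2, Y^2, `+`), Z^2, `+`))
    gx2 <- (X / scene$nucleus_radii[1])^2
    gy2 <- (Y / scene$nucleus_radii[2])^2
    gz2 <- (Z / scene$nucleus_radii[3])^2
    gnorm <- sqrt(outer(outer(gx2, gy2, `+`), gz2, `+`)) / pmax(rho, 1e-12)
    dist_surf <- (rho - 1) / pmax(gnorm, 1e-12)

    # Shell indicator convolved with the PSF, computed as the exact 1D
    # profile along the surface normal (slab * isotropic Gaussian = erf
    # difference; planar approximation, exact up to O(sigma^2/R) curvature
    # terms) followed by the residual anisotropic blur. Evaluating the
    # binary indicator on the voxel grid instead would alias badly: the
    # shell is thinner than the z spacing, so pole caps land on or between
    # z-planes depending on alignment.
    s_iso <- min(scene$psf_sigma_xy, scene$psf_sigma_z)
    th <- scene$shell_thickness / 2
    membrane <- array(0, dim(dist_surf))
    near <- abs(dist_surf) < th + 5 * s_iso # profile is ~0 farther out
    membrane[near] <- stats::pnorm((dist_surf[near] + th) / s_iso) -
      stats::pnorm((dist_surf[near] - th) / s_iso)
    extra_xy <- sqrt(max(scene$psf_sigma_xy^2 - s_iso^2, 0))
    extra_z <- sqrt(max(scene$psf_sigma_z^2 - s_iso^2, 0))
    if (extra_xy > 1e-9) {
      membrane <- conv_axis(membrane, gauss_kernel(extra_xy, vox[1]), 1L)
      membrane <- conv_axis(membrane, gauss_kernel(extra_xy, vox[2]), 2L)
    }
    if (extra_z > 1e-9)
      membrane <- conv_axis(membrane, gauss_kernel(extra_z, vox[3]), 3L)
    mx <- max(membrane)
    if (mx > 0) membrane <- membrane / mx
    membrane <- scene$membrane_amplitude * membrane + scene$background

    # spot position: from the center along `direction`, at scaled depth s
    dir <- scene$spot_direction
    if (identical(dir, "random")) {
      v <- rnorm(3)
      dir <- v / sqrt(sum(v^2))
    } else {
      dir <- as.numeric(dir)
      dir <- dir / sqrt(sum(dir^2))
    }
    r_eff <- prod(scene$nucleus_radii)^(1 / 3)
    target <- scene$spot_scaled_depth
    k_surf <- 1 / sqrt(sum((dir / scene$nucleus_radii)^2))
    if (target <= 0) {
      kk <- k_surf
    } else if (all(scene$nucleus_radii == scene$nucleus_radii[1])) {
      kk <- (1 - target) * scene$nucleus_radii[1]
    } else {
      dep <- function(k) -ellipsoid_signed_distance(k * dir,
                                                    scene$nucleus_radii) / r_eff
      kk <- stats::uniroot(function(k) dep(k) - target, c(0, k_surf),
                           tol = 1e-12)$root
    }
    spot <- scene$nucleus_center + kk * dir
    s_true <- -ellipsoid_signed_distance(matrix(spot - scene$nucleus_center, 1),
                                         scene$nucleus_radii) / r_eff

    gx <- exp(-(cx - spot[1])^2 / (2 * scene$psf_sigma_xy^2))
    gy <- exp(-(cy - spot[2])^2 / (2 * scene$psf_sigma_xy^2))
    gz <- exp(-(cz - spot[3])^2 / (2 * scene$psf_sigma_z^2))
    locus <- scene$spot_amplitude * outer(outer(gx, gy), gz) + scene$background

    noisy <- scene$poisson_noise || scene$read_noise_sd > 0
    apply_noise <- function(a) {
      if (scene$poisson_noise) a <- array(rpois(length(a), a), dim(a))
      if (scene$read_noise_sd > 0)
        a <- a + array(rnorm(length(a), 0, scene$read_noise_sd), dim(a))
      if (noisy) a <- round(pmax(a, 0)) # camera digitization
      a
    }
    membrane <- apply_noise(membrane)
    locus <- apply_noise(locus)

    truth <- list(spot_position = spot,
                  true_volume = 4 / 3 * pi * prod(scene$nucleus_radii),
                  true_effective_radius = r_eff,
                  true_scaled_depth = as.numeric(s_true))
    list(stack = image_stack(list(membrane = membrane, locus = locus), vox),
         truth = truth)
  })
}

#' Sample scaled locus positions in the unit ball
#'
#' Cohort generator for position analyses: `uniform_volume` draws points
#' uniformly in the unit ball; `periphery_biased` draws scaled depth s from
#' an exponential with the given scale truncated to `[0, 1]` and a uniform
#' direction, concentrating points near the surface as envelope-tethered
#' loci are.
#'
#' @param n number of points (>= 1).
#' @param mode `"uniform_volume"` or `"periphery_biased"`.
#' @param depth_scale scale of the truncated exponential in s
#'   (periphery_biased only); must be > 0.
#' @param seed integer seed.
#' @return A data frame with unit-ball coordinates `x, y, z`, radius `r` and
#'   scaled depth `s = 1 - r`.
#' @export
sample_locus_positions <- function(n, mode = c("uniform_volume", "periphery_biased"),
                                   depth_scale = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  if (mode == "periphery_biased" && depth_scale <= 0)
    stop("depth_scale must be > 0")
  withr::with_seed(as.integer(seed), {
    v <- matrix(rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    if (mode == "uniform_volume") {
      r <- runif(n)^(1 / 3)
    } else {
      u <- runif(n)
      s <- -depth_scale * log(1 - u * (1 - exp(-1 / depth_scale)))
      r <- 1 - s
    }
    data.frame(x = v[, 1] * r, y = v[, 2] * r, z = v[, 3] * r,
               r = r, s = 1 - r)
  })
}

#' Generate a genomic interval fixture with planted near-peak features
#'
#' Builds `n_features` features and `n_peaks` peaks on the given chromosomes
#' such that exactly `round(planted_fraction * n_features)` features have a
#' peak within `threshold_bp`, and every other feature is at least
#' `2 * threshold_bp` from all peaks. The layout is verified internally by a
#' full distance scan before returning.
#'
#' @param n_features,n_peaks counts; `n_peaks` must be at least the planted
#'   count.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param planted_fraction fraction of features given a nearby peak, in
#'   `[0, 1]`.
#' @param threshold_bp proximity threshold (bp).
#' @param seed integer seed.
#' @return list with `features`, `peaks` (interval tables) and `truth`
#'   (data frame: `name`, `near`).
#' @export
make_interval_fixture <- function(n_features, n_peaks, chrom_lengths,
                                  planted_fraction = 0.5, threshold_bp = 600,
                                  seed = 1L) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must lie in [0, 1]")
  n_near <- round(planted_fraction * n_features)
  if (n_peaks < n_near)
    stop("n_peaks must be at least the planted count ", n_near)
  withr::with_seed(as.integer(seed), {
    feat_len <- 1000L
    peak_len <- 200L
    # slot pitch guarantees planted peaks can never be near a neighbor
    pitch <- feat_len + 2L * (2L * threshold_bp + peak_len) + 1000L
    caps <- pmax(0L, floor((chrom_lengths - pitch) / pitch))
    if (sum(caps) < n_features + n_peaks - n_near)
      stop("chromosomes too short for ", n_features, " features and ",
           n_peaks, " peaks at the required separation")
    slots <- data.frame(
      chrom = rep(names(chrom_lengths), caps),
      start = unlist(lapply(caps, function(k) if (k > 0) (seq_len(k) - 1L) * pitch + 500L
                            else integer())),
      stringsAsFactors = FALSE)
    use <- sample(nrow(slots), n_features + (n_peaks - n_near))
    fslots <- slots[use[seq_len(n_features)], , drop = FALSE]
    dslots <- slots[use[-seq_len(n_features)], , drop = FALSE]
    near <- rep(FALSE, n_features)
    if (n_near > 0) near[sample(n_features, n_near)] <- TRUE
    features <- intervals(data.frame(
      chrom = fslots$chrom, start = fslots$start,
      end = fslots$start + feat_len,
      name = sprintf("feat%03d", seq_len(n_features)),
      stringsAsFactors = FALSE))
    peaks <- list()
    for (i in which(near)) {
      gap <- sample.int(threshold_bp, 1) - 1L
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = fslots$chrom[i], start = fslots$start[i] + feat_len + gap,
        end = fslots$start[i] + feat_len + gap + peak_len,
        stringsAsFactors = FALSE)
    }
    if (nrow(dslots) > 0) {
      # decoy peaks live in the reserved band past the feature slot, at
      # >= 2 * threshold from the slot's own (absent) feature position
      for (i in seq_len(nrow(dslots))) {
        st <- dslots$start[i] + feat_len + 2L * threshold_bp + 200L
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = dslots$chrom[i], start = st, end = st + peak_len,
          stringsAsFactors = FALSE)
      }
    }
    peaks <- do.call(rbind, peaks)
    peaks$name <- sprintf("peak%03d", seq_len(nrow(peaks)))
    peaks <- intervals(peaks)
    truth <- data.frame(name = features$name, near = near,
                        stringsAsFactors = FALSE)
    # verify layout by brute-force scan
    gap_min <- vapply(seq_len(nrow(features)), function(i) {
      g <- Inf
      for (j in seq_len(nrow(peaks)))
        g <- min(g, interval_gap(features[i, ], peaks[j, ]))
      g
    }, 0)
    stopifnot(all((gap_min <= threshold_bp) == near),
              all(gap_min[!near] >= 2 * threshold_bp))
    list(features = features, peaks = peaks, truth = truth)
  })
}

#' Simulate a fluctuation-assay plating table
#'
#' Each culture contributes a selective-plate colony count drawn
#' `Poisson(true_rate * cells_plated_selective)` and a permissive-plate count
#' drawn `Poisson(cells_plated_permissive)`; the plating dilutions are
#' recorded alongside, so the rate estimator in [rate_from_plating()] can be
#' tested against the planted rate.
#'
#' Defaults model the assay protocol: a ~5 mL saturated culture of ~1e8
#' cells/mL (5e8 cells) plated at 1:100 on the selective drug and 1:1e7 on
#' rich medium, i.e. 5e6 and 50 cells deposited respectively, giving
#' permissive plates in the comfortably countable range.
#'
#' @param true_rate per-cell event rate (>= 0).
#' @param cells_plated_selective expected cells deposited on the selective
#'   plate.
#' @param cells_plated_permissive expected cells deposited on the permissive
#'   plate.
#' @param dilution_selective,dilution_permissive plating dilutions in (0, 1].
#' @param n_cultures number of parallel cultures.
#' @param genotype label recorded on every row.
#' @param seed integer seed.
#' @return A `count_table` data frame.
#' @export
make_colony_fixture <- function(true_rate, cells_plated_selective = 5e6,
                                cells_plated_permissive = 50,
                                dilution_selective = 1e-2,
                                dilution_permissive = 1e-7,
                                n_cultures = 24, genotype = "WT", seed = 1L) {
  if (true_rate < 0) stop("true_rate must be >= 0")
  if (cells_plated_selective <= 0 || cells_plated_permissive <= 0)
    stop("plated cell numbers must be positive")
  if (n_cultures < 1) stop("n_cultures must be >= 1")
  withr::with_seed(as.integer(seed), {
    df <- data.frame(
      sample_id = sprintf("%s_%03d", genotype, seq_len(n_cultures)),
      genotype = genotype,
      colonies_selective = rpois(n_cultures, true_rate * cells_plated_selective),
      colonies_permissive = rpois(n_cultures, cells_plated_permissive),
      dilution_selective = dilution_selective,
      dilution_permissive = dilution_permissive,
      stringsAsFactors = FALSE)
    class(df) <- c("count_table", "data.frame")
    df
  })
}
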