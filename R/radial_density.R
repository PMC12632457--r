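#' Scaled depth of a fitted spot inside a reconstructed nucleus
#'
#' `s = d / R_eff`, with `d` the distance from the fitted spot center to the
#' nearest point of the envelope mesh and `R_eff` the volume-derived
#' effective radius. Interior points get positive s (s = 0 on the envelope,
#' s = 1 at the center of a sphere); exterior points get negative s and an
#' `exterior` flag so the density stage can exclude and count them.
#'
#' @param spot a `spot_fit` (or numeric length-3 position, um).
#' @param nucleus a `nucleus_model`; must be converged.
#' @return One-row data frame: `s`, `distance_um`, `exterior`.
#' @export
scaled_depth <- function(spot, nucleus) {
  stopifnot(inherits(nucleus, "nucleus_model"))
  if (!nucleus$converged) stop("nucleus model not converged; spot excluded")
  p <- if (inherits(spot, "spot_fit")) spot$center else as.numeric(spot)
  nd <- nearest_surface_distance(p, nucleus$mesh)
  s <- ifelse(nd$inside, nd$distance, -nd$distance) / nucleus$effective_radius
  data.frame(s = s, distance_um = nd$distance, exterior = !nd$inside)
}

#' Radial probability density of scaled depth
#'
#' Partitions the unit nucleus into concentric shells of scaled width `w`
#' and converts the per-shell probability `p = c/N` into a probability
#' density by dividing by the scaled shell volume:
#' `f = p / (4 pi r_mid^2 w)` with `r_mid = 1 - s_mid` the scaled radial
#' coordinate at the shell midpoint. The Poisson counting uncertainty on c
#' propagates to `sigma_f = sqrt(c) / (N * 4 pi * r_mid^2 * w)`, so
#' `sigma_f / f = 1 / sqrt(c)` in every occupied bin. `s = 1` falls in the
#' innermost shell (closure of the last interval). The innermost shell has a
#' tiny scaled volume, so its f and sigma_f amplify count noise; they are
#' reported as computed.
#'
#' @param s_values scaled depths, all in `[0, 1]`.
#' @param w shell width; `1/w` must be an integer (default 0.1, ten shells).
#' @param n_excluded count of upstream exclusions carried into the result.
#' @return A `radial_density` object: data frame of bins (`s_lo`, `s_hi`,
#'   `s_mid`, `r_mid`, `c`, `N`, `p`, `f`, `sigma_f`) plus attributes.
#' @export
radial_density <- function(s_values, w = 0.1, n_excluded = 0L) {
  s_values <- as.numeric(s_values)
  if (length(s_values) == 0) stop("empty input: no scaled depths")
  if (any(!is.finite(s_values)) || any(s_values < 0) || any(s_values > 1))
    stop("all scaled depths must lie in [0, 1]; exclude exterior spots upstream")
  nb <- 1 / w
  if (abs(nb - round(nb)) > 1e-9) stop("1/w must be an integer number of shells")
  nb <- as.integer(round(nb))
  bin <- pmin(floor(s_values / w) + 1L, nb) # s = 1 -> innermost shell
  c_bin <- tabulate(bin, nbins = nb)
  N <- length(s_values)
  s_lo <- (seq_len(nb) - 1L) * w
  s_hi <- seq_len(nb) * w
  s_mid <- (s_lo + s_hi) / 2
  r_mid <- 1 - s_mid
  p <- c_bin / N
  f <- p / (4 * pi * r_mid^2 * w)
  sigma_f <- density_uncertainty(c_bin, N, s_mid, w)
  out <- data.frame(s_lo = s_lo, s_hi = s_hi, s_mid = s_mid, r_mid = r_mid,
                    c = c_bin, N = N, p = p, f = f, sigma_f = sigma_f)
  structure(list(bins = out, w = w, N = N, n_excluded = as.integer(n_excluded)),
            class = "radial_density")
}

#' Poisson uncertainty of the shell probability density
#'
#' `sigma_f = sqrt(c) / (N * 4 pi * (1 - s_mid)^2 * w)`: the counting
#' uncertainty `sqrt(c)` on the shell count propagated through
#' `f = (c/N) / (4 pi r^2 w)`.
#'
#' @param c shell count(s), >= 0.
#' @param N total count, > 0.
#' @param s_mid shell midpoint scaled depth(s).
#' @param w shell width.
#' @return `sigma_f`, same length as `c`.
#' @export
density_uncertainty <- function(c, N, s_mid, w) {
  stopifnot(N > 0, all(c >= 0))
  sqrt(c) / (N * 4 * pi * (1 - s_mid)^2 * w)
}

#' @export
print.radial_density <- function(x, ...) {
  cat("radial_density: N =", x$N, "loci in", nrow(x$bins), "shells (w =",
      x$w, ")")
  if (x$n_excluded > 0) cat(";", x$n_excluded, "excluded")
  cat("\n")
  print(format(x$bins, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
plot.radial_density <- function(x, add = FALSE, col = "black",
                                ylim = NULL, ...) {
  b <- x$bins
  if (is.null(ylim)) ylim <- c(0, max(b$f + b$sigma_f, 3 / (4 * pi)) * 1.1)
  if (!add)
    plot(b$s_mid, b$f, type = "b", pch = 19, col = col, xlim = c(0, 1),
         ylim = ylim, xlab = "scaled depth s from nuclear envelope",
         ylab = "probability density f", ...)
  else
    lines(b$s_mid, b$f, type = "b", pch = 19, col = col, ...)
  ok <- b$sigma_f > 0
  if (any(ok))
    arrows(b$s_mid[ok], b$f[ok] - b$sigma_f[ok], b$s_mid[ok],
           b$f[ok] + b$sigma_f[ok], angle = 90, code = 3, length = 0.03,
           col = col)
  invisible(x)
}

#' Pooled radial density over a cohort of cells
#'
#' Matches spot fits with nucleus models cell by cell, computes scaled
#' depths, excludes (and counts) cells with a non-converged nucleus or spot
#' and spots that land outside the envelope, and pools the remaining depths
#' into one [radial_density()]. Depths marginally above 1 (possible under
#' mesh error for near-central spots) are clamped to 1 up to `s_slack`,
#' beyond which the cell is excluded.
#'
#' @param spots list of `spot_fit` (or NULL entries for cells with no spot).
#' @param nuclei list of `nucleus_model`, same length.
#' @param w shell width.
#' @param s_slack tolerated overshoot of s above 1 before exclusion.
#' @return A `radial_density` with an extra `cells` attribute (per-cell
#'   table: `sample`, `s`, `included`, `reason`).
#' @export
cohort_density <- function(spots, nuclei, w = 0.1, s_slack = 0.05) {
  stopifnot(length(spots) == length(nuclei))
  n <- length(spots)
  tab <- data.frame(sample = seq_len(n), s = NA_real_,
                    included = FALSE, reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- spots[[i]]; nu <- nuclei[[i]]
    if (is.null(sp) || (inherits(sp, "spot_fit") && !sp$converged)) {
      tab$reason[i] <- "no converged spot"; next
    }
    if (is.null(nu) || !nu$converged) {
      tab$reason[i] <- "nucleus not converged"; next
    }
    sd_ <- scaled_depth(sp, nu)
    tab$s[i] <- sd_$s
    if (sd_$exterior) {
      tab$reason[i] <- "exterior spot"
    } else if (sd_$s > 1 + s_slack) {
      tab$reason[i] <- "depth overflow"
    } else {
      tab$s[i] <- min(sd_$s, 1)
      tab$included[i] <- TRUE
      tab$reason[i] <- "ok"
    }
  }
  s_use <- tab$s[tab$included]
  if (length(s_use) == 0) stop("zero usable cells in cohort")
  rd <- radial_density(s_use, w = w, n_excluded = sum(!tab$included))
  attr(rd, "cells") <- tab
  rd
}

#' Cell-level bootstrap of the shell density uncertainties
#'
#' Nonparametric check of the Poisson `sigma_f`: resamples cells with
#' replacement, recomputes `f` per shell, and returns the bootstrap SD of f
#' alongside the analytic `sigma_f`.
#'
#' @param s_values scaled depths in `[0, 1]`.
#' @param w shell width.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return Data frame: `s_mid`, `c`, `sigma_f`, `sigma_boot`.
#' @export
bootstrap_density_uncertainty <- function(s_values, w = 0.1, n_boot = 2000,
                                          seed = 1L) {
  rd <- radial_density(s_values, w)
  N <- length(s_values)
  nb <- nrow(rd$bins)
  withr::with_seed(as.integer(seed), {
    fs <- matrix(0, n_boot, nb)
    for (b in seq_len(n_boot)) {
      rs <- s_values[sample.int(N, N, replace = TRUE)]
      fs[b, ] <- radial_density(rs, w)$bins$f
    }
    data.frame(s_mid = rd$bins$s_mid, c = rd$bins$c,
               sigma_f = rd$bins$sigma_f,
               sigma_boot = apply(fs, 2, sd))
  })
}
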