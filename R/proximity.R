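#' Gap between two genomic intervals
#'
#' Distance in bp between the bodies of two 0-based half-open intervals:
#' 0 when they overlap or are book-ended, `Inf` when on different
#' chromosomes, otherwise the number of bases separating them. Strand is
#' ignored.
#'
#' @param a,b one-row interval records (data frames or lists with `chrom`,
#'   `start`, `end`).
#' @return Gap in bp, or `Inf`.
#' @export
interval_gap <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  max(0, max(a$start, b$start) - min(a$end, b$end))
}

#' Nearest-peak distance for every feature
#'
#' Per-chromosome sorted sweep, exact: for each feature the minimum body-to-
#' body gap over all peaks on the same chromosome (`Inf` when there are
#' none). Results are independent of input record order.
#'
#' @param features,peaks interval tables ([intervals()]).
#' @return Numeric vector of nearest distances, one per feature row.
#' @export
nearest_peak <- function(features, peaks) {
  nf <- nrow(features)
  out <- rep(Inf, nf)
  if (nf == 0 || nrow(peaks) == 0) return(out)
  for (chr in unique(features$chrom)) {
    fi <- which(features$chrom == chr)
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (nrow(pk) == 0) next
    ord <- order(pk$start, pk$end)
    ps <- pk$start[ord]
    pe_cummax <- cummax(pk$end[ord])
    for (i in fi) {
      fs <- features$start[i]; fe <- features$end[i]
      d <- Inf
      # peaks starting inside or before the feature body
      k <- findInterval(fe - 1L, ps) # last peak with start <= fe - 1 (< fe)
      if (k > 0) {
        far_end <- pe_cummax[k]
        d <- if (far_end > fs) 0 else min(d, fs - far_end)
      }
      # nearest peak starting at or beyond the feature end
      k2 <- findInterval(fe - 1L, ps) + 1L
      if (k2 <= length(ps)) d <- min(d, ps[k2] - fe)
      out[i] <- d
    }
  }
  out
}

#' Fraction of features with a peak within a distance threshold
#'
#' The peak-proximity statistic: counts features whose nearest peak lies
#' within `threshold` bp (inclusive; overlap counts as distance 0) and
#' reports the fraction. Run separately on a feature class and a background
#' class to compare prevalences.
#'
#' @param features,peaks interval tables.
#' @param threshold bp, >= 0 (default 600).
#' @return A `proximity_result`: `per_feature` (name, chrom,
#'   nearest_distance, within_threshold), `n_within`, `n_total`, `fraction`,
#'   `threshold`.
#' @export
proximity_fraction <- function(features, peaks, threshold = 600) {
  if (nrow(features) == 0) stop("empty feature list")
  if (threshold < 0) stop("threshold must be >= 0")
  d <- nearest_peak(features, peaks)
  within <- d <= threshold
  per <- data.frame(name = features$name, chrom = features$chrom,
                    nearest_distance = d, within_threshold = within,
                    stringsAsFactors = FALSE)
  structure(list(per_feature = per, n_within = sum(within),
                 n_total = nrow(features),
                 fraction = sum(within) / nrow(features),
                 threshold = threshold),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("proximity_result: %d/%d features (%.1f%%) with a peak within %s bp\n",
              x$n_within, x$n_total, 100 * x$fraction,
              format(x$threshold)))
  invisible(x)
}
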