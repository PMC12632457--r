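#' Multi-channel 3D image stack
#'
#' Container for a microscopy z-stack: one 3D array of photon counts per
#' channel plus the physical voxel size. Arrays are indexed `[x, y, z]`; the
#' center of voxel `(i, j, k)` is at `((i-0.5)*dx, (j-0.5)*dy, (k-0.5)*dz)`
#' micrometres.
#'
#' @param channels named list of 3D numeric arrays with identical dimensions.
#' @param voxel_size numeric length-3, voxel pitch in um `(dx, dy, dz)`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)))
    stop("`channels` must be a non-empty named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array")
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), TRUE)))
    stop("all channels must share dimensions")
  if (any(dims[[1]] < 1)) stop("all dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (um)")
  for (nm in names(channels)) {
    x <- channels[[nm]]
    if (any(!is.finite(x)) || any(x < 0))
      stop("channel '", nm, "' has non-finite or negative intensities")
  }
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("image_stack:", paste(d, collapse = " x "), "voxels,",
      length(x$channels), "channel(s) [", paste(names(x$channels), collapse = ", "),
      "]\n  voxel size (um):", paste(signif(x$voxel_size, 4), collapse = " x "), "\n")
  invisible(x)
}

stack_dim <- function(stack) dim(stack$channels[[1]])

#' Write an image stack as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...),
#' matching standard multi-series microscopy exports. Intensities are stored
#' as 16-bit unsigned integers (camera counts); values must lie in
#' `[0, 65535]` after rounding. Voxel size and channel layout go into a
#' sidecar JSON at `<path>.json` because baseline TIFF has no z-spacing tag.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack_dim(stack)
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- round(stack$channels[[ch]])
    if (any(a < 0) || any(a > 65535))
      stop("intensities outside the 16-bit range [0, 65535]")
    for (k in seq_len(d[3])) {
      # TIFF pages are row-major images: rows = y, cols = x
      pages[[length(pages) + 1L]] <- t(a[, , k]) / 65535
    }
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  sidecar <- list(voxel_size_um = as.numeric(stack$voxel_size),
                  channels = names(stack$channels),
                  n_z = d[3], n_x = d[1], n_y = d[2])
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF z-stack
#'
#' Reads a TIFF written by [write_stack()] (or any multi-page z-series),
#' restoring integer photon counts. Voxel size comes from the JSON sidecar
#' unless overridden.
#'
#' @param path TIFF path.
#' @param voxel_size_override optional numeric length-3 voxel size (um) used
#'   when no sidecar is present (or to override it).
#' @param channel_names optional channel names when no sidecar is present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size_override = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop("not a z-stack: file has a single page")
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else NULL
  voxel <- voxel_size_override %||%
    (if (!is.null(side)) as.numeric(unlist(side$voxel_size_um)) else NULL)
  if (is.null(voxel))
    stop("voxel size unknown: no sidecar JSON and no `voxel_size_override`")
  chans <- if (!is.null(side)) unlist(side$channels) else channel_names
  if (is.null(chans)) chans <- "channel1"
  n_z <- if (!is.null(side)) side$n_z else length(pages) %/% length(chans)
  if (length(pages) != n_z * length(chans))
    stop("page count ", length(pages), " does not match ", length(chans),
         " channel(s) x ", n_z, " slices")
  out <- list()
  pg <- 1L
  for (ch in chans) {
    slices <- lapply(seq_len(n_z), function(k) {
      m <- pages[[pg + k - 1L]]
      t(m) # back to [x, y]
    })
    pg <- pg + n_z
    a <- array(0, c(dim(slices[[1]]), n_z))
    for (k in seq_len(n_z)) a[, , k] <- slices[[k]]
    out[[ch]] <- a
  }
  image_stack(out, voxel)
}
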