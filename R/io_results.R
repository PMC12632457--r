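#' Write result tables plus a JSON run manifest
#'
#' Serializes each named data frame as CSV under `dir` and writes
#' `manifest.json` recording the configuration, seeds, package version and
#' any exclusion counts the caller supplies. Numeric values survive a CSV
#' round trip to at least 12 significant digits. The manifest carries no
#' timestamp so repeated runs with one configuration are byte-identical.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @param manifest list of run metadata (config, seed, exclusions, ...).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, dir, manifest = list()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("cannot write to '", dir, "'")
  files <- character()
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) {
      out <- vapply(v, function(x) format(x, digits = 15, scientific = NA), "")
      out[is.na(v)] <- NA_character_
      out
    })
    write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest$package_version <- as.character(utils::packageVersion("periloc"))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mf))
}

#' Write a triangle mesh as ASCII PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(v, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
  writeLines(apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}
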