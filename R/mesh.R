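#' Closed triangulated surface mesh
#'
#' @param vertices numeric matrix n x 3 (um).
#' @param faces integer matrix m x 3 of 1-based vertex indices, consistently
#'   outward-oriented.
#' @param validate check closedness, orientation and volume sign.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  if (validate) validate_mesh(m)
  m
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (any(f < 1) || any(f > nrow(v))) stop("face index out of range")
  # closed 2-manifold: every undirected edge in exactly two faces,
  # consistent orientation: every directed edge appears exactly once
  dir_edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(dir_edges[, 1], dir_edges[, 2])
  if (anyDuplicated(key)) stop("inconsistent orientation: repeated directed edge")
  ukey <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
                pmax(dir_edges[, 1], dir_edges[, 2]))
  cnt <- table(ukey)
  if (any(cnt != 2)) stop("mesh is not closed: boundary or non-manifold edges")
  ne <- length(cnt)
  if (nrow(v) - ne + nrow(f) != 2) stop("Euler characteristic is not 2")
  areas <- face_areas(mesh)
  if (any(areas <= 1e-14)) stop("degenerate (zero-area) face")
  if (mesh_volume_signed(mesh) <= 0)
    stop("negative signed volume: faces must be outward-oriented")
  invisible(mesh)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

mesh_volume_signed <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Enclosed volume of a closed mesh
#'
#' Sum of signed tetrahedra spanned by the origin and each face; positive
#' for an outward-oriented closed surface.
#'
#' @param mesh a `surface_mesh`.
#' @return Volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  validate_mesh(mesh)
  mesh_volume_signed(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Icosphere mesh
#'
#' Regular icosahedron subdivided `subdivision_level` times (each level
#' splits every face in four, midpoints projected to the sphere), scaled and
#' translated. Level 3 gives 642 vertices / 1280 faces.
#'
#' @param subdivision_level non-negative integer.
#' @param radius sphere radius (um).
#' @param center sphere center (um).
#' @return A `surface_mesh`.
#' @export
icosphere <- function(subdivision_level = 3L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision_level)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      idx <- length(vlist)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(cc, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  verts <- sweep(v * radius, 2, center, `+`)
  surface_mesh(verts, f)
}

# undirected edge list (2-col) and CSR vertex neighborhood of a mesh
mesh_topology <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  n <- nrow(mesh$vertices)
  adj <- split(c(e[, 2], e[, 1]),
               factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
  adj <- lapply(adj, function(x) sort(unique(x)))
  deg <- vapply(adj, length, 0L)
  list(edges = e, offsets = c(0L, cumsum(deg)),
       indices = unlist(adj, use.names = FALSE))
}

#' Distance from points to the nearest point of a mesh surface
#'
#' Exact minimum point-to-triangle distance over all faces (vertex, edge and
#' interior cases handled); interiority from the generalized winding number.
#'
#' @param points numeric vector (one point) or n x 3 matrix, um.
#' @param mesh a `surface_mesh`.
#' @return Data frame with `distance` (um) and `inside` (logical); a single
#'   point yields a one-row data frame.
#' @export
nearest_surface_distance <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  d <- cpp_point_mesh_distance(points, mesh$vertices,
                               mesh$faces - 1L)
  wn <- cpp_winding_number(points, mesh$vertices, mesh$faces - 1L)
  data.frame(distance = d, inside = wn > 0.5)
}
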