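#' Triangulated surface meshes
#'
#' A `surface_mesh` is a list with `vertices` (n x 3 numeric matrix,
#' millimetres) and `faces` (m x 3 integer matrix of 1-based vertex
#' indices). A `labeled_surface_mesh` additionally carries a per-face
#' anatomical region factor (`aneurysm`, `neck_band`, `parent_roi`,
#' `extension`, `other`) and the neck curve (a closed polyline separating
#' the sac from the parent vessel).
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

mesh_regions <- c("aneurysm", "neck_band", "parent_roi", "extension", "other")

#' Attach region labels and a neck curve to a mesh
#'
#' @param mesh A `surface_mesh`.
#' @param face_region Character or factor of length `nrow(mesh$faces)` with
#'   levels among aneurysm, neck_band, parent_roi, extension, other.
#' @param neck_curve k x 3 matrix of points tracing the closed neck curve.
#' @return A `labeled_surface_mesh`.
#' @export
labeled_surface_mesh <- function(mesh, face_region, neck_curve = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  face_region <- factor(as.character(face_region), levels = mesh_regions)
  if (length(face_region) != nrow(mesh$faces))
    stop("face_region length must equal the number of faces")
  if (anyNA(face_region))
    stop("every face must carry exactly one known region label")
  mesh$face_region <- face_region
  mesh$neck_curve <- if (is.null(neck_curve)) NULL else as.matrix(neck_curve)
  class(mesh) <- c("labeled_surface_mesh", "surface_mesh")
  mesh
}

#' @export
print.labeled_surface_mesh <- function(x, ...) {
  cat(sprintf("labeled_surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  print(table(x$face_region))
  invisible(x)
}

# ---- mesh measures ---------------------------------------------------------

face_corner <- function(mesh, j) mesh$vertices[mesh$faces[, j], , drop = FALSE]

#' Per-face areas, normals, centroids; total area and enclosed volume
#'
#' `mesh_volume` uses the divergence theorem and assumes a consistently
#' outward-oriented watertight mesh.
#'
#' @param mesh A `surface_mesh`.
#' @return `mesh_face_areas`: numeric vector (mm^2); `mesh_face_normals` and
#'   `mesh_face_centroids`: m x 3 matrices; `mesh_area`, `mesh_volume`:
#'   scalars (mm^2, mm^3).
#' @export
mesh_face_areas <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  cr <- vec_cross(b - a, c - a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname mesh_face_areas
#' @export
mesh_face_normals <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  cr <- vec_cross(b - a, c - a)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

#' @rdname mesh_face_areas
#' @export
mesh_face_centroids <- function(mesh) {
  (face_corner(mesh, 1) + face_corner(mesh, 2) + face_corner(mesh, 3)) / 3
}

#' @rdname mesh_face_areas
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' @rdname mesh_face_areas
#' @export
mesh_volume <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  sum(rowSums(a * vec_cross(b, c))) / 6
}

#' Per-vertex barycentric areas (one third of incident triangle areas)
#'
#' @param mesh A `surface_mesh`.
#' @return Numeric vector of length `nrow(mesh$vertices)` (mm^2).
#' @export
mesh_vertex_areas <- function(mesh) {
  fa <- mesh_face_areas(mesh) / 3
  va <- numeric(nrow(mesh$vertices))
  s <- rowsum(rep(fa, 3), as.vector(mesh$faces))
  va[as.integer(rownames(s))] <- s
  va
}

#' Area-weighted per-vertex outward normals
#' @param mesh A `surface_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  fn <- mesh_face_normals(mesh) * mesh_face_areas(mesh)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  s <- rowsum(fn[rep(seq_len(nrow(fn)), 3), , drop = FALSE],
              as.vector(mesh$faces))
  vn[as.integer(rownames(s)), ] <- s
  n <- sqrt(rowSums(vn^2))
  n[n == 0] <- 1
  vn / n
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Topology checks
#'
#' `mesh_is_watertight` requires every undirected edge to be shared by
#' exactly two faces; `mesh_euler` returns V - E + F (2 for a closed
#' surface of genus 0).
#'
#' @param mesh A `surface_mesh`.
#' @return Logical / integer.
#' @export
mesh_is_watertight <- function(mesh) {
  e <- mesh_edge_table(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' @rdname mesh_is_watertight
#' @export
mesh_euler <- function(mesh) {
  e <- unique(mesh_edge_table(mesh))
  nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces)
}

#' Vertex adjacency as a sparse matrix
#' @param mesh A `surface_mesh`.
#' @return A symmetric sparse 0/1 `Matrix::sparseMatrix`.
#' @export
mesh_adjacency <- function(mesh) {
  e <- unique(mesh_edge_table(mesh))
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

#' Apply a rigid (or affine) 4 x 4 transform to a mesh
#' @param mesh A `surface_mesh`.
#' @param transform 4 x 4 homogeneous transform matrix.
#' @return Transformed mesh (labels preserved; neck curve transformed too).
#' @export
transform_mesh <- function(mesh, transform) {
  stopifnot(all(dim(transform) == c(4, 4)))
  tp <- function(p) {
    sweep(p %*% t(transform[1:3, 1:3]), 2, transform[1:3, 4], "+")
  }
  mesh$vertices <- tp(mesh$vertices)
  if (!is.null(mesh$neck_curve)) mesh$neck_curve <- tp(mesh$neck_curve)
  mesh
}

#' Build a rigid 4 x 4 transform from a rotation and translation
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return 4 x 4 homogeneous matrix.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  m
}

#' Rotation matrix about an axis
#' @param axis Length-3 axis (need not be unit).
#' @param angle_deg Rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Closest points on a mesh surface
#'
#' Exact point-to-triangle projection accelerated by a uniform spatial grid.
#'
#' @param points q x 3 matrix of query points (mm).
#' @param mesh A `surface_mesh`.
#' @return List with `distance` (q), `point` (q x 3 closest surface points)
#'   and `face` (q, 1-based face index).
#' @export
mesh_closest_point <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_closest_point(points, mesh$vertices, mesh$faces)
}

#' Deterministic area-stratified surface samples
#'
#' Returns all vertices plus, for each face, enough interior points (on a
#' fixed barycentric lattice) to reach the requested density.
#'
#' @param mesh A `surface_mesh`.
#' @param density Samples per mm^2 contributed by face-interior points.
#' @return s x 3 matrix of sample points.
#' @export
sample_surface_points <- function(mesh, density = 10) {
  areas <- mesh_face_areas(mesh)
  n_extra <- pmax(0L, as.integer(ceiling(areas * density)) - 1L)
  pts <- list(mesh$vertices)
  if (any(n_extra > 0)) {
    a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
    maxn <- max(n_extra)
    # fixed low-discrepancy barycentric sequence (Kronecker lattice, folded)
    i <- seq_len(maxn)
    u <- (i * 0.7548776662466927) %% 1
    v <- (i * 0.5698402909980532) %% 1
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    keep <- which(n_extra > 0)
    for (k in i) {
      sel <- keep[n_extra[keep] >= k]
      if (!length(sel)) break
      w0 <- 1 - u[k] - v[k]
      pts[[length(pts) + 1L]] <-
        w0 * a[sel, , drop = FALSE] + u[k] * b[sel, , drop = FALSE] +
        v[k] * c[sel, , drop = FALSE]
    }
  }
  do.call(rbind, pts)
}

#' Drop vertices not referenced by any face
#' @param mesh A `surface_mesh`.
#' @return Re-indexed mesh.
#' @export
compact_mesh <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  mesh$vertices <- mesh$vertices[used, , drop = FALSE]
  mesh$faces[] <- map[mesh$faces]
  mesh
}

#' Keep the largest edge-connected face component
#' @param mesh A `surface_mesh`.
#' @return Mesh restricted to its largest connected component.
#' @export
largest_component <- function(mesh) {
  g <- igraph::graph_from_edgelist(unique(mesh_edge_table(mesh)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  keepv <- comp$membership == big
  keepf <- keepv[mesh$faces[, 1]]
  mesh$faces <- mesh$faces[keepf, , drop = FALSE]
  compact_mesh(mesh)
}
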