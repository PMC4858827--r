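# Shared fixtures. Heavier objects are cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# image volume holding -signed distance (lumen positive), isosurface level 0
sdf_volume <- function(sdf, lo, hi, spacing, pad = 1) {
  xs <- seq(lo[1] - pad, hi[1] + pad, by = spacing)
  ys <- seq(lo[2] - pad, hi[2] + pad, by = spacing)
  zs <- seq(lo[3] - pad, hi[3] + pad, by = spacing)
  gp <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  image_volume(array(-sdf(gp), c(length(xs), length(ys), length(zs))),
               spacing = rep(spacing, 3), origin = c(xs[1], ys[1], zs[1]))
}

make_sphere_mesh <- function(r = 5, spacing = 0.25, center = c(0, 0, 0)) {
  vol <- sdf_volume(function(p) sqrt(rowSums(sweep(p, 2, center)^2)) - r,
                    center - r, center + r, spacing)
  extract_surface(vol, 0)
}

make_ellipsoid_mesh <- function(axes = c(2, 1, 1.5), spacing = 0.1) {
  vol <- sdf_volume(function(p) {
    # scaled-sphere pseudo-distance: exact zero level set
    sqrt(rowSums(sweep(p, 2, axes, "/")^2)) - 1
  }, -axes, axes, spacing, pad = 0.5)
  extract_surface(vol, 0)
}

# regular triangulated square patch on z = 0, [0, L]^2, n intervals per side;
# jitter > 0 perturbs interior vertices in-plane (seeded, proportional to the
# grid step) to break the symmetric error cancellation of the uniform grid
make_flat_patch <- function(n = 16, L = 4, jitter = 0) {
  xs <- seq(0, L, length.out = n + 1)
  g <- as.matrix(expand.grid(x = xs, y = xs))
  verts <- cbind(g, 0)
  if (jitter > 0) {
    h <- L / n
    inner <- !(g[, 1] %in% range(xs) | g[, 2] %in% range(xs))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(1234)
    verts[inner, 1:2] <- verts[inner, 1:2] +
      matrix(runif(2 * sum(inner), -jitter * h, jitter * h), ncol = 2)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  id <- function(i, j) (j - 1) * (n + 1) + i
  faces <- list()
  for (j in 1:n) for (i in 1:n) {
    faces[[length(faces) + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    faces[[length(faces) + 1]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  mesh <- surface_mesh(verts, do.call(rbind, faces))
  border <- verts[, 1] %in% range(xs) | verts[, 2] %in% range(xs)
  attr(mesh, "interior") <- which(!border)
  mesh
}

# constant-in-time field from a per-vertex matrix
steady_field <- function(mesh, vmat, nt = 9, period = 0.8) {
  times <- seq(0, period, length.out = nt)
  vec <- array(0, c(nrow(vmat), 3, nt))
  for (k in seq_len(nt)) vec[, , k] <- vmat
  wss_field(mesh, times, vec)
}

default_phantom <- function() cached("phantom02", build_phantom_mesh(aneurysm_spec()))

coarse_phantom <- function() {
  cached("phantom03",
         build_phantom_mesh(aneurysm_spec(mesh_edge_length = 0.3)))
}

# uniform-Laplacian curvature proxy, used to check smoothing behaviour
curvature_proxy <- function(mesh) {
  A <- mesh_adjacency(mesh)
  W <- A / Matrix::rowSums(A)
  sqrt(rowSums((as.matrix(W %*% mesh$vertices) - mesh$vertices)^2))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
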