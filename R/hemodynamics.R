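#' Time-resolved wall shear stress field on a mesh
#'
#' @param mesh The carrier `labeled_surface_mesh`.
#' @param times Sample times (s), strictly increasing within [0, T],
#'   including both cycle endpoints for whole-cycle quadrature.
#' @param vectors Array of dimension (n_vertices, 3, n_times): per-vertex
#'   3-component WSS in Pa at each time.
#' @param t_peak_systole Cycle time of maximum inlet flow (s); must be a
#'   member of `times`.
#' @param t_end_diastole Cycle time of the end-diastolic sample (s).
#' @return A `wss_field`.
#' @export
wss_field <- function(mesh, times, vectors, t_peak_systole = times[1],
                      t_end_diastole = times[length(times)]) {
  stopifnot(inherits(mesh, "surface_mesh"))
  dv <- dim(vectors)
  if (length(dv) != 3 || dv[1] != nrow(mesh$vertices) || dv[2] != 3 ||
      dv[3] != length(times))
    stop("vectors must be (n_vertices, 3, n_times)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  for (t in c(t_peak_systole, t_end_diastole))
    if (min(abs(times - t)) > 1e-9)
      stop("t_peak_systole / t_end_diastole must be members of times")
  structure(list(mesh = mesh, times = times, vectors = vectors,
                 t_peak_systole = t_peak_systole,
                 t_end_diastole = t_end_diastole),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf(
    "wss_field: %d vertices, %d time samples over T = %.3g s\n",
    dim(x$vectors)[1], length(x$times), max(x$times)))
  cat(sprintf("  peak systole %.3g s, end diastole %.3g s\n",
              x$t_peak_systole, x$t_end_diastole))
  invisible(x)
}

time_index <- function(field, t) which.min(abs(field$times - t))

# trapezoidal integral over time of an (n x n_t) matrix -> length-n vector
trapz_rows <- function(m, times) {
  dt <- diff(times)
  w <- c(dt / 2, 0) + c(0, dt / 2)
  as.vector(m %*% w)
}

field_magnitudes <- function(vectors) {
  sqrt(vectors[, 1, , drop = FALSE]^2 + vectors[, 2, , drop = FALSE]^2 +
       vectors[, 3, , drop = FALSE]^2)[, 1, ]
}

#' Time-averaged wall shear stress (AWSS)
#'
#' Magnitude of the component-wise trapezoidal time average of the WSS
#' vector over one cycle: AWSS = |(1/T) integral WSS dt|.
#'
#' @param x A `wss_field`, or an (n, 3, n_t) array.
#' @param times Sample times when `x` is an array.
#' @return Per-vertex AWSS (Pa).
#' @export
time_average_wss <- function(x, times = NULL) {
  v <- if (inherits(x, "wss_field")) x$vectors else x
  if (inherits(x, "wss_field")) times <- x$times
  if (length(times) < 3) stop("need at least 3 time samples")
  T_ <- times[length(times)] - times[1]
  mx <- trapz_rows(v[, 1, , drop = FALSE][, 1, ], times) / T_
  my <- trapz_rows(v[, 2, , drop = FALSE][, 1, ], times) / T_
  mz <- trapz_rows(v[, 3, , drop = FALSE][, 1, ], times) / T_
  sqrt(mx^2 + my^2 + mz^2)
}

#' Oscillatory shear index (OSI)
#'
#' OSI = 0.5 (1 - |integral WSS dt| / integral |WSS| dt), the classical
#' measure of WSS directional change over the cycle: 0 for a fixed
#' direction, 0.5 for full reversal with zero mean. Clamped to [0, 0.5]
#' against round-off; vertices with identically zero WSS get OSI 0 and are
#' flagged in `attr(, "zero_wss")`.
#'
#' @inheritParams time_average_wss
#' @return Per-vertex OSI in [0, 0.5].
#' @export
compute_osi <- function(x, times = NULL) {
  v <- if (inherits(x, "wss_field")) x$vectors else x
  if (inherits(x, "wss_field")) times <- x$times
  if (length(times) < 3) stop("need at least 3 time samples")
  mean_vec <- time_average_wss(v, times)       # |mean vector| (1/T cancels)
  mag <- field_magnitudes(v)
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = dim(v)[1])
  T_ <- times[length(times)] - times[1]
  mean_mag <- trapz_rows(mag, times) / T_
  zero <- mean_mag <= 0
  osi <- numeric(length(mean_mag))
  osi[!zero] <- 0.5 * (1 - mean_vec[!zero] / mean_mag[!zero])
  osi <- pmin(0.5, pmax(0, osi))
  attr(osi, "zero_wss") <- which(zero)
  osi
}

#' Tangential surface gradient of a per-vertex scalar field
#'
#' Per-triangle linear-shape-function gradient (constant in each triangle,
#' lying in the triangle plane), averaged to vertices with triangle-area
#' weights. Degenerate zero-area triangles are excluded with a warning.
#'
#' @param mesh A `surface_mesh`.
#' @param f Numeric vector over vertices (field units).
#' @return n x 3 matrix: per-vertex tangential gradient (field units/mm).
#' @export
surface_gradient <- function(mesh, f) {
  stopifnot(length(f) == nrow(mesh$vertices))
  g <- face_gradients(mesh, matrix(f, ncol = 1))[[1]]
  area <- attr(g, "area")
  accumulate_to_vertices(mesh, g, area)
}

# shared per-face gradient machinery: returns a list of m x 3 matrices,
# one per column of fmat
face_gradients <- function(mesh, fmat, warn = TRUE) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  e0 <- c - b; e1 <- a - c; e2 <- b - a
  n <- vec_cross(e2, -e1)                      # (b-a) x (c-a)
  two_area <- sqrt(rowSums(n^2))
  # degeneracy is judged relative to the typical facet so the exclusion
  # set is invariant under uniform rescaling of the mesh
  bad <- two_area < 1e-6 * median(two_area)
  if (any(bad)) {
    if (warn)
      warning(sprintf("%d degenerate zero-area triangles excluded", sum(bad)))
    two_area[bad] <- 1
  }
  nh <- n / two_area
  # grad f = (f_a * (n x e0) + f_b * (n x e1) + f_c * (n x e2)) / (2A)
  r0 <- vec_cross(nh, e0); r1 <- vec_cross(nh, e1); r2 <- vec_cross(nh, e2)
  warea <- two_area / 2
  warea[bad] <- 0                            # excluded from vertex averaging
  out <- vector("list", ncol(fmat))
  for (k in seq_len(ncol(fmat))) {
    fa <- fmat[mesh$faces[, 1], k]
    fb <- fmat[mesh$faces[, 2], k]
    fc <- fmat[mesh$faces[, 3], k]
    g <- (r0 * fa + r1 * fb + r2 * fc) / two_area
    g[bad, ] <- 0
    attr(g, "area") <- warea
    attr(g, "degenerate") <- bad
    out[[k]] <- g
  }
  out
}

accumulate_to_vertices <- function(mesh, face_vals, weights) {
  nv <- nrow(mesh$vertices)
  idx <- as.vector(mesh$faces)
  wv <- face_vals * weights
  stacked <- wv[rep(seq_len(nrow(wv)), 3), , drop = FALSE]
  acc_s <- rowsum(stacked, idx)
  w_s <- rowsum(rep(weights, 3), idx)
  acc <- matrix(0, nv, ncol(face_vals))
  wacc <- numeric(nv)
  ids <- as.integer(rownames(acc_s))
  acc[ids, ] <- acc_s
  wacc[ids] <- w_s
  wacc[wacc == 0] <- 1
  acc / wacc
}

#' Time-averaged wall shear stress gradient (AWSSG)
#'
#' At each time sample the tangential surface gradient of each Cartesian
#' WSS component is computed; their root-sum-square magnitude is then
#' trapezoidally averaged over the cycle. (The instantaneous gradient
#' magnitude is averaged; the cycle average does not commute with the
#' root.)
#'
#' @param field A `wss_field`.
#' @return Per-vertex AWSSG (Pa/mm).
#' @export
compute_awssg <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  mesh <- field$mesh
  nt <- length(field$times)
  nv <- nrow(mesh$vertices)
  geo <- gradient_geometry(mesh)
  f1 <- mesh$faces[, 1]; f2 <- mesh$faces[, 2]; f3 <- mesh$faces[, 3]
  gmag <- matrix(0, nv, nt)
  for (k in seq_len(nt)) {
    vk <- field$vectors[, , k]
    face_sq <- 0
    for (comp in 1:3) {
      fa <- vk[f1, comp]; fb <- vk[f2, comp]; fc <- vk[f3, comp]
      g <- (geo$r0 * fa + geo$r1 * fb + geo$r2 * fc) / geo$two_area
      face_sq <- face_sq + rowSums(g^2)
    }
    face_mag <- sqrt(face_sq)
    face_mag[geo$bad] <- 0
    acc <- rowsum(rep(face_mag * geo$warea, 3), geo$idx)
    col <- numeric(nv)
    col[geo$ids] <- acc / geo$wacc
    gmag[, k] <- col
  }
  T_ <- field$times[nt] - field$times[1]
  trapz_rows(gmag, field$times) / T_
}

# precomputed per-face gradient geometry shared across timesteps
gradient_geometry <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  e0 <- c - b; e1 <- a - c; e2 <- b - a
  n <- vec_cross(e2, -e1)
  two_area <- sqrt(rowSums(n^2))
  bad <- two_area < 1e-6 * median(two_area)
  two_area[bad] <- 1
  nh <- n / two_area
  warea <- two_area / 2
  warea[bad] <- 0
  idx <- as.vector(mesh$faces)
  w_s <- rowsum(rep(warea, 3), idx)
  ids <- as.integer(rownames(w_s))
  wacc <- as.vector(w_s)
  wacc[wacc == 0] <- 1
  list(r0 = vec_cross(nh, e0), r1 = vec_cross(nh, e1),
       r2 = vec_cross(nh, e2), two_area = two_area, bad = bad,
       warea = warea, idx = idx, ids = ids, wacc = wacc)
}

#' Hemodynamic summary configuration
#'
#' @param low_wss_threshold Low-WSS cut-off (Pa) for the LWSS area fraction
#'   at end diastole.
#' @param high_osi_threshold High-OSI cut-off for the HOSI area fraction.
#' @param wss_percentile Percentile (percent) for the high-end WSS summary
#'   at peak systole.
#' @return A `hemo_config`.
#' @export
hemo_config <- function(low_wss_threshold = 0.4, high_osi_threshold = 0.2,
                        wss_percentile = 90) {
  stopifnot(low_wss_threshold > 0, high_osi_threshold > 0,
            wss_percentile > 0, wss_percentile < 100)
  structure(list(low_wss_threshold = low_wss_threshold,
                 high_osi_threshold = high_osi_threshold,
                 wss_percentile = wss_percentile),
            class = "hemo_config")
}

#' Area-weighted quantile with linear interpolation
#'
#' @param x Values.
#' @param w Non-negative weights (areas).
#' @param p Probability in (0, 1).
#' @return Interpolated weighted quantile.
#' @export
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2                      # midpoint convention
  cw <- cw / sum(w)
  if (p <= cw[1]) return(x[1])
  if (p >= cw[length(cw)]) return(x[length(x)])
  approx(cw, x, xout = p, ties = "ordered")$y
}

#' Regional hemodynamic statistics (the nine-parameter report)
#'
#' Area-weighted regional summaries of AWSS, OSI and AWSSG over the
#' aneurysm sac (subscript A) and parent-vessel ROI (subscript P):
#' AWSS_A/AWSS_P (mean AWSS), LWSS_A (area fraction below the low-WSS
#' threshold at end diastole), MWSS_A (maximum WSS at peak systole),
#' WSS90_A (area-weighted 90th-percentile WSS at peak systole), OSI_A
#' (mean), MOSI_A (maximum), HOSI_A (area fraction above the high-OSI
#' threshold), AWSSG_A (mean). OSI statistics use the cycle-integrated OSI
#' map. Vertex areas are one third of the incident triangle areas.
#'
#' @param field A `wss_field` on a labeled mesh.
#' @param config A `hemo_config`.
#' @return A `hemo_report`.
#' @export
regional_statistics <- function(field, config = hemo_config()) {
  mesh <- field$mesh
  if (!inherits(mesh, "labeled_surface_mesh"))
    stop("field mesh must be region-labeled")
  vreg <- vertex_regions(mesh)
  for (r in c("aneurysm", "parent_roi"))
    if (!any(vreg == r))
      stop(sprintf("missing region label: %s", r))
  va <- mesh_vertex_areas(mesh)
  A <- vreg == "aneurysm"
  P <- vreg == "parent_roi"
  awss <- time_average_wss(field)
  osi <- compute_osi(field)
  awssg <- compute_awssg(field)
  mag_ps <- sqrt(rowSums(field$vectors[, , time_index(field, field$t_peak_systole)]^2))
  mag_ed <- sqrt(rowSums(field$vectors[, , time_index(field, field$t_end_diastole)]^2))
  wmean <- function(x, sel) sum(x[sel] * va[sel]) / sum(va[sel])
  frac <- function(cond, sel) sum(va[sel & cond]) / sum(va[sel])
  rep <- list(
    AWSS_A = wmean(awss, A),
    AWSS_P = wmean(awss, P),
    LWSS_A = frac(mag_ed < config$low_wss_threshold, A),
    MWSS_A = max(mag_ps[A]),
    WSS90_A = weighted_quantile(mag_ps[A], va[A],
                                config$wss_percentile / 100),
    OSI_A = wmean(osi, A),
    MOSI_A = max(osi[A]),
    HOSI_A = frac(osi > config$high_osi_threshold, A),
    AWSSG_A = wmean(awssg, A))
  structure(c(rep, list(config = config,
                        provenance = list(
                          n_times = length(field$times),
                          t_peak_systole = field$t_peak_systole,
                          t_end_diastole = field$t_end_diastole))),
            class = "hemo_report")
}

#' @export
print.hemo_report <- function(x, digits = 4, ...) {
  cat("Hemodynamic parameters (A = aneurysm, P = parent ROI)\n")
  nm <- c("AWSS_A", "AWSS_P", "LWSS_A", "MWSS_A", "WSS90_A",
          "OSI_A", "MOSI_A", "HOSI_A", "AWSSG_A")
  un <- c("Pa", "Pa", "frac", "Pa", "Pa", "-", "-", "frac", "Pa/mm")
  for (i in seq_along(nm))
    cat(sprintf("  %-8s %10.*f %s\n", nm[i], digits, x[[nm[i]]], un[i]))
  invisible(x)
}

#' Resample a WSS field onto another mesh
#'
#' Each target vertex takes the barycentric interpolation of the field at
#' its closest point on the source surface (nearest-point projection).
#'
#' @param field A `wss_field`.
#' @param mesh Target `labeled_surface_mesh`.
#' @return A `wss_field` on `mesh`.
#' @export
map_wss_field <- function(field, mesh) {
  src <- field$mesh
  cp <- mesh_closest_point(mesh$vertices, src)
  f <- src$faces[cp$face, , drop = FALSE]
  a <- src$vertices[f[, 1], , drop = FALSE]
  b <- src$vertices[f[, 2], , drop = FALSE]
  c <- src$vertices[f[, 3], , drop = FALSE]
  # barycentric coordinates of the closest points
  v0 <- b - a; v1 <- c - a; v2 <- cp$point - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01 * d01
  den[den < 1e-14] <- 1
  wv <- (d11 * d20 - d01 * d21) / den
  wc <- (d00 * d21 - d01 * d20) / den
  wa <- pmin(1, pmax(0, 1 - wv - wc))
  wv <- pmin(1, pmax(0, wv)); wc <- pmin(1, pmax(0, wc))
  s <- wa + wv + wc
  wa <- wa / s; wv <- wv / s; wc <- wc / s
  nt <- length(field$times)
  nq <- nrow(mesh$vertices)
  # sparse interpolation operator: one row per target vertex
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(nq), 3), j = c(f[, 1], f[, 2], f[, 3]),
    x = c(wa, wv, wc), dims = c(nq, nrow(src$vertices)))
  out <- array(0, c(nq, 3, nt))
  flat <- matrix(field$vectors, nrow = nrow(src$vertices))  # (nv, 3 * nt)
  res <- as.matrix(M %*% flat)
  out[] <- res
  wss_field(mesh, field$times, out, field$t_peak_systole,
            field$t_end_diastole)
}
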