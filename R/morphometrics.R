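#' Neck plane of an aneurysm
#'
#' Least-squares plane through the neck-curve vertices. The normal is a
#' unit vector oriented toward the sac. Diameters are widths of the curve
#' projected into the plane: the maximum and minimum directional extent
#' over a dense sweep of in-plane directions; `average_diameter` is their
#' arithmetic mean.
#'
#' @param mesh A `labeled_surface_mesh` carrying a closed `neck_curve`.
#' @return A `neck_plane` with `centroid`, `unit_normal`, `max_diameter`,
#'   `min_diameter`, `average_diameter` (mm).
#' @export
fit_neck_plane <- function(mesh) {
  if (is.null(mesh$neck_curve)) stop("mesh carries no neck curve")
  pl <- fit_neck_plane_points(mesh$neck_curve, mesh)
  w <- curve_widths(mesh$neck_curve, pl)
  structure(list(centroid = pl$centroid, unit_normal = pl$normal,
                 max_diameter = w$max, min_diameter = w$min,
                 average_diameter = (w$max + w$min) / 2),
            class = "neck_plane")
}

#' @export
print.neck_plane <- function(x, ...) {
  cat(sprintf(
    "neck_plane: centroid (%.2f, %.2f, %.2f) mm, diameters %.2f/%.2f (avg %.2f) mm\n",
    x$centroid[1], x$centroid[2], x$centroid[3],
    x$max_diameter, x$min_diameter, x$average_diameter))
  invisible(x)
}

# LS plane through points; orientation toward the sac when a labeled mesh
# is supplied (otherwise arbitrary)
fit_neck_plane_points <- function(curve, mesh = NULL) {
  curve <- as.matrix(curve)
  centroid <- colMeans(curve)
  cc <- sweep(curve, 2, centroid)
  sv <- svd(cc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear) neck curve")
  normal <- sv$v[, 3]
  if (!is.null(mesh) && inherits(mesh, "labeled_surface_mesh") &&
      any(mesh$face_region == "aneurysm")) {
    sac_c <- colMeans(
      mesh_face_centroids(mesh)[mesh$face_region == "aneurysm", , drop = FALSE])
    if (sum((sac_c - centroid) * normal) < 0) normal <- -normal
  }
  list(centroid = centroid, normal = normal,
       r_curve = mean(sqrt(rowSums(cc^2))),
       basis = sv$v[, 1:2, drop = FALSE])
}

# directional widths of a point loop projected into a plane
curve_widths <- function(points, pl, n_dir = 720) {
  p2 <- sweep(as.matrix(points), 2, pl$centroid) %*% pl$basis
  th <- seq(0, pi, length.out = n_dir + 1)[-(n_dir + 1)]
  proj <- p2 %*% rbind(cos(th), sin(th))
  w <- apply(proj, 2, max) - apply(proj, 2, min)
  list(max = max(w), min = min(w))
}

#' Maximum perpendicular height of the aneurysm (size)
#'
#' Maximum signed distance of aneurysm-region vertices from the neck plane,
#' measured along the plane normal.
#'
#' @param mesh A `labeled_surface_mesh`.
#' @param plane A `neck_plane` (default: fitted from the mesh).
#' @return Height in mm (NA with a warning when the aneurysm region is
#'   empty).
#' @export
compute_size <- function(mesh, plane = fit_neck_plane(mesh)) {
  vi <- aneurysm_vertices(mesh)
  if (!length(vi)) {
    warning("no aneurysm faces; size undefined")
    return(NA_real_)
  }
  d <- as.vector(sweep(mesh$vertices[vi, , drop = FALSE], 2,
                       plane$centroid) %*% plane$unit_normal)
  max(d)
}

aneurysm_vertices <- function(mesh) {
  f <- which(mesh$face_region == "aneurysm")
  unique(as.vector(mesh$faces[f, ]))
}

# ---- planar sections -------------------------------------------------------

#' Planar cross-sections of a mesh
#'
#' Intersects the mesh with the plane through `point` with normal `normal`
#' and chains the per-triangle intersection segments into loops.
#'
#' @param mesh A `surface_mesh`.
#' @param point Point on the cutting plane (mm).
#' @param normal Plane normal.
#' @param faces Optional integer vector restricting the faces to cut.
#' @return List of loops; each loop is a list with `points` (ordered k x 3
#'   matrix) and `closed` (logical).
#' @export
section_loops <- function(mesh, point, normal, faces = NULL) {
  normal <- normal / sqrt(sum(normal^2))
  V <- mesh$vertices
  Fc <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  d <- as.vector(sweep(V, 2, point) %*% normal)
  eps <- 1e-9 * max(abs(d), 1)
  d[d == 0] <- eps
  s1 <- d[Fc[, 1]] > 0; s2 <- d[Fc[, 2]] > 0; s3 <- d[Fc[, 3]] > 0
  cut <- which((s1 != s2) | (s2 != s3))
  if (!length(cut)) return(list())
  seg_pts <- vector("list", length(cut))
  seg_keys <- matrix("", length(cut), 2)
  edge_pt <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    V[i, ] + t * (V[j, ] - V[i, ])
  }
  for (n in seq_along(cut)) {
    f <- Fc[cut[n], ]
    ss <- d[f] > 0
    pts <- list(); keys <- character()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- f[e[1]]; j <- f[e[2]]
      if (ss[e[1]] != ss[e[2]]) {
        pts[[length(pts) + 1]] <- edge_pt(i, j)
        keys <- c(keys, paste(min(i, j), max(i, j)))
      }
    }
    seg_pts[[n]] <- do.call(rbind, pts)
    seg_keys[n, ] <- keys
  }
  # chain segments that share a cut mesh-edge
  n_seg <- length(cut)
  adj <- split(rep(seq_len(n_seg), 2), c(seg_keys[, 1], seg_keys[, 2]))
  used <- rep(FALSE, n_seg)
  loops <- list()
  for (start in seq_len(n_seg)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- list(seg_pts[[start]][1, ], seg_pts[[start]][2, ])
    cur <- start
    cur_key <- seg_keys[start, 2]
    closed <- FALSE
    repeat {
      cands <- adj[[cur_key]]
      cands <- cands[cands != cur & !used[cands]]
      if (!length(cands)) {
        closed <- identical(cur_key, seg_keys[start, 1]) && n_seg > 2
        break
      }
      nxt <- cands[1]
      used[nxt] <- TRUE
      ent <- if (identical(seg_keys[nxt, 1], cur_key)) 1L else 2L
      out <- 3L - ent
      pts[[length(pts) + 1]] <- seg_pts[[nxt]][out, ]
      cur <- nxt
      cur_key <- seg_keys[nxt, out]
    }
    pm <- do.call(rbind, pts)
    if (closed) pm <- pm[-nrow(pm), , drop = FALSE]  # drop repeated point
    loops[[length(loops) + 1]] <- list(points = pm, closed = closed)
  }
  loops
}

loop_area <- function(loop, normal) {
  p <- loop$points
  basis <- plane_basis(normal)
  p2 <- p %*% basis
  n <- nrow(p2)
  j <- c(2:n, 1)
  abs(sum(p2[, 1] * p2[j, 2] - p2[j, 1] * p2[, 2])) / 2
}

plane_basis <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  cbind(e1, e2)
}

# distance from a point to a loop polyline (projected 3-D points)
loop_min_distance <- function(loop, point) {
  min(sqrt(rowSums(sweep(loop$points, 2, point)^2)))
}

#' Minimum neck cross-sectional area
#'
#' Sections the sac/neck surface with planes through the neck centroid
#' whose normals are perturbed up to `max_tilt` degrees from the fitted
#' neck-plane normal, and returns the smallest closed-section area.
#'
#' @param mesh A `labeled_surface_mesh`.
#' @param plane A `neck_plane`.
#' @param max_tilt Maximum normal perturbation (degrees).
#' @param n_azimuth Number of tilt azimuths searched.
#' @param max_offset Maximum axial offset of the cutting plane along the
#'   normal, as a fraction of the neck radius.
#' @return Area in mm^2.
#' @export
compute_neck_area <- function(mesh, plane = fit_neck_plane(mesh),
                              max_tilt = 10, n_azimuth = 8,
                              max_offset = 0.1) {
  pl <- list(centroid = plane$centroid, normal = plane$unit_normal)
  r_c <- plane$max_diameter / 2
  cen <- mesh_face_centroids(mesh)
  near <- which(
    as.character(mesh$face_region) %in%
      c("aneurysm", "neck_band", "parent_roi") &
    sqrt(rowSums(sweep(cen, 2, pl$centroid)^2)) < 3 * r_c)
  basis <- plane_basis(pl$normal)
  tilts <- unique(c(0, max_tilt / 2, max_tilt))
  offsets <- unique(c(0, -0.5, -1, 0.5, 1) * max_offset * r_c)
  best <- Inf
  for (tl in tilts) {
    azs <- if (tl == 0) 0 else seq(0, 2 * pi, length.out = n_azimuth + 1)[-1]
    for (az in azs) for (off in offsets) {
      tdir <- cos(az) * basis[, 1] + sin(az) * basis[, 2]
      nrm <- cos(tl * pi / 180) * pl$normal + sin(tl * pi / 180) * tdir
      loops <- section_loops(mesh, pl$centroid + off * pl$normal, nrm,
                             faces = near)
      for (lp in loops) {
        if (!lp$closed) next
        if (loop_min_distance(lp, pl$centroid) < 0.3 * r_c) next
        lc <- colMeans(lp$points)
        if (sqrt(sum((lc - pl$centroid)^2)) > r_c) next
        a <- loop_area(lp, nrm)
        if (a < best) best <- a
      }
    }
  }
  if (!is.finite(best))
    stop("neck section is not a simple closed polygon")
  best
}

# width statistics of the closed section at an axial station
section_diameters <- function(mesh, axis, station, faces = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  point <- axis * station
  loops <- section_loops(mesh, point, axis, faces = faces)
  loops <- Filter(function(l) l$closed && nrow(l$points) >= 6, loops)
  if (!length(loops)) return(NULL)
  # the parent section: the closed loop with the largest area
  areas <- vapply(loops, loop_area, numeric(1), normal = axis)
  lp <- loops[[which.max(areas)]]
  pl <- list(centroid = colMeans(lp$points), basis = plane_basis(axis))
  w <- curve_widths(lp$points, pl)
  list(max = w$max, min = w$min, average = (w$max + w$min) / 2,
       centroid = colMeans(lp$points))
}

#' Parent vessel diameter (PVD)
#'
#' D1 is the average diameter ((max + min) / 2 of the sectional widths) of
#' the parent cross-section at the proximal neck, D2 the same at arclength
#' 1.5 x D1 upstream; PVD = (D1 + D2) / 2. Cross-sections are taken
#' perpendicular to the parent principal axis; D1 sits at the first closed
#' parent section proximal to the neck aperture.
#'
#' @param mesh A `labeled_surface_mesh`.
#' @param plane A `neck_plane`.
#' @param stations Optional explicit axial stations `c(s1, s2)` (mm),
#'   bypassing the automatic placement.
#' @param axis Optional explicit parent axis.
#' @return PVD in mm, with D1 and D2 in attributes.
#' @export
compute_pvd <- function(mesh, plane = fit_neck_plane(mesh),
                        stations = NULL, axis = NULL) {
  lab <- as.character(mesh$face_region)
  pfaces <- which(lab %in% c("parent_roi", "extension", "neck_band"))
  if (!length(pfaces)) pfaces <- seq_len(nrow(mesh$faces))
  if (is.null(axis)) {
    cen <- mesh_face_centroids(mesh)[pfaces, , drop = FALSE]
    w <- mesh_face_areas(mesh)[pfaces]
    cc <- sweep(cen, 2, colSums(cen * w) / sum(w))
    axis <- eigen(crossprod(cc * sqrt(w)))$vectors[, 1]
  }
  axis <- axis / sqrt(sum(axis^2))
  if (!is.null(stations)) {
    d1s <- section_diameters(mesh, axis, stations[1], faces = pfaces)
    d2s <- section_diameters(mesh, axis, stations[2], faces = pfaces)
    if (is.null(d1s) || is.null(d2s))
      stop("no closed parent cross-section at the requested station")
    pvd <- (d1s$average + d2s$average) / 2
    return(structure(pvd, D1 = d1s$average, D2 = d2s$average))
  }
  s0 <- sum(plane$centroid * axis)
  guess <- plane$max_diameter
  d1s <- NULL; sgn_used <- NA; s1 <- NA
  for (off in seq(0.6, 3, by = 0.2) * guess) {
    for (sgn in c(-1, 1)) {
      cand <- section_diameters(mesh, axis, s0 + sgn * off, faces = pfaces)
      if (!is.null(cand)) { d1s <- cand; sgn_used <- sgn; s1 <- s0 + sgn * off }
      if (!is.null(d1s)) break
    }
    if (!is.null(d1s)) break
  }
  if (is.null(d1s)) stop("could not place D1: no closed parent section near the neck")
  d1 <- d1s$average
  s2 <- s0 + sgn_used * 1.5 * d1
  d2s <- section_diameters(mesh, axis, s2, faces = pfaces)
  if (is.null(d2s))
    stop("parent vessel too short to reach the D2 station (1.5 x D1 upstream)")
  structure((d1 + d2s$average) / 2, D1 = d1, D2 = d2s$average)
}

#' Size ratio and aneurysm angle
#'
#' H_max is the maximum Euclidean distance from the neck-plane centroid to
#' any aneurysm vertex (the maximum aneurysm height, distinct from the
#' perpendicular size); SR = H_max / PVD. AA is the inclination between
#' the aneurysm axis (centroid to farthest dome vertex) and the neck
#' plane, in degrees in (0, 90]: a sac perpendicular to its neck plane
#' reads 90.
#'
#' @param mesh A `labeled_surface_mesh`.
#' @param plane A `neck_plane`.
#' @param pvd Parent vessel diameter (mm).
#' @return List with `SR`, `AA` (degrees) and `H_max` (mm).
#' @export
compute_sr_aa <- function(mesh, plane = fit_neck_plane(mesh),
                          pvd = compute_pvd(mesh, plane)) {
  vi <- aneurysm_vertices(mesh)
  if (!length(vi)) {
    warning("no aneurysm faces; SR and AA undefined")
    return(list(SR = NA_real_, AA = NA_real_, H_max = NA_real_))
  }
  rel <- sweep(mesh$vertices[vi, , drop = FALSE], 2, plane$centroid)
  dd <- sqrt(rowSums(rel^2))
  h_max <- max(dd)
  # the aneurysm axis points at the farthest dome patch; averaging the
  # direction over the farthest 1% of reach makes the angle robust to
  # facet-level jitter of the single farthest vertex
  top <- which(dd >= 0.99 * h_max)
  dirs <- rel[top, , drop = FALSE] / dd[top]
  axis <- colMeans(dirs)
  axis <- axis / sqrt(sum(axis^2))
  sin_elev <- abs(sum(axis * plane$unit_normal))
  aa <- asin(pmin(1, sin_elev)) * 180 / pi
  list(SR = h_max / as.numeric(pvd), AA = aa, H_max = h_max)
}

#' Morphological report
#'
#' Container for the seven-parameter morphological description of one
#' aneurysm model (surface distance being pairwise, it lives in
#' `distance_report`).
#'
#' @param size,AR,NA_,PVD,SR,AA The morphometric parameters (mm, -, mm^2,
#'   mm, -, degrees).
#' @param neck_avg_diameter,H_max Auxiliary quantities (mm).
#' @param sac_area Optional labeled aneurysm area (mm^2).
#' @param undefined Flag for degenerate (sac-less) models.
#' @param provenance List of configuration/mesh provenance.
#' @return A `morpho_report`.
#' @export
morpho_report <- function(size, AR, NA_, PVD, SR, AA,
                          neck_avg_diameter = NA_real_, H_max = NA_real_,
                          sac_area = NA_real_, undefined = FALSE,
                          provenance = list()) {
  out <- list(size = size, AR = AR, "NA" = NA_, PVD = PVD, SR = SR, AA = AA,
              neck_avg_diameter = neck_avg_diameter, H_max = H_max,
              sac_area = sac_area, undefined = undefined,
              provenance = provenance)
  class(out) <- "morpho_report"
  out
}

#' @export
print.morpho_report <- function(x, digits = 4, ...) {
  cat("Morphological parameters\n")
  if (isTRUE(x$undefined)) cat("  (aneurysm region empty; sac metrics undefined)\n")
  v <- c(size = x$size, AR = x$AR, "NA" = x[["NA"]], PVD = x$PVD,
         SR = x$SR, AA = x$AA)
  u <- c("mm", "-", "mm^2", "mm", "-", "deg")
  for (i in seq_along(v))
    cat(sprintf("  %-4s %10.*f %s\n", names(v)[i], digits, v[i], u[i]))
  invisible(x)
}

#' Compute all morphological parameters of a labeled mesh
#'
#' @param mesh A `labeled_surface_mesh` with a neck curve.
#' @param neck_area_tilt Maximum neck-plane perturbation searched by the
#'   minimum-neck-area optimization (degrees).
#' @return A `morpho_report`.
#' @export
morphometrics <- function(mesh, neck_area_tilt = 10) {
  plane <- fit_neck_plane(mesh)
  size <- compute_size(mesh, plane)
  na_ <- compute_neck_area(mesh, plane, max_tilt = neck_area_tilt)
  pvd <- compute_pvd(mesh, plane)
  sraa <- compute_sr_aa(mesh, plane, pvd)
  sac_area <- sum(mesh_face_areas(mesh)[mesh$face_region == "aneurysm"])
  morpho_report(size = size, AR = size / plane$average_diameter,
                NA_ = na_, PVD = as.numeric(pvd), SR = sraa$SR, AA = sraa$AA,
                neck_avg_diameter = plane$average_diameter,
                H_max = sraa$H_max, sac_area = sac_area,
                undefined = is.na(size),
                provenance = list(mesh_hash = hash_object(mesh$vertices),
                                  D1 = attr(pvd, "D1"), D2 = attr(pvd, "D2"),
                                  neck_area_tilt = neck_area_tilt))
}
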