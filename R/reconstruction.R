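#' Segmentation and reconstruction configuration
#'
#' @param threshold Intensity threshold, or "auto" (midpoint between the
#'   background and lumen intensity modes, 2-means fallback for weakly
#'   bimodal histograms).
#' @param seed_point Physical (mm) coordinates of a point inside the lumen,
#'   used by region growing.
#' @param smoothing_sigma Surface smoothing neighbourhood width (mm);
#'   <= 0 gives uniform neighbour weights.
#' @param smoothing_passes Taubin smoothing passes (0 = no smoothing).
#' @param iso_level Isosurface level as a fraction of the threshold.
#' @return A `segmentation_config`.
#' @export
segmentation_config <- function(threshold = "auto",
                                seed_point = c(0, 0, 0),
                                smoothing_sigma = 0.3,
                                smoothing_passes = 10L,
                                iso_level = 1) {
  stopifnot(smoothing_sigma >= 0, smoothing_passes >= 0, iso_level > 0)
  structure(list(threshold = threshold, seed_point = as.numeric(seed_point),
                 smoothing_sigma = smoothing_sigma,
                 smoothing_passes = as.integer(smoothing_passes),
                 iso_level = iso_level),
            class = "segmentation_config")
}

#' Automatic intensity threshold
#'
#' Midpoint between the two largest modes of the intensity histogram;
#' falls back to the midpoint of 2-means cluster centres when the density
#' has fewer than two clear modes.
#'
#' @param vol An `image_volume` (or numeric array/vector).
#' @return Scalar threshold.
#' @export
auto_threshold <- function(vol) {
  x <- if (inherits(vol, "image_volume")) as.vector(vol$data) else as.vector(vol)
  if (length(x) > 2e5) x <- x[seq(1, length(x), length.out = 2e5)]
  dn <- density(x, n = 512)
  y <- dn$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  if (length(pk) >= 2) {
    top <- pk[order(y[pk], decreasing = TRUE)[1:2]]
    return(mean(dn$x[sort(top)]))
  }
  km <- kmeans(x, centers = 2, nstart = 3)
  mean(km$centers)
}

#' Threshold segmentation
#'
#' @param vol An `image_volume`.
#' @param config A `segmentation_config` (or a numeric threshold).
#' @return Logical 3-D array: voxels with intensity >= threshold.
#' @export
threshold_segment <- function(vol, config = segmentation_config()) {
  thr <- if (is.numeric(config)) config else config$threshold
  if (identical(thr, "auto")) thr <- auto_threshold(vol)
  mask <- vol$data >= thr
  if (!any(mask))
    stop(sprintf("empty segmentation at threshold %.4g", thr))
  attr(mask, "threshold") <- thr
  mask
}

#' Region growing: keep the 26-connected component containing a seed
#'
#' @param mask Logical 3-D array.
#' @param seed_point Seed in physical coordinates (mm) when `vol` is given,
#'   otherwise a voxel index triple.
#' @param vol Optional `image_volume` providing the world frame of `mask`.
#' @return Logical array with only the seed's component retained.
#' @export
region_grow <- function(mask, seed_point, vol = NULL) {
  d <- dim(mask)
  idx <- if (!is.null(vol)) world_to_index(vol, seed_point)
         else round(as.numeric(seed_point))
  if (any(idx < 1) || any(idx > d))
    stop("seed point outside volume bounds")
  if (!mask[idx[1], idx[2], idx[3]]) {
    inm <- which(mask, arr.ind = TRUE)
    d2 <- colSums((t(inm) - idx)^2)
    near <- inm[which.min(d2), ]
    stop(sprintf(
      "seed voxel (%d, %d, %d) is outside the mask; nearest in-mask voxel is (%d, %d, %d)",
      idx[1], idx[2], idx[3], near[1], near[2], near[3]))
  }
  lin <- idx[1] + d[1] * ((idx[2] - 1) + d[2] * (idx[3] - 1))
  out <- cpp_region_grow(mask, d, as.integer(lin))
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Isosurface extraction in world coordinates
#'
#' Marching tetrahedra at the given intensity level (0.5 for binary masks),
#' honouring the volume's voxel spacing and origin. The largest connected
#' component is returned.
#'
#' @param x An `image_volume`, or a logical/numeric 3-D array (unit spacing).
#' @param level Isosurface level; defaults to 0.5 for logical input,
#'   otherwise the intensity midrange.
#' @return A watertight `surface_mesh`.
#' @export
extract_surface <- function(x, level = NULL) {
  if (inherits(x, "image_volume")) {
    dat <- x$data; spacing <- x$spacing; origin <- x$origin
  } else {
    dat <- x; spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  }
  if (is.logical(dat)) {
    dat <- array(as.numeric(dat), dim(dat))
    if (is.null(level)) level <- 0.5
  }
  if (is.null(level)) level <- (max(dat) + min(dat)) / 2
  d <- dim(dat)
  border <- c(dat[1, , ], dat[d[1], , ], dat[, 1, ], dat[, d[2], ],
              dat[, , 1], dat[, , d[3]])
  if (any(border >= level))
    stop("segmented region touches the volume border; pad the volume before extracting a closed surface")
  if (all(dat < level) || all(dat >= level))
    stop("empty isosurface at the requested level")
  dat[dat == level] <- level + 1e-9 * max(abs(dat), 1)
  res <- cpp_march_tets(as.numeric(-dat), d, origin, spacing, -level)
  mesh <- surface_mesh(res$vertices, res$faces)
  largest_component(mesh)
}

#' Taubin surface smoothing
#'
#' Volume-preserving lambda/mu smoothing (a discrete counterpart of
#' recursive Gaussian surface filtering). Vertex count and topology are
#' preserved; volume shrinkage beyond 5% raises a warning.
#'
#' @param mesh A `surface_mesh`.
#' @param sigma Neighbourhood weighting width (mm); <= 0 for uniform
#'   weights.
#' @param passes Number of lambda/mu pass pairs.
#' @param lambda,mu Taubin coefficients.
#' @return Smoothed mesh (labels and neck curve preserved).
#' @export
smooth_surface <- function(mesh, sigma = 0.3, passes = 10L,
                           lambda = 0.5, mu = -0.53) {
  if (passes <= 0) return(mesh)
  A <- mesh_adjacency(mesh)
  if (sigma > 0) {
    e <- Matrix::summary(A)
    d <- sqrt(rowSums((mesh$vertices[e$i, , drop = FALSE] -
                       mesh$vertices[e$j, , drop = FALSE])^2))
    w <- exp(-0.5 * (d / sigma)^2)
    A <- Matrix::sparseMatrix(i = e$i, j = e$j, x = w, dims = dim(A))
  }
  W <- A / Matrix::rowSums(A)
  v0 <- mesh$vertices
  vol0 <- abs(mesh_volume(mesh))
  v <- v0
  for (i in seq_len(passes)) {
    v <- v + lambda * (as.matrix(W %*% v) - v)
    v <- v + mu * (as.matrix(W %*% v) - v)
  }
  out <- mesh
  out$vertices <- v
  vol1 <- abs(mesh_volume(out))
  shrink <- 1 - vol1 / vol0
  if (is.finite(shrink) && shrink > 0.05)
    warning(sprintf("surface smoothing shrank the volume by %.1f%%",
                    100 * shrink))
  attr(out, "volume_shrinkage") <- shrink
  out
}

#' Partition a mesh into anatomical regions from a neck curve
#'
#' Faces on the sac side of the fitted neck plane are labeled `aneurysm`;
#' a band of total width `neck_band_frac * D1` around the neck curve is
#' labeled `neck_band`; parent faces within arclength station
#' `parent_extent_factor * D1` of the neck along the parent axis are
#' `parent_roi`; the remainder is `extension`. D1 is the parent vessel
#' diameter at the proximal neck, measured from the first closed parent
#' cross-section next to the neck aperture unless supplied.
#'
#' @param mesh A `surface_mesh`.
#' @param neck_curve k x 3 matrix tracing the closed neck curve.
#' @param d1 Optional known parent diameter at the neck (mm).
#' @param neck_band_frac Band width as a fraction of D1.
#' @param parent_extent_factor Parent ROI half-extent in units of D1.
#' @param sac_direction Optional length-3 vector pointing from the neck
#'   toward the sac (otherwise the smaller-area side of the plane is taken).
#' @return A `labeled_surface_mesh`.
#' @export
partition_regions <- function(mesh, neck_curve, d1 = NULL,
                              neck_band_frac = 0.1,
                              parent_extent_factor = 1.5,
                              sac_direction = NULL) {
  neck_curve <- as.matrix(neck_curve)
  if (nrow(neck_curve) < 3) stop("neck curve must be a closed loop")
  pl <- fit_neck_plane_points(neck_curve, NULL)
  cen <- mesh_face_centroids(mesh)
  areas <- mesh_face_areas(mesh)
  sd_plane <- as.vector(sweep(cen, 2, pl$centroid) %*% pl$normal)
  if (!is.null(sac_direction)) {
    if (sum(sac_direction * pl$normal) < 0) {
      pl$normal <- -pl$normal; sd_plane <- -sd_plane
    }
  } else {
    # orient toward the side with less total area (the sac)
    if (sum(areas[sd_plane > 0]) > sum(areas[sd_plane < 0])) {
      pl$normal <- -pl$normal; sd_plane <- -sd_plane
    }
  }
  lab <- rep("parent_roi", nrow(mesh$faces))
  # parent principal axis from the non-sac faces
  keep <- sd_plane <= 0
  mu <- colSums(cen[keep, , drop = FALSE] * areas[keep]) / sum(areas[keep])
  cc <- sweep(cen[keep, , drop = FALSE], 2, mu)
  axis <- eigen(crossprod(cc * sqrt(areas[keep])))$vectors[, 1]
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(d1)) {
    tmp <- surface_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
    d1 <- proximal_parent_diameter(tmp, axis, pl$centroid,
                                   guess = 2 * pl$r_curve)
  }
  band_half <- 0.5 * neck_band_frac * d1
  dcurve <- curve_min_distance(cen, neck_curve)
  # The sac is the largest connected component of sac-side faces after
  # cutting the mesh along the neck band. The cut radius adapts to the
  # facet size so that coarse reconstructions, whose parent-top ridge can
  # graze the neck plane far from the sac, cannot leak into the aneurysm
  # label through near-plane faces.
  edge_est <- sqrt(4 / sqrt(3) * median(areas))
  cut_half <- max(band_half, 1.5 * edge_est)
  cand <- which(sd_plane > 0 & dcurve > cut_half)
  if (length(cand) > 1) {
    comp <- face_components(mesh, cand)
    carea <- tapply(areas[cand], comp, sum)
    dome <- as.integer(names(carea)[which.max(carea)])
    lab[cand[comp == dome]] <- "aneurysm"
    # collar between the dome component and the neck band
    lab[sd_plane > 0 & dcurve <= cut_half] <- "aneurysm"
  } else {
    lab[sd_plane > 0] <- "aneurysm"
  }
  lab[dcurve <= band_half] <- "neck_band"
  s <- as.vector(cen %*% axis)
  s_neck <- sum(pl$centroid * axis)
  far <- abs(s - s_neck) > parent_extent_factor * d1
  lab[lab == "parent_roi" & far] <- "extension"
  labeled_surface_mesh(mesh, lab, neck_curve)
}

# connected components of a face subset (faces adjacent when sharing an edge)
face_components <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_along(face_idx), 3)
  pairs <- split(fid, key)
  pairs <- pairs[lengths(pairs) == 2]
  if (!length(pairs))
    return(seq_along(face_idx))
  el <- do.call(rbind, pairs)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(face_idx) - igraph::vcount(g)))
  igraph::components(g)$membership
}

# diameter of the first closed parent cross-section proximal to the neck
proximal_parent_diameter <- function(parent_mesh, axis, neck_centroid,
                                     guess) {
  s0 <- sum(neck_centroid * axis)
  for (off in seq(0.6, 3, by = 0.2) * guess) {
    for (sgn in c(-1, 1)) {
      sec <- try(section_diameters(parent_mesh, axis,
                                   s0 + sgn * off), silent = TRUE)
      if (!inherits(sec, "try-error") && !is.null(sec))
        return(sec$average)
    }
  }
  stop("could not find a closed parent cross-section near the neck")
}

#' Full reconstruction pipeline for one volume
#'
#' Threshold segmentation, region growing from the seed, grey-level
#' isosurface extraction restricted to the retained component, Taubin
#' smoothing, and (when a neck curve is supplied) anatomical partition.
#'
#' @param vol An `image_volume`.
#' @param config A `segmentation_config`.
#' @param neck_curve Optional neck curve for region partition.
#' @param d1 Optional known parent diameter at the neck (mm).
#' @return A `surface_mesh` (labeled when `neck_curve` is given), with the
#'   threshold used stored in `attr(, "threshold")`.
#' @export
reconstruct_model <- function(vol, config = segmentation_config(),
                              neck_curve = NULL, d1 = NULL) {
  mask <- threshold_segment(vol, config)
  thr <- attr(mask, "threshold")
  mask <- region_grow(mask, config$seed_point, vol)
  # carve away other components but keep grey levels for sub-voxel accuracy
  keepmask <- cpp_dilate26(mask, dim(mask), 2L)
  dat <- vol$data
  lo <- min(dat)
  dat[!keepmask] <- lo
  vol2 <- image_volume(dat, vol$spacing, vol$origin, vol$meta)
  mesh <- extract_surface(vol2, level = thr * config$iso_level)
  mesh <- smooth_surface(mesh, config$smoothing_sigma,
                         config$smoothing_passes)
  if (!is.null(neck_curve))
    mesh <- partition_regions(mesh, neck_curve, d1 = d1)
  attr(mesh, "threshold") <- thr
  mesh
}
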