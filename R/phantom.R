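#' Synthetic saccular-aneurysm phantom specification
#'
#' The phantom is a spherical sac sitting on a (possibly curved) cylindrical
#' parent vessel. The geometry is defined implicitly as the signed distance
#' of tube-union-sphere, which gives closed-form morphological ground truth
#' and a watertight isosurface mesh. The main sac sphere of radius
#' `sac_radius` is centred at height `sqrt(R^2 - r_n^2)` above the neck
#' point, so the neck aperture in the tangent plane is an exact circle of
#' radius `neck_radius`. When `sac_offset_angle > 0` an apex lobe (a smaller
#' sphere along the tilted sac axis) is added so the inclination is
#' geometrically expressed; a pure sphere's farthest point from the neck
#' centroid is always perpendicular to the neck plane.
#'
#' @param parent_radius Parent vessel radius (mm).
#' @param parent_length Parent vessel centerline length (mm).
#' @param parent_curvature Centerline curvature (1/mm); 0 = straight tube.
#'   The centerline bends in the xy-plane so the sac (at +z) keeps its
#'   closed-form ground truth.
#' @param sac_radius Main sac sphere radius R (mm); 0 gives a plain tube.
#' @param neck_radius Neck aperture radius r_n (mm), 0 < r_n <= R.
#' @param sac_offset_angle Tilt of the sac axis from the neck-plane normal,
#'   degrees in [0, 60).
#' @param neck_standoff Height of the neck aperture plane above the parent
#'   tube (mm); the neck column of radius \code{neck_radius} bridges the
#'   two, so the aperture is the exact minimal neck section and all
#'   sections near it are transversal.
#' @param mesh_edge_length Target isosurface grid pitch (mm).
#' @param rng_seed Integer seed (reserved for randomized variants).
#' @return An `aneurysm_spec` object.
#' @export
aneurysm_spec <- function(parent_radius = 2, parent_length = 16,
                          parent_curvature = 0, sac_radius = 3,
                          neck_radius = 1.5, sac_offset_angle = 0,
                          neck_standoff = 0.4, mesh_edge_length = 0.2,
                          rng_seed = 1L) {
  stopifnot(parent_radius > 0, parent_length > 2 * parent_radius,
            parent_curvature >= 0, sac_radius >= 0,
            mesh_edge_length > 0, sac_offset_angle >= 0,
            sac_offset_angle < 60, neck_standoff >= 0)
  if (sac_radius > 0) {
    if (!(neck_radius > 0 && neck_radius <= sac_radius))
      stop("need 0 < neck_radius <= sac_radius")
  }
  if (parent_curvature > 0 &&
      parent_curvature * parent_length > pi)
    stop("parent vessel bends more than a half circle")
  structure(list(parent_radius = parent_radius,
                 parent_length = parent_length,
                 parent_curvature = parent_curvature,
                 sac_radius = sac_radius, neck_radius = neck_radius,
                 sac_offset_angle = sac_offset_angle,
                 neck_standoff = neck_standoff,
                 mesh_edge_length = mesh_edge_length,
                 rng_seed = as.integer(rng_seed)),
            class = "aneurysm_spec")
}

# sac construction constants for a spec (closed form)
sac_geometry <- function(spec) {
  if (spec$sac_radius <= 0) return(NULL)
  R <- spec$sac_radius; rn <- spec$neck_radius
  delta <- sqrt(R^2 - rn^2)
  z_ap <- spec$parent_radius + spec$neck_standoff   # aperture plane height
  P <- c(0, 0, z_ap)                         # neck centre
  C1 <- P + c(0, 0, delta)                   # main sphere centre
  out <- list(P = P, C1 = C1, R = R, rn = rn, delta = delta,
              z_ap = z_ap, z_hi = z_ap + 0.5 * R)
  if (spec$sac_offset_angle > 0) {
    a <- spec$sac_offset_angle * pi / 180
    u <- c(sin(a), 0, cos(a))                # tilted sac axis (tilts along x)
    R2 <- rn                                 # apex lobe radius
    M <- delta + R - R2 / 2                  # apex centre distance from P
    out$u <- u; out$R2 <- R2; out$M <- M
    out$C2 <- P + M * u
  }
  out
}

#' Signed distance function of a phantom
#'
#' Negative inside the lumen. The parent tube is end-capped so the surface
#' is closed.
#'
#' @param spec An `aneurysm_spec`.
#' @return Function mapping an n x 3 point matrix to signed distances (mm).
#' @export
aneurysm_sdf <- function(spec) {
  g <- sac_geometry(spec)
  rp <- spec$parent_radius
  L <- spec$parent_length
  k <- spec$parent_curvature
  function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    if (k == 0) {
      radial <- sqrt(p[, 2]^2 + p[, 3]^2) - rp
      axial <- abs(p[, 1]) - L / 2
    } else {
      # centerline: arc of radius Rc in the xy-plane through the origin,
      # tangent to x at s = 0; curve centre at (0, -Rc, 0)
      Rc <- 1 / k
      dxy <- sqrt(p[, 1]^2 + (p[, 2] + Rc)^2)
      radial <- sqrt((dxy - Rc)^2 + p[, 3]^2) - rp
      theta <- atan2(p[, 1], p[, 2] + Rc)    # 0 at the neck station
      axial <- abs(theta) * Rc - L / 2
    }
    d <- pmax(radial, axial)                 # capped tube
    if (!is.null(g)) {
      # neck column bridging tube and sac (radius rn, vertical axis)
      dcol <- pmax(sqrt(p[, 1]^2 + p[, 2]^2) - g$rn, -p[, 3],
                   p[, 3] - g$z_hi)
      d <- pmin(d, dcol)
      d1 <- sqrt(rowSums(sweep(p, 2, g$C1)^2)) - g$R
      d <- pmin(d, d1)
      if (!is.null(g$C2)) {
        d2 <- sqrt(rowSums(sweep(p, 2, g$C2)^2)) - g$R2
        d <- pmin(d, d2)
      }
    }
    d
  }
}

#' Analytic neck curve of a phantom
#'
#' The circle of radius `neck_radius` around the neck centre in the plane
#' tangent to the parent tube, traversed counter-clockwise as seen from the
#' sac.
#'
#' @param spec An `aneurysm_spec`.
#' @param n Number of polyline points.
#' @return n x 3 matrix (closed curve; first point not repeated).
#' @export
phantom_neck_curve <- function(spec, n = 96) {
  g <- sac_geometry(spec)
  if (is.null(g)) stop("plain-tube phantom has no neck")
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(g$P[1] + g$rn * cos(th), g$P[2] + g$rn * sin(th),
        rep(g$P[3], n))
}

#' Closed-form morphological ground truth of a phantom
#'
#' @param spec An `aneurysm_spec`.
#' @return A `morpho_report` with fields size, AR, NA, PVD, SR, AA (plus
#'   `neck_avg_diameter`, `H_max`, `sac_area`), or an undefined-flagged
#'   report for a plain tube.
#' @export
phantom_ground_truth <- function(spec) {
  g <- sac_geometry(spec)
  pvd <- 2 * spec$parent_radius
  if (is.null(g)) {
    return(morpho_report(size = NA_real_, AR = NA_real_, NA_ = NA_real_,
                         PVD = pvd, SR = NA_real_, AA = NA_real_,
                         neck_avg_diameter = NA_real_, H_max = NA_real_,
                         undefined = TRUE, provenance = list(source = "analytic")))
  }
  if (is.null(g$C2)) {
    size <- g$delta + g$R
    H_max <- size
    AA <- 90
    sac_area <- 2 * pi * g$R * size          # spherical cap 2*pi*R*h
  } else {
    size <- max(g$delta + g$R, g$M * cos(spec$sac_offset_angle * pi / 180) + g$R2)
    H_max <- max(g$delta + g$R, g$M + g$R2)
    AA <- if (g$M + g$R2 > g$delta + g$R) 90 - spec$sac_offset_angle else 90
    sac_area <- NA_real_                     # lobed sac: no closed form kept
  }
  nd <- 2 * g$rn
  morpho_report(size = size, AR = size / nd, NA_ = pi * g$rn^2,
                PVD = pvd, SR = H_max / pvd, AA = AA,
                neck_avg_diameter = nd, H_max = H_max,
                sac_area = sac_area,
                provenance = list(source = "analytic"))
}

#' Build a watertight labeled phantom mesh with its ground truth
#'
#' The implicit geometry is sampled on a regular grid at pitch
#' `mesh_edge_length` and meshed by marching tetrahedra at level 0.
#'
#' @param spec An `aneurysm_spec`.
#' @return List with `mesh` (a `labeled_surface_mesh`), `ground_truth`
#'   (a `morpho_report`) and `spec`.
#' @export
build_phantom_mesh <- function(spec) {
  sdf <- aneurysm_sdf(spec)
  h <- spec$mesh_edge_length
  bb <- phantom_bbox(spec, pad = 3 * h)
  xs <- seq(bb[1, 1], bb[2, 1], by = h)
  ys <- seq(bb[1, 2], bb[2, 2], by = h)
  zs <- seq(bb[1, 3], bb[2, 3], by = h)
  gp <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  f <- sdf(gp)
  f[f == 0] <- 1e-9
  res <- cpp_march_tets(f, c(length(xs), length(ys), length(zs)),
                        c(xs[1], ys[1], zs[1]), c(h, h, h), 0)
  if (nrow(res$faces) == 0)
    stop("constructive-geometry error: empty isosurface")
  mesh <- surface_mesh(res$vertices, res$faces)
  mesh <- largest_component(mesh)
  if (!mesh_is_watertight(mesh))
    stop("constructive-geometry error: non-manifold phantom surface")
  gt <- phantom_ground_truth(spec)
  if (spec$sac_radius > 0) {
    curve <- phantom_neck_curve(spec)
    mesh <- partition_regions(mesh, curve, d1 = 2 * spec$parent_radius)
  } else {
    mesh <- labeled_surface_mesh(mesh,
      rep("parent_roi", nrow(mesh$faces)))
  }
  list(mesh = mesh, ground_truth = gt, spec = spec)
}

phantom_bbox <- function(spec, pad = 1) {
  g <- sac_geometry(spec)
  rp <- spec$parent_radius; L <- spec$parent_length; k <- spec$parent_curvature
  if (k == 0) {
    lo <- c(-L / 2, -rp, -rp); hi <- c(L / 2, rp, rp)
  } else {
    Rc <- 1 / k; th <- L / 2 * k
    lo <- c(-Rc * sin(th) - rp, -(Rc - Rc * cos(th)) - rp, -rp)
    hi <- c(Rc * sin(th) + rp, rp, rp)
  }
  if (!is.null(g)) {
    lo <- pmin(lo, g$C1 - g$R); hi <- pmax(hi, g$C1 + g$R)
    if (!is.null(g$C2)) {
      lo <- pmin(lo, g$C2 - g$R2); hi <- pmax(hi, g$C2 + g$R2)
    }
  }
  rbind(lo - pad, hi + pad)
}

# ---- modality profiles -----------------------------------------------------

#' Imaging modality profiles
#'
#' Encodes the acquisition differences between rotational angiography
#' (best spatial fidelity), CT angiography and MR angiography as voxel
#' spacing, Gaussian point-spread width and additive noise level. The
#' defaults order the three modalities by decreasing fidelity; every value
#' can be overridden.
#'
#' @param name One of "DRA_like", "CTA_like", "MRA_like".
#' @param voxel_spacing Voxel spacing per axis (mm); scalar is recycled.
#' @param psf_sigma Gaussian point-spread sigma (mm).
#' @param noise_sigma Additive Gaussian noise, as a fraction of the
#'   lumen-background contrast.
#' @param lumen_intensity,background_intensity Arbitrary intensity units.
#' @param rng_seed Integer seed for the noise field.
#' @return A `modality_profile`.
#' @export
modality_profile <- function(name = c("DRA_like", "CTA_like", "MRA_like"),
                             voxel_spacing = NULL, psf_sigma = NULL,
                             noise_sigma = NULL, lumen_intensity = 100,
                             background_intensity = 10, rng_seed = 1L) {
  name <- match.arg(name)
  defaults <- list(
    DRA_like = list(spacing = 0.15, psf = 0.10, noise = 0.01),
    CTA_like = list(spacing = 0.40, psf = 0.30, noise = 0.03),
    MRA_like = list(spacing = 0.50, psf = 0.45, noise = 0.05))[[name]]
  if (is.null(voxel_spacing)) voxel_spacing <- defaults$spacing
  if (is.null(psf_sigma)) psf_sigma <- defaults$psf
  if (is.null(noise_sigma)) noise_sigma <- defaults$noise
  voxel_spacing <- rep(as.numeric(voxel_spacing), length.out = 3)
  stopifnot(all(voxel_spacing > 0), psf_sigma >= 0, noise_sigma >= 0,
            lumen_intensity > background_intensity)
  structure(list(name = name, voxel_spacing = voxel_spacing,
                 psf_sigma = psf_sigma, noise_sigma = noise_sigma,
                 lumen_intensity = lumen_intensity,
                 background_intensity = background_intensity,
                 rng_seed = as.integer(rng_seed)),
            class = "modality_profile")
}

#' The three default modality profiles
#' @param rng_seed Seed shared by the three profiles.
#' @return Named list of `modality_profile`s (DRA_like, CTA_like, MRA_like).
#' @export
default_modality_profiles <- function(rng_seed = 1L) {
  list(DRA_like = modality_profile("DRA_like", rng_seed = rng_seed),
       CTA_like = modality_profile("CTA_like", rng_seed = rng_seed),
       MRA_like = modality_profile("MRA_like", rng_seed = rng_seed))
}

#' Render a modality-degraded image volume of a phantom or mesh
#'
#' The lumen is rendered with linear partial-volume weighting from the
#' signed distance (intensity ramps from background to lumen across one
#' voxel), blurred with the profile's Gaussian point spread, and corrupted
#' with seeded Gaussian noise. For a `surface_mesh` input the signed
#' distance is obtained from parity voxelization (sign) and exact
#' closest-point distance (magnitude); the mesh must be watertight.
#'
#' @param x An `aneurysm_spec` or a watertight `surface_mesh`.
#' @param profile A `modality_profile`.
#' @param pad Padding around the geometry bounding box (mm).
#' @return An `image_volume`.
#' @export
voxelize <- function(x, profile, pad = 1.5) {
  stopifnot(inherits(profile, "modality_profile"))
  sp <- profile$voxel_spacing
  if (inherits(x, "aneurysm_spec")) {
    bb <- phantom_bbox(x, pad = pad)
    feature <- min(x$parent_radius,
                   if (x$sac_radius > 0) x$neck_radius else Inf)
    sdf_fun <- aneurysm_sdf(x)
  } else if (inherits(x, "surface_mesh")) {
    bb <- rbind(apply(x$vertices, 2, min) - pad,
                apply(x$vertices, 2, max) + pad)
    feature <- NA_real_
    sdf_fun <- NULL
  } else stop("x must be an aneurysm_spec or surface_mesh")
  xs <- seq(bb[1, 1], bb[2, 1], by = sp[1])
  ys <- seq(bb[1, 2], bb[2, 2], by = sp[2])
  zs <- seq(bb[1, 3], bb[2, 3], by = sp[3])
  dims <- c(length(xs), length(ys), length(zs))
  warn <- character()
  if (!is.na(feature) && max(sp) > feature)
    warn <- c(warn, sprintf(
      "voxel spacing %.3g mm exceeds the smallest geometric feature %.3g mm",
      max(sp), feature))
  if (!is.null(sdf_fun)) {
    gp <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    sdf <- sdf_fun(gp)
  } else {
    # parity gives the sign everywhere; exact surface distances are only
    # needed in the shell where the partial-volume ramp is active
    inside <- as.vector(cpp_voxelize_parity(x$vertices, x$faces, xs, ys, zs))
    shell <- as.vector(cpp_mark_tri_cells(x$vertices, x$faces,
                                          xs, ys, zs, 2L))
    gp <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    big <- 2 * mean(sp)
    sdf <- ifelse(inside, -big, big)
    if (any(shell)) {
      d <- mesh_closest_point(gp[shell, , drop = FALSE], x)$distance
      sdf[shell] <- d * ifelse(inside[shell], -1, 1)
    }
  }
  s_eff <- mean(sp)
  cov <- pmin(1, pmax(0, 0.5 - sdf / s_eff))
  vol <- profile$background_intensity +
    (profile$lumen_intensity - profile$background_intensity) * cov
  dim(vol) <- dims
  if (profile$psf_sigma > 0)
    vol <- cpp_gauss_blur3(vol, dims, profile$psf_sigma / sp)
  if (profile$noise_sigma > 0) {
    vol <- vol + with_seed(profile$rng_seed, array(
      rnorm(prod(dims), sd = profile$noise_sigma *
              (profile$lumen_intensity - profile$background_intensity)),
      dims))
  }
  image_volume(vol, spacing = sp, origin = c(xs[1], ys[1], zs[1]),
               meta = list(modality = profile$name, warnings = warn,
                           lumen_intensity = profile$lumen_intensity,
                           background_intensity = profile$background_intensity))
}

# run expr under a local seed without disturbing the global RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- waveform and inlet helpers -------------------------------------------

#' Pulsatile inlet flow waveform
#'
#' @param times Sample times (s), strictly increasing, spanning [0, period].
#' @param flow_rates Volume flow q(t) (mm^3/s); first and last samples must
#'   agree (periodicity).
#' @param period Cycle period T (s).
#' @return A `waveform` object.
#' @export
waveform <- function(times, flow_rates, period = max(times)) {
  stopifnot(length(times) == length(flow_rates), all(diff(times) > 0),
            min(times) >= 0, max(times) <= period + 1e-12)
  if (abs(flow_rates[1] - flow_rates[length(flow_rates)]) >
      1e-8 * max(abs(flow_rates)))
    stop("waveform must be periodic: first and last flow samples must agree")
  structure(list(times = times, flow_rates = flow_rates, period = period),
            class = "waveform")
}

#' Default internal-carotid-like inlet waveform
#'
#' A two-harmonic positive pulse, period 0.8 s, 32 intervals (33 samples
#' including the periodic endpoint). Amplitude is scaled so that with the
#' default 4 mm inlet the peak Reynolds number falls in the physiological
#' mid-range for the internal carotid artery.
#'
#' @param period Cycle period (s).
#' @param n Number of intervals per cycle.
#' @param q_mean Mean volume flow (mm^3/s).
#' @return A `waveform`.
#' @export
default_waveform <- function(period = 0.8, n = 32, q_mean = 4700) {
  t <- seq(0, period, length.out = n + 1)
  ph <- 2 * pi * t / period
  q <- q_mean * (1 + 0.25 * sin(ph) + 0.10 * sin(2 * ph))
  q[length(q)] <- q[1]
  waveform(t, q, period)
}

#' @export
plot.waveform <- function(x, ...) {
  plot(x$times, x$flow_rates, type = "l", xlab = "time (s)",
       ylab = expression(q(t) ~ (mm^3 / s)), ...)
  invisible(x)
}

#' Inlet specification (diameter, fluid constants, outflow split)
#'
#' @param diameter Inlet diameter d (mm).
#' @param fluid_density Blood density rho (kg/m^3).
#' @param fluid_viscosity Dynamic viscosity mu (Pa s).
#' @param outflow_split Flow split between the two outlets (MCA:ACA);
#'   positive, sums to 1.
#' @return An `inlet_spec`.
#' @export
inlet_spec <- function(diameter = 4, fluid_density = 1056,
                       fluid_viscosity = 0.0035,
                       outflow_split = c(0.65, 0.35)) {
  stopifnot(diameter > 0, fluid_density > 0, fluid_viscosity > 0,
            length(outflow_split) == 2, all(outflow_split > 0),
            abs(sum(outflow_split) - 1) < 1e-9)
  structure(list(diameter = diameter, fluid_density = fluid_density,
                 fluid_viscosity = fluid_viscosity,
                 outflow_split = outflow_split),
            class = "inlet_spec")
}

#' Mean inlet velocity and Reynolds number
#'
#' `inlet_mean_velocity` evaluates v_mean(t) = q(t) / (pi (d/2)^2) by linear
#' interpolation of the waveform. `peak_reynolds` converts to SI and returns
#' Re = rho v d / mu at the cycle maximum.
#'
#' @param wave A `waveform`.
#' @param inlet An `inlet_spec`.
#' @param t Time(s) within one period (s).
#' @return Velocity in mm/s; Reynolds number (dimensionless).
#' @export
inlet_mean_velocity <- function(wave, inlet, t) {
  stopifnot(inherits(wave, "waveform"), inherits(inlet, "inlet_spec"))
  if (inlet$diameter <= 0) stop("inlet diameter must be positive")
  if (any(t < 0 | t > wave$period)) stop("t outside one period")
  q <- approx(wave$times, wave$flow_rates, xout = t, rule = 2)$y
  q / (pi * (inlet$diameter / 2)^2)
}

#' @rdname inlet_mean_velocity
#' @export
peak_reynolds <- function(wave, inlet) {
  v_peak <- max(wave$flow_rates) / (pi * (inlet$diameter / 2)^2)  # mm/s
  v_si <- v_peak / 1000
  d_si <- inlet$diameter / 1000
  inlet$fluid_density * v_si * d_si / inlet$fluid_viscosity
}

# ---- synthetic WSS field ---------------------------------------------------

#' Specification of the synthetic wall-shear-stress field
#'
#' The generator stands in for a CFD solve. It is constructed so that the
#' cycle-averaged field reproduces the canonical spatial pattern of
#' saccular-aneurysm hemodynamics: low time-averaged WSS over the sac
#' (strongest at the dome), elevated oscillatory shear (direction reversal)
#' over the sac body, and a steep tangential magnitude ramp across the neck
#' giving a high WSS spatial gradient there.
#'
#' @param base_magnitude Parent-vessel WSS scale (Pa).
#' @param dome_attenuation Multiplicative attenuation of sac WSS at the
#'   dome, in (0, 1].
#' @param neck_gradient_scale Magnitude ramp slope across the neck (Pa/mm).
#' @param body_oscillation_fraction Fraction of the sac-body signal carried
#'   by a direction-reversing component, in [0, 1].
#' @param n_timesteps Number of intervals per cycle (>= 8); the stored field
#'   has `n_timesteps + 1` samples including the periodic endpoint.
#' @param spatial_jitter Relative seeded per-vertex magnitude jitter.
#' @param rng_seed Integer seed.
#' @return A `wss_synthesis_spec`.
#' @export
wss_synthesis_spec <- function(base_magnitude = 3, dome_attenuation = 0.15,
                               neck_gradient_scale = 2,
                               body_oscillation_fraction = 0.8,
                               n_timesteps = 32L, spatial_jitter = 0.05,
                               rng_seed = 1L) {
  if (n_timesteps < 8) stop("configuration error: n_timesteps must be >= 8")
  stopifnot(base_magnitude > 0, dome_attenuation > 0, dome_attenuation <= 1,
            neck_gradient_scale >= 0, body_oscillation_fraction >= 0,
            body_oscillation_fraction <= 1, spatial_jitter >= 0)
  structure(list(base_magnitude = base_magnitude,
                 dome_attenuation = dome_attenuation,
                 neck_gradient_scale = neck_gradient_scale,
                 body_oscillation_fraction = body_oscillation_fraction,
                 n_timesteps = as.integer(n_timesteps),
                 spatial_jitter = spatial_jitter,
                 rng_seed = as.integer(rng_seed)),
            class = "wss_synthesis_spec")
}

smoothstep <- function(x, lo, hi) {
  t <- pmin(1, pmax(0, (x - lo) / (hi - lo)))
  t * t * (3 - 2 * t)
}

#' Synthesize a pulsatile WSS field on a labeled mesh
#'
#' Per-vertex vector time series, exactly periodic over one cycle. The
#' magnitude follows the instantaneous waveform; sac vertices are
#' attenuated toward the dome; body vertices carry a direction-reversing
#' tangential component; a tangential magnitude ramp is laid across the
#' neck band.
#'
#' @param mesh A `labeled_surface_mesh` (aneurysm + parent regions, or
#'   parent-only for plain-vessel fixtures).
#' @param wave A `waveform`.
#' @param spec A `wss_synthesis_spec`.
#' @return A `wss_field`.
#' @export
synthesize_wss <- function(mesh, wave, spec = wss_synthesis_spec()) {
  stopifnot(inherits(mesh, "labeled_surface_mesh"),
            inherits(wave, "waveform"),
            inherits(spec, "wss_synthesis_spec"))
  nv <- nrow(mesh$vertices)
  vn <- mesh_vertex_normals(mesh)
  # vertex region = majority label of incident faces (aneurysm wins ties)
  vreg <- vertex_regions(mesh)
  has_sac <- any(vreg == "aneurysm")

  # local flow direction: parent axis projected onto the tangent plane
  axis <- parent_axis_direction(mesh)
  d_hat <- matrix(axis, nv, 3, byrow = TRUE)
  d_hat <- d_hat - vn * rowSums(d_hat * vn)
  nrm <- sqrt(rowSums(d_hat^2))
  deg <- nrm < 1e-6
  if (any(deg)) {
    # arbitrary tangent where the axis is normal to the surface
    alt <- cbind(-vn[deg, 2], vn[deg, 1], rep(0, sum(deg)))
    alt_n <- sqrt(rowSums(alt^2)); alt_n[alt_n < 1e-9] <- 1
    d_hat[deg, ] <- alt / alt_n
    nrm[deg] <- 1
  }
  d_hat <- d_hat / nrm
  o_hat <- vec_cross(vn, d_hat)

  # static magnitude profile
  m <- rep(spec$base_magnitude, nv)
  beta <- rep(0, nv)
  if (has_sac) {
    pl <- fit_neck_plane_points(mesh$neck_curve, mesh)
    hgt <- as.vector(sweep(mesh$vertices, 2, pl$centroid) %*% pl$normal)
    hmax <- max(hgt[vreg == "aneurysm"], 1e-9)
    hf <- pmin(1, pmax(0, hgt / hmax))
    sac <- vreg == "aneurysm"
    atten <- spec$dome_attenuation +
      (1 - spec$dome_attenuation) * (1 - smoothstep(hf, 0.05, 0.6))
    m[sac] <- spec$base_magnitude * atten[sac]
    # direction-reversing component over the sac body
    beta <- spec$body_oscillation_fraction *
      (smoothstep(hf, 0.10, 0.25) - smoothstep(hf, 0.60, 0.85))
    beta[!sac] <- 0
    # tangential magnitude ramp across the neck (tent on plane distance)
    w_ramp <- 0.35 * 2 * pl$r_curve
    nearneck <- abs(hgt) < w_ramp &
      (vreg %in% c("neck_band", "aneurysm", "parent_roi"))
    dcurve <- rep(Inf, nv)
    dcurve[nearneck] <- curve_min_distance(
      mesh$vertices[nearneck, , drop = FALSE], mesh$neck_curve)
    onramp <- dcurve < w_ramp
    m[onramp] <- m[onramp] +
      spec$neck_gradient_scale * (w_ramp - dcurve[onramp])
  }
  if (spec$spatial_jitter > 0) {
    m <- m * (1 + spec$spatial_jitter *
                with_seed(spec$rng_seed, rnorm(nv)))
    m <- pmax(m, 0.01 * spec$base_magnitude)
  }

  times <- seq(0, wave$period, length.out = spec$n_timesteps + 1)
  qt <- approx(wave$times, wave$flow_rates, xout = times, rule = 2)$y
  wt <- qt / mean(qt[-length(qt)])
  st <- sin(2 * pi * times / wave$period)
  wt[length(wt)] <- wt[1]                    # exact periodic closure
  st[length(st)] <- st[1]

  nt <- length(times)
  vec <- array(0, c(nv, 3, nt))
  base <- (1 - beta) * m
  osc <- beta * m
  for (k in seq_len(nt)) {
    vec[, , k] <- d_hat * (base * wt[k]) + o_hat * (osc * st[k])
  }
  t_peak <- times[which.max(qt[-length(qt)])]
  wss_field(mesh, times, vec, t_peak_systole = t_peak,
            t_end_diastole = times[nt])
}


vertex_regions <- function(mesh) {
  nv <- nrow(mesh$vertices)
  reg <- character(nv)
  pri <- c("aneurysm", "neck_band", "parent_roi", "extension", "other")
  lab <- as.character(mesh$face_region)
  for (r in rev(pri)) {
    f <- which(lab == r)
    if (length(f)) reg[unique(as.vector(mesh$faces[f, ]))] <- r
  }
  reg[reg == ""] <- "other"
  reg
}

# dominant direction of the parent vessel (area-weighted PCA of non-sac faces)
parent_axis_direction <- function(mesh) {
  lab <- as.character(mesh$face_region)
  keep <- lab %in% c("parent_roi", "extension")
  if (!any(keep)) keep <- rep(TRUE, length(lab))
  cen <- mesh_face_centroids(mesh)[keep, , drop = FALSE]
  w <- mesh_face_areas(mesh)[keep]
  mu <- colSums(cen * w) / sum(w)
  cc <- sweep(cen, 2, mu)
  ev <- eigen(crossprod(cc * sqrt(w)))$vectors[, 1]
  ev / sqrt(sum(ev^2))
}

curve_min_distance <- function(points, curve) {
  if (!nrow(points)) return(numeric(0))
  # min distance to the curve's points (curve is densely sampled)
  d2 <- outer(rowSums(points^2), rowSums(curve^2), "+") -
    2 * points %*% t(curve)
  sqrt(pmax(0, apply(d2, 1, min)))
}
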