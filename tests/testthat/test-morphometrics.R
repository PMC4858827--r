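# attach an arbitrary neck curve to a small carrier mesh so the neck-plane
# fitter can be exercised on analytic curves
curve_carrier <- function(curve) {
  m <- make_flat_patch(n = 2, L = 1)
  labeled_surface_mesh(m, rep("parent_roi", nrow(m$faces)), curve)
}

test_that("neck plane diameters: circle and ellipse, with pairwise oracle", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circ <- cbind(1.5 * cos(th), 1.5 * sin(th), 2)
  pl <- fit_neck_plane(curve_carrier(circ))
  expect_equal(pl$average_diameter, 3, tolerance = 1e-3)
  expect_lt(pl$max_diameter - pl$min_diameter, 0.01)

  ell <- cbind(2 * cos(th), sin(th), 0)
  pe <- fit_neck_plane(curve_carrier(ell))
  expect_equal(pe$max_diameter, 4, tolerance = 1e-3)
  expect_equal(pe$min_diameter, 2, tolerance = 1e-3)
  expect_equal(pe$average_diameter, 3, tolerance = 1e-3)
  # brute force over all projected vertex pairs bounds the maximum width
  expect_equal(pe$max_diameter, max(dist(ell)), tolerance = 1e-6)

  # rigid rotation leaves diameters unchanged
  R <- rotation_about(c(1, 1, 0), 33)
  rot <- curve_carrier(ell %*% t(R))
  pr <- fit_neck_plane(rot)
  expect_equal(pr$max_diameter, pe$max_diameter, tolerance = 1e-9)
  expect_equal(pr$min_diameter, pe$min_diameter, tolerance = 1e-9)

  expect_error(fit_neck_plane(curve_carrier(cbind(th, th, th))),
               "degenerate")
})

test_that("size matches the sphere-cap height and hemisphere special case", {
  ph <- default_phantom()
  pl <- fit_neck_plane(ph$mesh)
  expect_rel_equal(compute_size(ph$mesh, pl), 3 + sqrt(6.75), 0.02)

  hemi <- cached("hemisphere",
                 build_phantom_mesh(aneurysm_spec(sac_radius = 3,
                                                  neck_radius = 3,
                                                  mesh_edge_length = 0.3)))
  plh <- fit_neck_plane(hemi$mesh)
  expect_rel_equal(compute_size(hemi$mesh, plh), 3, 0.03)
})

test_that("morphometrics are rigid-invariant and scale correctly", {
  ph <- coarse_phantom()
  mr <- morphometrics(ph$mesh)
  tr <- rigid_transform(rotation_about(c(1, 2, 3), 25), c(4, -2, 7))
  mt <- morphometrics(transform_mesh(ph$mesh, tr))
  for (k in c("size", "AR", "NA", "PVD", "SR", "AA"))
    expect_equal(mt[[k]], mr[[k]], tolerance = 0.01)

  # uniform scaling: lengths scale by k, areas by k^2, ratios unchanged
  k <- 1.7
  sc <- ph$mesh
  sc$vertices <- sc$vertices * k
  sc$neck_curve <- sc$neck_curve * k
  ms <- morphometrics(sc)
  expect_equal(ms$size, k * mr$size, tolerance = 1e-4)
  expect_equal(ms[["NA"]], k^2 * mr[["NA"]], tolerance = 1e-3)
  expect_equal(ms$PVD, k * mr$PVD, tolerance = 1e-3)
  expect_equal(ms$AR, mr$AR, tolerance = 1e-4)
  expect_equal(ms$SR, mr$SR, tolerance = 1e-3)
  expect_equal(ms$AA, mr$AA, tolerance = 1e-3)
  # AR identity holds exactly by construction
  expect_equal(mr$AR * mr$neck_avg_diameter, mr$size, tolerance = 1e-12)
})

test_that("neck area: circle value and sectioned-ellipse shoelace oracle", {
  ph <- default_phantom()
  pl <- fit_neck_plane(ph$mesh)
  expect_rel_equal(compute_neck_area(ph$mesh, pl), pi * 1.5^2, 0.02)

  # equatorial section of an ellipsoid with semi-axes (2, 1): area 2*pi
  ell <- make_ellipsoid_mesh(axes = c(2, 1, 1.5), spacing = 0.1)
  loops <- section_loops(ell, c(0, 0, 0), c(0, 0, 1))
  loops <- Filter(function(l) l$closed, loops)
  expect_equal(length(loops), 1)
  pts <- loops[[1]]$points
  # independent shoelace evaluation of the ordered polygon
  n <- nrow(pts)
  j <- c(2:n, 1)
  shoelace <- abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
  expect_rel_equal(shoelace, 2 * pi, 0.01)
})

test_that("PVD: cylinder, tapered tube and explicit stations", {
  ph <- default_phantom()
  pl <- fit_neck_plane(ph$mesh)
  pvd <- compute_pvd(ph$mesh, pl)
  expect_rel_equal(as.numeric(pvd), 4, 0.02)
  expect_rel_equal(attr(pvd, "D1"), 4, 0.02)

  # linearly tapering tube: d(s) = 4 + s/6 so D(0) = 4, D(-6) = 3
  taper <- cached("taper_mesh", {
    vol <- sdf_volume(function(p) {
      r <- (4 + p[, 1] / 6) / 2
      pmax(sqrt(p[, 2]^2 + p[, 3]^2) - r, abs(p[, 1]) - 7.5)
    }, c(-8, -3, -3), c(8, 3, 3), 0.2)
    m <- extract_surface(vol, 0)
    labeled_surface_mesh(m, rep("parent_roi", nrow(m$faces)))
  })
  pvd2 <- compute_pvd(taper, stations = c(0, -6), axis = c(1, 0, 0))
  expect_rel_equal(attr(pvd2, "D1"), 4, 0.02)
  expect_rel_equal(attr(pvd2, "D2"), 3, 0.02)
  expect_rel_equal(as.numeric(pvd2), 3.5, 0.02)

  # too-short parent cannot reach the D2 station
  short <- cached("short_tube", {
    vol <- sdf_volume(function(p) {
      pmax(sqrt(p[, 2]^2 + p[, 3]^2) - 2, abs(p[, 1]) - 2)
    }, c(-2, -2, -2), c(2, 2, 2), 0.2)
    m <- extract_surface(vol, 0)
    labeled_surface_mesh(m, rep("parent_roi", nrow(m$faces)),
                         cbind(1.5 * cos(seq(0, 2 * pi, length.out = 48)),
                               1.5 * sin(seq(0, 2 * pi, length.out = 48)), 2))
  })
  expect_error(compute_pvd(short), "short|section")
})

test_that("SR and AA: perpendicular sac, tilted sac, PVD scaling", {
  ph <- default_phantom()
  pl <- fit_neck_plane(ph$mesh)
  sraa <- compute_sr_aa(ph$mesh, pl, pvd = 4)
  h <- 3 + sqrt(6.75)
  expect_rel_equal(sraa$H_max, h, 0.02)
  expect_rel_equal(sraa$SR, h / 4, 0.02)
  expect_gt(sraa$AA, 88)
  expect_lte(sraa$AA, 90)
  # halving PVD doubles SR at fixed sac
  sr2 <- compute_sr_aa(ph$mesh, pl, pvd = 2)
  expect_equal(sr2$SR, 2 * sraa$SR, tolerance = 1e-12)

  tilted <- cached("tilted30",
                   build_phantom_mesh(aneurysm_spec(sac_offset_angle = 30,
                                                    mesh_edge_length = 0.3)))
  expect_equal(tilted$ground_truth$AA, 60)
  mrt <- compute_sr_aa(tilted$mesh, fit_neck_plane(tilted$mesh),
                       pvd = 4)
  expect_lt(abs(mrt$AA - 60), 2)
})

test_that("phantom morphometrics track the analytic ground truth within 2%", {
  ph <- coarse_phantom()
  mr <- morphometrics(ph$mesh)
  gt <- ph$ground_truth
  for (k in c("size", "AR", "NA", "PVD", "SR", "AA"))
    expect_rel_equal(mr[[k]], gt[[k]], 0.02)
})
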