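test_that("identical meshes are at zero distance and self-alignment is identity", {
  mesh <- make_sphere_mesh(r = 4, spacing = 0.35)
  dr <- symmetric_distance(mesh, mesh)
  expect_equal(dr$mean, 0, tolerance = 1e-12)
  expect_equal(dr$max, 0, tolerance = 1e-12)
  tr <- rigid_align(mesh, mesh)
  expect_lt(max(abs(tr - diag(4))), 1e-6)
})

test_that("ICP recovers a known rigid perturbation", {
  ph <- coarse_phantom()
  mesh <- ph$mesh
  R <- rotation_about(c(0.2, 1, 0.4), 10)
  tr <- rigid_transform(R, c(2, -1, 0.7))
  moving <- transform_mesh(mesh, tr)
  rec <- rigid_align(moving, mesh)
  expect_true(attr(rec, "converged"))
  # recovered transform must invert the perturbation
  comp <- rec %*% tr
  expect_lt(max(abs(comp - diag(4))), 1e-3)
  moved <- transform_mesh(moving, rec)
  d <- mesh_closest_point(moved$vertices, mesh)$distance
  expect_lt(mean(d), 0.01)
  # rotation block stays a proper rotation
  Rr <- rec[1:3, 1:3]
  expect_lt(max(abs(crossprod(Rr) - diag(3))), 1e-9)
  expect_equal(det(Rr), 1, tolerance = 1e-9)
})

test_that("concentric spheres read the radial gap; the report is symmetric", {
  a <- cached("sphere5", make_sphere_mesh(r = 5, spacing = 0.25))
  b <- make_sphere_mesh(r = 5.3, spacing = 0.25)
  d1 <- symmetric_distance(a, b)
  expect_lt(abs(d1$mean - 0.3), 0.25 / 2)
  expect_lt(abs(d1$max - 0.3), 0.25)
  d2 <- symmetric_distance(b, a)
  expect_equal(d2$mean, d1$mean, tolerance = 1e-12)
  expect_equal(d2$max, d1$max, tolerance = 1e-12)
  expect_error(symmetric_distance(a, surface_mesh(matrix(0, 0, 3),
                                                  matrix(0L, 0, 3))),
               "empty")
})

test_that("sampled Hausdorff distances satisfy the triangle inequality", {
  a <- make_sphere_mesh(r = 4, spacing = 0.25)
  b <- make_sphere_mesh(r = 4.4, spacing = 0.25)
  c <- make_sphere_mesh(r = 4.9, spacing = 0.25)
  dab <- symmetric_distance(a, b)$max
  dbc <- symmetric_distance(b, c)$max
  dac <- symmetric_distance(a, c)$max
  expect_lte(dac, dab + dbc + 0.25)
})

test_that("doubling the sampling density changes the mean by < 2%", {
  ph <- coarse_phantom()
  other <- build_phantom_mesh(aneurysm_spec(mesh_edge_length = 0.3,
                                            sac_radius = 3.1))
  d1 <- symmetric_distance(ph$mesh, other$mesh, density = 5)
  d2 <- symmetric_distance(ph$mesh, other$mesh, density = 10)
  expect_lt(abs(d1$mean - d2$mean) / d2$mean, 0.02)
})
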