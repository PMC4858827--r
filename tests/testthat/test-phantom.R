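test_that("sphere-cap ground truth matches closed-form and sampling oracle", {
  spec <- aneurysm_spec(sac_radius = 3, neck_radius = 1.5, parent_radius = 2)
  gt <- phantom_ground_truth(spec)
  h <- 3 + sqrt(9 - 2.25)
  expect_equal(gt$size, h, tolerance = 1e-12)
  expect_equal(gt[["NA"]], pi * 1.5^2, tolerance = 1e-12)
  expect_equal(gt$AR, h / 3, tolerance = 1e-12)
  expect_equal(gt$PVD, 4)
  expect_equal(gt$SR, h / 4, tolerance = 1e-12)
  expect_equal(gt$AA, 90)

  # brute-force oracle: dense sampling of the implicit lumen
  sdf <- aneurysm_sdf(spec)
  z_ap <- 2 + spec$neck_standoff
  # size: highest lumen point above the aperture plane, via fine vertical probing
  zs <- seq(z_ap, z_ap + 8, by = 0.001)
  probe <- cbind(0, 0, zs)
  size_oracle <- max(zs[sdf(probe) < 0]) - z_ap
  expect_rel_equal(size_oracle, gt$size, 0.005)
  # neck area: in-plane occupancy integration at the aperture
  s <- 0.01
  xy <- as.matrix(expand.grid(x = seq(-2, 2, by = s), y = seq(-2, 2, by = s)))
  na_oracle <- sum(sdf(cbind(xy, z_ap + 1e-6)) < 0) * s^2
  expect_rel_equal(na_oracle, gt[["NA"]], 0.005)
})

test_that("degenerate sac-free spec gives a plain tube with undefined metrics", {
  spec <- aneurysm_spec(sac_radius = 0, mesh_edge_length = 0.3)
  ph <- build_phantom_mesh(spec)
  expect_true(ph$ground_truth$undefined)
  expect_true(is.na(ph$ground_truth$size))
  expect_true(all(ph$mesh$face_region == "parent_roi"))
  # capped-tube surface area: lateral 2*pi*r*L plus two end caps
  expect_rel_equal(mesh_area(ph$mesh), 2 * pi * 2 * 16 + 2 * pi * 4, 0.01)
})

test_that("phantom meshes are watertight with genus-0 topology", {
  ph <- coarse_phantom()
  expect_true(mesh_is_watertight(ph$mesh))
  expect_equal(mesh_euler(ph$mesh), 2)
  expect_true(all(table(ph$mesh$face_region)[c("aneurysm", "parent_roi")] > 0))
})

test_that("voxelize reproduces analytic volumes and exact clean occupancy", {
  sph <- cached("sphere5", make_sphere_mesh(r = 5, spacing = 0.25))
  prof <- modality_profile("DRA_like", voxel_spacing = 0.25, psf_sigma = 0,
                           noise_sigma = 0)
  vol <- voxelize(sph, prof, pad = 1)
  mid <- (prof$lumen_intensity + prof$background_intensity) / 2
  vox_vol <- sum(vol$data >= mid) * prod(vol$spacing)
  expect_rel_equal(vox_vol, 4 / 3 * pi * 125, 0.02)

  # clean spec voxelization thresholded at mid-intensity = exact occupancy
  spec <- aneurysm_spec(mesh_edge_length = 0.3)
  v2 <- voxelize(spec, modality_profile("CTA_like", psf_sigma = 0,
                                        noise_sigma = 0))
  ax <- volume_axes(v2)
  gp <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  occupancy <- array(aneurysm_sdf(spec)(gp) <= 0, dim(v2$data))
  expect_identical(v2$data >= mid, occupancy)
})

test_that("voxelize is deterministic given the profile seed", {
  spec <- aneurysm_spec(mesh_edge_length = 0.3)
  prof <- modality_profile("MRA_like", rng_seed = 42L)
  v1 <- voxelize(spec, prof)
  v2 <- voxelize(spec, prof)
  expect_identical(v1$data, v2$data)
  v3 <- voxelize(spec, modality_profile("MRA_like", rng_seed = 43L))
  expect_false(identical(v1$data, v3$data))
})

test_that("voxelize records a warning when voxels exceed the smallest feature", {
  spec <- aneurysm_spec(mesh_edge_length = 0.3)
  prof <- modality_profile("MRA_like", voxel_spacing = 2)
  vol <- voxelize(spec, prof)
  expect_true(length(vol$meta$warnings) > 0)
})

test_that("inlet mean velocity follows q / (pi (d/2)^2)", {
  wave <- waveform(c(0, 0.4, 0.8), rep(pi, 3), period = 0.8)
  inlet <- inlet_spec(diameter = 2)
  expect_equal(inlet_mean_velocity(wave, inlet, 0.2), 1, tolerance = 1e-12)
  # doubling the diameter divides the velocity by 4
  inlet2 <- inlet_spec(diameter = 4)
  expect_equal(inlet_mean_velocity(wave, inlet2, 0.2), 0.25,
               tolerance = 1e-12)
  expect_error(inlet_mean_velocity(wave, inlet, 1.5), "period")
})

test_that("default waveform with the default inlet hits the ICA Reynolds range", {
  re <- peak_reynolds(default_waveform(), inlet_spec())
  expect_gte(re, 500)
  expect_lte(re, 750)
})

test_that("synthesized WSS is periodic, deterministic and regionally patterned", {
  ph <- coarse_phantom()
  wave <- default_waveform()
  spec <- wss_synthesis_spec(rng_seed = 5L)
  f1 <- synthesize_wss(ph$mesh, wave, spec)
  f2 <- synthesize_wss(ph$mesh, wave, spec)
  expect_identical(f1$vectors, f2$vectors)
  nt <- dim(f1$vectors)[3]
  expect_identical(f1$vectors[, , 1], f1$vectors[, , nt])

  vreg <- aneumorph:::vertex_regions(ph$mesh)
  awss <- time_average_wss(f1)
  osi <- compute_osi(f1)
  awssg <- compute_awssg(f1)
  pl <- fit_neck_plane(ph$mesh)
  hgt <- as.vector(sweep(ph$mesh$vertices, 2, pl$centroid) %*% pl$unit_normal)
  hmax <- max(hgt)
  dome <- vreg == "aneurysm" & hgt > 0.66 * hmax
  body <- vreg == "aneurysm" & hgt > 0.15 * hmax & hgt <= 0.66 * hmax
  parent <- vreg == "parent_roi"
  neckband <- vreg == "neck_band"
  expect_lt(mean(awss[dome]), mean(awss[parent]))
  expect_gt(mean(osi[body]), mean(osi[parent]))
  expect_gt(mean(awssg[neckband]), mean(awssg[dome]))
})

test_that("zero oscillation and a constant waveform give zero OSI everywhere", {
  ph <- coarse_phantom()
  wave <- waveform(seq(0, 0.8, length.out = 9), rep(4000, 9), period = 0.8)
  f <- synthesize_wss(ph$mesh, wave,
                      wss_synthesis_spec(body_oscillation_fraction = 0,
                                         spatial_jitter = 0))
  expect_lt(max(compute_osi(f)), 1e-10)
})

test_that("n_timesteps below 8 is a configuration error", {
  expect_error(wss_synthesis_spec(n_timesteps = 4), "n_timesteps")
})
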