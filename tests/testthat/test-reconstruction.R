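clean_profile <- function(spacing = 0.3)
  modality_profile("CTA_like", voxel_spacing = spacing, psf_sigma = 0,
                   noise_sigma = 0)

test_that("threshold segmentation recovers exact clean occupancy and errors when empty", {
  spec <- aneurysm_spec(mesh_edge_length = 0.3)
  vol <- voxelize(spec, clean_profile())
  mask <- threshold_segment(vol, segmentation_config(threshold = 55))
  ax <- volume_axes(vol)
  gp <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  expect_identical(as.vector(mask),
                   as.vector(aneurysm_sdf(spec)(gp) <= 0))
  # auto threshold lands between the two intensity modes
  thr <- auto_threshold(vol)
  expect_gt(thr, 20)
  expect_lt(thr, 90)
  empty <- image_volume(array(0, c(5, 5, 5)))
  expect_error(threshold_segment(empty, segmentation_config(threshold = 1)),
               "empty segmentation")
})

test_that("noisy segmentation recovers the equivalent radius within half a voxel", {
  sph <- cached("sphere5", make_sphere_mesh(r = 5, spacing = 0.25))
  prof <- modality_profile("CTA_like", voxel_spacing = 0.25, psf_sigma = 0,
                           noise_sigma = 0.03, rng_seed = 7L)
  vol <- voxelize(sph, prof)
  mask <- threshold_segment(vol, segmentation_config())
  mask <- region_grow(mask, c(0, 0, 0), vol)
  r_eq <- (3 * sum(mask) * prod(vol$spacing) / (4 * pi))^(1 / 3)
  expect_lt(abs(r_eq - 5), 0.125)
})

test_that("region growing keeps only the seed component", {
  d <- c(40, 20, 20)
  mask <- array(FALSE, d)
  ix <- as.matrix(expand.grid(x = 1:40, y = 1:20, z = 1:20))
  a <- sqrt(rowSums(sweep(ix, 2, c(10, 10, 10))^2)) < 6
  b <- sqrt(rowSums(sweep(ix, 2, c(30, 10, 10))^2)) < 5
  mask[ix[a | b, ]] <- TRUE
  grown <- region_grow(mask, c(10, 10, 10))
  expect_equal(sum(grown), sum(a))
  # identity on a single component
  m2 <- array(FALSE, d); m2[ix[a, ]] <- TRUE
  expect_identical(as.vector(region_grow(m2, c(10, 10, 10))),
                   as.vector(m2))
  # seed outside the mask suggests the nearest in-mask voxel
  expect_error(region_grow(mask, c(20, 10, 10)), "nearest in-mask")
})

test_that("extract_surface honours world coordinates and sphere accuracy", {
  vol <- sdf_volume(function(p) sqrt(rowSums(p^2)) - 5,
                    rep(-5, 3), rep(5, 3), 0.25)
  mesh <- extract_surface(vol, 0)
  expect_true(mesh_is_watertight(mesh))
  expect_equal(mesh_euler(mesh), 2)
  d_err <- abs(sqrt(rowSums(mesh$vertices^2)) - 5)
  expect_lte(mean(d_err), 0.25)
  # translating the volume origin translates the vertices identically
  vol2 <- image_volume(vol$data, vol$spacing, vol$origin + c(1, 2, 3))
  mesh2 <- extract_surface(vol2, 0)
  expect_equal(mesh2$vertices,
               sweep(mesh$vertices, 2, c(1, 2, 3), "+"),
               tolerance = 1e-12)
  # mask touching the border is refused
  solid <- image_volume(array(1, c(8, 8, 8)))
  expect_error(extract_surface(solid, 0.5), "pad")
})

test_that("surface smoothing preserves topology, volume and reduces curvature noise", {
  mesh <- make_sphere_mesh(r = 3, spacing = 0.3)
  expect_identical(smooth_surface(mesh, passes = 0), mesh)
  set.seed(11)
  noisy <- mesh
  vn <- mesh_vertex_normals(mesh)
  noisy$vertices <- noisy$vertices + vn * rnorm(nrow(vn), sd = 0.05)
  sm <- smooth_surface(noisy, sigma = 0.3, passes = 10)
  expect_identical(dim(sm$faces), dim(noisy$faces))
  expect_gte(abs(mesh_volume(sm)), 0.95 * abs(mesh_volume(noisy)))
  expect_lte(var(curvature_proxy(sm)), var(curvature_proxy(noisy)))
})

test_that("region partition is a complete labeling with the stated parent extent", {
  ph <- default_phantom()
  mesh <- ph$mesh
  expect_false(anyNA(mesh$face_region))
  expect_equal(length(mesh$face_region), nrow(mesh$faces))
  # D1 = 4 mm: parent ROI reaches 6 mm along the centerline on each side
  cen <- mesh_face_centroids(mesh)
  s <- cen[, 1]
  roi <- mesh$face_region == "parent_roi"
  ext <- mesh$face_region == "extension"
  expect_lt(max(abs(s[roi])), 6 + 0.3)
  expect_gt(max(abs(s[roi])), 6 - 0.3)
  expect_gt(min(abs(s[ext])), 6 - 0.3)
  # labeled aneurysm area close to the analytic spherical cap
  sac_area <- sum(mesh_face_areas(mesh)[mesh$face_region == "aneurysm"])
  expect_rel_equal(sac_area, 2 * pi * 3 * (3 + sqrt(6.75)), 0.02)
})

test_that("noise-free voxelize/reconstruct round trip stays within one voxel", {
  spec <- aneurysm_spec(mesh_edge_length = 0.25)
  truth <- cached("phantom025", build_phantom_mesh(spec))$mesh
  s <- 0.3
  vol <- voxelize(spec, clean_profile(s))
  mesh <- reconstruct_model(vol, segmentation_config(seed_point = c(0, 0, 0)))
  dr <- symmetric_distance(truth, mesh, density = 4)
  expect_lte(dr$mean, s)
})

test_that("reconstruction is idempotent on clean data", {
  spec <- aneurysm_spec(mesh_edge_length = 0.25)
  prof <- modality_profile("DRA_like", voxel_spacing = 0.25, psf_sigma = 0,
                           noise_sigma = 0)
  cfg <- segmentation_config(seed_point = c(0, 0, 0))
  r1 <- reconstruct_model(voxelize(spec, prof), cfg)
  r2 <- reconstruct_model(voxelize(r1, prof), cfg)
  dr <- symmetric_distance(r1, r2, density = 4)
  expect_lt(dr$mean, 0.05)
})
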