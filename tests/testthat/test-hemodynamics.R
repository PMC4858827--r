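one_vertex_field <- function(fx, nt = 33, period = 1) {
  times <- seq(0, period, length.out = nt)
  v <- array(0, c(1, 3, nt))
  v[1, 1, ] <- fx(times)
  list(vectors = v, times = times)
}

test_that("AWSS: constant field, zero-mean sine, offset sine vs quadrature oracle", {
  f <- one_vertex_field(function(t) rep(2, length(t)))
  expect_equal(time_average_wss(f$vectors, f$times), 2, tolerance = 1e-12)

  f <- one_vertex_field(function(t) sin(2 * pi * t))
  expect_lt(time_average_wss(f$vectors, f$times), 1e-10)

  f <- one_vertex_field(function(t) 1 + sin(2 * pi * t))
  oracle <- integrate(function(t) 1 + sin(2 * pi * t), 0, 1,
                      rel.tol = 1e-10)$value
  expect_lt(abs(time_average_wss(f$vectors, f$times) - oracle), 1e-3)

  expect_error(time_average_wss(array(0, c(1, 3, 2)), c(0, 1)), "3 time")
})

test_that("OSI: fixed direction 0, square wave 0.5, offset sine vs oracle", {
  # varying magnitude, fixed sign
  f <- one_vertex_field(function(t) 1 + 0.5 * sin(2 * pi * t))
  expect_equal(as.numeric(compute_osi(f$vectors, f$times)), 0,
               tolerance = 1e-12)
  # square-wave reversal with periodic closure: exactly 0.5
  sq <- one_vertex_field(function(t) ifelse(t < 0.5 | t >= 1, 1, -1))
  expect_equal(as.numeric(compute_osi(sq$vectors, sq$times)), 0.5,
               tolerance = 1e-12)
  # 1 + 2 sin: reversing part of the cycle; oracle by adaptive quadrature
  f <- one_vertex_field(function(t) 1 + 2 * sin(2 * pi * t), nt = 513)
  num <- abs(integrate(function(t) 1 + 2 * sin(2 * pi * t), 0, 1,
                       rel.tol = 1e-10)$value)
  den <- integrate(function(t) abs(1 + 2 * sin(2 * pi * t)), 0, 1,
                   rel.tol = 1e-10, subdivisions = 400)$value
  oracle <- 0.5 * (1 - num / den)
  expect_equal(as.numeric(compute_osi(f$vectors, f$times)), oracle,
               tolerance = 1e-3)
  expect_equal(round(oracle, 3), 0.152)
  # identically-zero WSS is defined as OSI 0 and flagged
  z <- array(0, c(2, 3, 5))
  osi <- compute_osi(z, seq(0, 1, length.out = 5))
  expect_equal(as.numeric(osi), c(0, 0))
  expect_equal(attr(osi, "zero_wss"), c(1L, 2L))
})

test_that("OSI stays in [0, 0.5] and AWSS obeys the integral triangle inequality", {
  set.seed(42)
  for (rep in 1:20) {
    nv <- 7; nt <- 17
    times <- seq(0, 0.8, length.out = nt)
    v <- array(rnorm(nv * 3 * nt), c(nv, 3, nt))
    osi <- compute_osi(v, times)
    expect_true(all(osi >= 0 & osi <= 0.5))
    awss <- time_average_wss(v, times)
    mag <- sqrt(v[, 1, ]^2 + v[, 2, ]^2 + v[, 3, ]^2)
    mean_mag <- aneumorph:::trapz_rows(mag, times) / 0.8
    expect_true(all(awss <= mean_mag + 1e-12))
  }
})

test_that("surface gradient reproduces linear fields and converges on quadratics", {
  patch <- make_flat_patch(n = 16, L = 4)
  interior <- attr(patch, "interior")
  g <- surface_gradient(patch, 3 * patch$vertices[, 1])
  expect_lt(max(abs(g[interior, 1] - 3)), 1e-10)
  expect_lt(max(abs(g[interior, 2:3])), 1e-10)
  g0 <- surface_gradient(patch, rep(5, nrow(patch$vertices)))
  expect_lt(max(abs(g0)), 1e-10)

  # refinement on an irregular patch (the uniform grid superconverges)
  err <- sapply(c(16, 32), function(n) {
    p <- make_flat_patch(n = n, L = 4, jitter = 0.25)
    ii <- attr(p, "interior")
    gg <- surface_gradient(p, p$vertices[, 1]^2)
    max(abs(gg[ii, 1] - 2 * p$vertices[ii, 1]))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.15)
})

test_that("AWSSG: linear fields give the closed-form root-sum-square", {
  patch <- make_flat_patch(n = 12, L = 4)
  interior <- attr(patch, "interior")
  nt <- 9
  times <- seq(0, 0.8, length.out = nt)
  mk_field <- function(fmat) {
    v <- array(0, c(nrow(patch$vertices), 3, nt))
    for (k in seq_len(nt)) v[, , k] <- fmat
    wss_field(patch, times, v)
  }
  # wss_x = 2x: AWSSG = 2 Pa/mm at interior vertices
  f1 <- mk_field(cbind(2 * patch$vertices[, 1], 0, 0))
  a1 <- compute_awssg(f1)
  expect_lt(max(abs(a1[interior] - 2)), 1e-9)
  # spatially uniform field: zero gradient
  f2 <- mk_field(cbind(3, 1, -2)[rep(1, nrow(patch$vertices)), ])
  expect_lt(max(abs(compute_awssg(f2))), 1e-9)
  # wss_x = a x, wss_y = b y: sqrt(a^2 + b^2)
  a <- 1.3; b <- -0.7
  f3 <- mk_field(cbind(a * patch$vertices[, 1], b * patch$vertices[, 2], 0))
  a3 <- compute_awssg(f3)
  expect_lt(max(abs(a3[interior] - sqrt(a^2 + b^2))), 1e-9)
})

test_that("AWSSG scales as 1/k under uniform spatial scaling at fixed WSS", {
  ph <- coarse_phantom()
  f <- synthesize_wss(ph$mesh, default_waveform(),
                      wss_synthesis_spec(n_timesteps = 8))
  a1 <- compute_awssg(f)
  k <- 2
  mesh2 <- ph$mesh
  mesh2$vertices <- mesh2$vertices * k
  f2 <- wss_field(mesh2, f$times, f$vectors, f$t_peak_systole,
                  f$t_end_diastole)
  expect_equal(compute_awssg(f2), a1 / k, tolerance = 1e-9)
})

test_that("regional statistics: uniform and half-low constructions", {
  # labeled flat patch: odd grid so no vertex sits on the half split
  patch <- make_flat_patch(n = 15, L = 4)
  cen <- mesh_face_centroids(patch)
  lab <- ifelse(cen[, 2] > 2, "aneurysm", "parent_roi")
  lm <- labeled_surface_mesh(patch, lab)
  nv <- nrow(lm$vertices)
  nt <- 9
  times <- seq(0, 0.8, length.out = nt)
  vx <- rep(1, nv)
  v <- array(0, c(nv, 3, nt))
  for (k in seq_len(nt)) v[, , k] <- cbind(vx, 0, 0)
  f <- wss_field(lm, times, v)
  rep1 <- regional_statistics(f)
  expect_equal(rep1$MWSS_A, 1, tolerance = 1e-12)
  expect_equal(rep1$WSS90_A, 1, tolerance = 1e-12)
  expect_equal(rep1$LWSS_A, 0)
  expect_equal(rep1$AWSS_A, 1, tolerance = 1e-12)
  expect_equal(rep1$OSI_A, 0, tolerance = 1e-12)

  # half the aneurysm (split at x = 2, no vertex on the split) at 0.2 Pa,
  # half at 1 Pa; the exact area fraction is recomputed by an independent
  # barycentric-area oracle and sits near one half
  vx2 <- ifelse(lm$vertices[, 1] < 2, 0.2, 1)
  v2 <- v
  for (k in seq_len(nt)) v2[, , k] <- cbind(vx2, 0, 0)
  f2 <- wss_field(lm, times, v2)
  rep2 <- regional_statistics(f2)
  # oracle vertex areas: one third of incident triangle areas
  areas <- sapply(seq_len(nrow(lm$faces)), function(i) {
    f <- lm$faces[i, ]
    ab <- lm$vertices[f[2], ] - lm$vertices[f[1], ]
    ac <- lm$vertices[f[3], ] - lm$vertices[f[1], ]
    nrm <- c(ab[2] * ac[3] - ab[3] * ac[2], ab[3] * ac[1] - ab[1] * ac[3],
             ab[1] * ac[2] - ab[2] * ac[1])
    sqrt(sum(nrm^2)) / 2
  })
  va_o <- numeric(nrow(lm$vertices))
  for (i in seq_len(nrow(lm$faces)))
    va_o[lm$faces[i, ]] <- va_o[lm$faces[i, ]] + areas[i] / 3
  sac_v <- which(sapply(seq_len(nrow(lm$vertices)), function(v0)
    any(lab[rowSums(lm$faces == v0) > 0] == "aneurysm")))
  frac_oracle <- sum(va_o[sac_v][vx2[sac_v] < 0.4]) / sum(va_o[sac_v])
  expect_equal(rep2$LWSS_A, frac_oracle, tolerance = 1e-10)
  expect_lt(abs(rep2$LWSS_A - 0.5), 0.01)

  # missing region label errors by name
  bad <- labeled_surface_mesh(patch, rep("parent_roi", nrow(patch$faces)))
  fb <- wss_field(bad, times, v)
  expect_error(regional_statistics(fb), "aneurysm")
})

test_that("area-weighted percentile matches a sort-and-accumulate oracle", {
  set.seed(9)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    w <- runif(n, 0.1, 2)
    p <- runif(1, 0.05, 0.95)
    got <- weighted_quantile(x, w, p)
    # oracle: step-function inverse CDF over sorted (area, value) pairs;
    # the interpolated estimate must sit within one order statistic of it
    o <- order(x)
    xo <- x[o]; cw <- cumsum(w[o]) / sum(w)
    k <- which(cw >= p)[1]
    expect_gte(got, xo[max(1, k - 1)] - 1e-12)
    expect_lte(got, xo[min(n, k + 1)] + 1e-12)
  }
})

test_that("report fields are invariant under rigid motion of mesh and vectors", {
  ph <- coarse_phantom()
  f <- synthesize_wss(ph$mesh, default_waveform(),
                      wss_synthesis_spec(n_timesteps = 8))
  rep1 <- regional_statistics(f)
  R <- rotation_about(c(0, 1, 1), 40)
  tr <- rigid_transform(R, c(1, -3, 2))
  mesh2 <- transform_mesh(ph$mesh, tr)
  v2 <- f$vectors
  for (k in seq_len(dim(v2)[3])) v2[, , k] <- f$vectors[, , k] %*% t(R)
  rep2 <- regional_statistics(wss_field(mesh2, f$times, v2,
                                        f$t_peak_systole, f$t_end_diastole))
  for (k in c("AWSS_A", "AWSS_P", "LWSS_A", "MWSS_A", "WSS90_A",
              "OSI_A", "MOSI_A", "HOSI_A", "AWSSG_A"))
    expect_equal(rep2[[k]], rep1[[k]], tolerance = 1e-8)
})

test_that("quadrature converges: doubling timesteps moves AWSS/OSI by < 0.5%", {
  ph <- coarse_phantom()
  f32 <- synthesize_wss(ph$mesh, default_waveform(),
                        wss_synthesis_spec(n_timesteps = 32))
  f64 <- synthesize_wss(ph$mesh, default_waveform(n = 64),
                        wss_synthesis_spec(n_timesteps = 64))
  a32 <- mean(time_average_wss(f32)); a64 <- mean(time_average_wss(f64))
  o32 <- mean(compute_osi(f32)); o64 <- mean(compute_osi(f64))
  expect_lt(abs(a32 - a64) / a64, 0.005)
  expect_lt(abs(o32 - o64) / max(o64, 1e-9), 0.005)
})
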