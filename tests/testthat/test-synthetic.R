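test_that("scenes and scans are bit-reproducible for a fixed seed", {
  a <- generate_canopy(4, seed = 5L)
  b <- generate_canopy(4, seed = 5L)
  expect_identical(a, b)
  expect_false(identical(a, generate_canopy(4, seed = 6L)))
  cfg <- scanner_config(seed = 9L, angular_step = 0.002)
  s1 <- simulate_scan(a$leaves, cfg, 20L, 10L)
  s2 <- simulate_scan(a$leaves, cfg, 20L, 10L)
  expect_identical(s1$clouds, s2$clouds)
  expect_identical(s1$transforms, s2$transforms)
})

test_that("a flat elliptical leaf has the closed-form area", {
  leaf <- parametric_leaf(1, length = 0.2, width = 0.1, curvature = 0)
  expect_equal(leaf$true_area, pi * 0.1 * 0.05, tolerance = 1e-6)
  # curvature only adds area
  withr::local_seed(10)
  for (i in 1:10) {
    L <- runif(1, 0.05, 0.25)
    W <- L * runif(1, 0.5, 0.7)
    A <- L * runif(1, 0.05, 0.25)
    bent <- parametric_leaf(1, length = L, width = W, curvature = A,
                            inclination_deg = runif(1, 0, 75))
    expect_gte(bent$true_area, pi * (L / 2) * (W / 2) * (1 - 1e-9))
  }
})

test_that("scene truth satisfies the LAI conservation identity", {
  scene <- generate_canopy(8, seed = 23L)
  expect_equal(scene$truth$lai * scene$truth$footprint_area,
               sum(scene$truth$leaf_table$true_area), tolerance = 1e-6)
  expect_equal(sum(scene$truth$lad$lad) * scene$truth$layer_thickness,
               scene$truth$lai, tolerance = 1e-9)
})

test_that("single-ray intersections match the closed-form oracle", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(ray_triangle_intersect(c(0.25, 0.25, 1), c(0, 0, -1), tri), 1)
  expect_true(is.na(ray_triangle_intersect(c(0, 0, 1), c(1, 0, 0), tri)))
  withr::local_seed(14)
  n_hit <- 0L
  for (i in 1:20000) {
    tri <- matrix(rnorm(9), 3, 3)
    o <- rnorm(3)
    d <- rnorm(3)
    d <- d / sqrt(sum(d^2))
    got <- ray_triangle_intersect(o, d, tri)
    want <- oracle_ray_tri(o, d, tri)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(got)) {
      n_hit <- n_hit + 1L
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  expect_gt(n_hit, 100L)  # the comparison exercised real hits
})

test_that("the beam-grid scanner equals the exhaustive nearest-hit oracle", {
  scene <- generate_canopy(2, seed = 41L)
  tess <- lapply(scene$leaves, tessellate_leaf, n_u = 5L, n_t = 4L)
  comb <- combine_meshes(tess)
  cfg <- scanner_config(seed = 42L, angular_step = 0.004,
                        range_noise_sd = 0)  # coarse grid, no noise
  sim <- simulate_scan(scene$leaves, cfg, tessellation_n_u = 5L,
                       tessellation_n_t = 4L)
  for (k in 1:3) {
    cloud <- sim$clouds[[k]]
    inv <- invert_transform(sim$transforms[[k]])
    verts_local <- transform_points(comb$vertices, inv)
    for (i in seq_len(min(400, n_points(cloud)))) {
      p <- cloud$points[i, ]
      d <- p / sqrt(sum(p^2))
      t_oracle <- brute_nearest_hit(c(0, 0, 0), d, verts_local, comb$faces)
      expect_equal(sqrt(sum(p^2)), t_oracle, tolerance = 1e-9)
    }
  }
})

test_that("a beam through a shared edge returns exactly one point", {
  # two coplanar faces sharing the vertical edge through (5, 0); a single
  # horizontal beam along +x passes exactly through that edge
  V <- rbind(c(5, 0, -1), c(5, 0, 1), c(5, 2, 0), c(5, -2, 0))
  F_ <- rbind(c(1, 2, 3), c(1, 4, 2))
  res <- canopy3d:::scan_grid_cpp(V, F_, c(1L, 2L),
                                  pi / 2, 0.001, 1L, 0, 0.001, 1L)
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$hits[1, 1], 5, tolerance = 1e-9)
})

test_that("occlusion: a lower leaf under an upper one receives fewer returns", {
  # one station looking steeply down so the upper leaf shadows the lower
  upper <- parametric_leaf(1, base = c(-0.06, 0, 1.13), length = 0.12,
                           width = 0.1)
  lower <- parametric_leaf(2, base = c(-0.06, 0, 1.10), length = 0.12,
                           width = 0.1)
  cfg <- scanner_config(n_stations = 1L, azimuths_deg = 0, range = 1.5,
                        station_height = 3, zenith_span_deg = c(128, 145),
                        seed = 2L, azimuth_jitter_deg = 0,
                        position_jitter = 0, height_jitter = 0)
  sim <- simulate_scan(list(upper, lower), cfg)
  counts <- table(factor(sim$clouds[[1]]$labels, levels = 1:2))
  expect_gt(counts[["1"]], 2 * counts[["2"]])
})

test_that("point spacing on a fronto-parallel target is ~2 mm", {
  # vertical leaf at the canopy center facing station 1
  # inclination 90 points the midrib up; azimuth 0 faces the sheet at
  # station 1, so the target is fronto-parallel at the configured range
  target <- parametric_leaf(1, base = c(0, 0, 1.35), azimuth_deg = 0,
                            inclination_deg = 90, length = 0.2, width = 0.15)
  cfg <- scanner_config(n_stations = 1L, azimuths_deg = 0, seed = 3L,
                        azimuth_jitter_deg = 0, position_jitter = 0,
                        height_jitter = 0, range_noise_sd = 0)
  sim <- simulate_scan(list(target), cfg)
  pts <- sim$clouds[[1]]$points
  expect_gt(nrow(pts), 1000)
  nn <- RANN::nn2(pts, k = 2L)
  spacing <- median(nn$nn.dists[, 2])
  expect_gt(spacing, 0.002 * 0.8)
  expect_lt(spacing, 0.002 * 1.2)
})

test_that("noise-free returns lie on the surface; noisy ones within 3 sigma", {
  scene <- generate_canopy(4, seed = 51L)
  dense <- do.call(rbind, lapply(scene$leaves, function(l) {
    leaf_quadrature(l, 500L, 200L)$points
  }))
  for (noise in c(0, 0.001)) {
    cfg <- scanner_config(seed = 52L, range_noise_sd = noise,
                          angular_step = 0.003)
    sim <- simulate_scan(scene$leaves, cfg)
    world <- lapply(1:3, function(k) {
      apply_transform(sim$clouds[[k]], sim$transforms[[k]], "world")
    })
    merged <- merge_clouds(world, frame_id = "world")
    d <- RANN::nn2(dense, merged$points, k = 1)$nn.dists[, 1]
    # slack for tessellation chord error and the finite reference sampling
    slack <- 1e-3
    expect_lt(quantile(d, 0.997), 3 * noise + slack)
  }
})

test_that("stem occluders block beams and return label 0", {
  leaf <- parametric_leaf(1, base = c(0, 0, 1.35), azimuth_deg = 0,
                          inclination_deg = 90, length = 0.2, width = 0.15)
  stem <- stem_cylinder(center_xy = c(2, 0), radius = 0.05,
                        z_bottom = 0.5, z_top = 2.2)
  cfg <- scanner_config(n_stations = 1L, azimuths_deg = 0, seed = 4L,
                        azimuth_jitter_deg = 0, position_jitter = 0,
                        height_jitter = 0, range_noise_sd = 0)
  bare <- simulate_scan(list(leaf), cfg)
  occl <- simulate_scan(list(leaf), cfg, occluders = list(stem))
  expect_true(any(occl$clouds[[1]]$labels == 0L))
  expect_lt(sum(occl$clouds[[1]]$labels == 1L),
            sum(bare$clouds[[1]]$labels == 1L))
})
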