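test_that("four corner points triangulate to the exact unit square", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  m <- triangulate_leaf(pc, meshing_params(min_points = 3L))
  expect_equal(nrow(m$faces), 2L)
  expect_equal(mesh_area(m), 1.0)
})

test_that("a tilted planar grid meshes to its analytic area", {
  for (tilt in c(0, 30)) {
    pc <- grid_cloud(21, side = 0.1, tilt_deg = tilt)
    m <- triangulate_leaf(pc)
    expect_equal(mesh_area(m), 0.1 * 0.1, tolerance = 1e-9)
    expect_equal(nrow(m$faces), 2 * 20 * 20)
  }
})

test_that("a curved leaf sampled at 2 mm meshes to within 1% of quadrature", {
  leaf <- parametric_leaf(1, inclination_deg = 25, azimuth_deg = 40,
                          length = 0.15, width = 0.09, curvature = 0.03)
  pc <- leaf_surface_cloud(leaf, spacing = 0.002)
  m <- triangulate_leaf(pc)
  expect_lt(abs(mesh_area(m) - leaf$true_area) / leaf$true_area, 0.01)
})

test_that("triangulation reproduces the exhaustive Delaunay oracle", {
  for (s in 1:3) {
    withr::local_seed(s)
    n <- 30
    x <- runif(n)
    y <- runif(n)
    got <- face_key(delaunay_triangles(x, y))
    expect_identical(got, brute_delaunay(x, y))
    # same faces through the full leaf path (flat cloud, filters off)
    pc <- point_cloud(cbind(x * 0.1, y * 0.1, 0))
    m <- triangulate_leaf(pc, meshing_params(smooth = FALSE))
    expect_identical(face_key(m$faces), brute_delaunay(x, y))
  }
})

test_that("triangulation is Delaunay and agrees with deldir at scale", {
  withr::local_seed(9)
  x <- runif(800)
  y <- runif(800)
  f <- delaunay_triangles(x, y)
  # the defining property: no point strictly inside any circumcircle
  expect_equal(circumcircle_violations(x, y, f), 0L)
  # independent implementation agrees on the triangulation's gross shape
  # (exact face sets can differ on near-cocircular ties)
  dd <- deldir::triMat(deldir::deldir(x, y))
  expect_equal(nrow(f), nrow(dd))
  area2 <- function(ff) {
    sum(abs((x[ff[, 2]] - x[ff[, 1]]) * (y[ff[, 3]] - y[ff[, 1]]) -
              (y[ff[, 2]] - y[ff[, 1]]) * (x[ff[, 3]] - x[ff[, 1]]))) / 2
  }
  expect_equal(area2(f), area2(dd), tolerance = 1e-12)
  expect_gt(mean(face_key(f) %in% face_key(dd)), 0.995)
})

test_that("mesh area shrinks monotonically as edge_factor tightens", {
  scene <- generate_canopy(1, seed = 77L)
  pc <- leaf_surface_cloud(scene$leaves[[1]], spacing = 0.003)
  areas <- vapply(c(1.5, 2, 3, 5, Inf), function(ef) {
    mesh_area(triangulate_leaf(pc, meshing_params(edge_factor = ef)))
  }, 1.0)
  expect_true(all(diff(areas) >= 0))
})

test_that("face normals are unit, edge-orthogonal and upward folded", {
  horiz <- triangle_mesh(rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)),
                         rbind(c(1, 2, 3)))
  expect_equal(face_normals(horiz)[1, ], c(x = 0, y = 0, z = 1))
  vert <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 1)),
                        rbind(c(1, 2, 3)))
  expect_equal(abs(face_normals(vert)[1, ]), c(x = 0, y = 1, z = 0))

  withr::local_seed(2)
  for (i in 1:50) {
    v <- matrix(rnorm(9), 3, 3)
    m <- triangle_mesh(v, rbind(c(1, 2, 3)), check_area = FALSE)
    n <- face_normals(m)[1, ]
    expect_equal(sum(n^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(n * (v[2, ] - v[1, ]))), 1e-9)
    expect_lt(abs(sum(n * (v[3, ] - v[1, ]))), 1e-9)
    expect_gte(n[3], 0)
  }

  degen <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(1, 2, 3)), check_area = FALSE)
  expect_error(face_normals(degen), "face 1")
})

test_that("mesh area is invariant under rigid motion", {
  leaf <- parametric_leaf(1, length = 0.1, width = 0.06, curvature = 0.01)
  m <- tessellate_leaf(leaf, 10, 6)
  a0 <- mesh_area(m)
  withr::local_seed(4)
  for (i in 1:10000) {
    tr <- rand_rigid()
    m2 <- m
    m2$vertices <- transform_points(m$vertices, tr)
    expect_lt(abs(mesh_area(m2) - a0) / a0, 1e-12)
  }
})

test_that("planar leaves return their tilt at every vertex", {
  for (tilt in c(0, 15, 30, 45, 60, 75, 90)) {
    m <- triangulate_leaf(grid_cloud(11, side = 0.05, tilt_deg = tilt))
    ang <- point_inclination_angles(m)
    expect_true(all(is.finite(ang)))
    expect_lt(max(abs(ang - tilt)), 1e-6)
    expect_true(all(ang >= 0 & ang <= 90))
  }
})

test_that("vertex angles on a curved leaf match the analytic normals", {
  leaf <- parametric_leaf(1, inclination_deg = 20, azimuth_deg = 70,
                          length = 0.16, width = 0.1, curvature = 0.03)
  pc <- leaf_surface_cloud(leaf, spacing = 0.002)
  m <- triangulate_leaf(pc)
  ang <- point_inclination_angles(m)
  q <- leaf_quadrature(leaf, 300L, 60L)
  nn <- RANN::nn2(q$points, m$vertices, k = 1)
  ref <- q$angle_deg[nn$nn.idx[, 1]]
  expect_lt(quantile(abs(ang - ref), 0.95), 2)
  # vertices isolated by face filtering are flagged missing, not zero
  m2 <- m
  m2$faces <- m$faces[-which(m$faces == 1, arr.ind = TRUE)[, 1], , drop = FALSE]
  expect_true(is.na(point_inclination_angles(m2)[1]))
})

test_that("projection plane choice barely moves the area of 2.5-D leaves", {
  leaf <- parametric_leaf(1, inclination_deg = 35, length = 0.12,
                          width = 0.08, curvature = 0.02)
  pc <- leaf_surface_cloud(leaf, spacing = 0.002)
  a_pca <- mesh_area(triangulate_leaf(pc))
  # tilt the projection plane 20 degrees away from the PCA normal
  ctr <- colMeans(pc$points)
  dec <- svd(sweep(pc$points, 2, ctr), nu = 0)
  n_alt <- as.vector(canopy3d:::rotation_y_up(20) %*% dec$v[, 3])
  a_alt <- mesh_area(triangulate_leaf(
    pc, plane = list(normal = n_alt, origin = ctr)))
  expect_lt(abs(a_alt - a_pca) / a_pca, 0.005)
})

test_that("too-few or collinear points are rejected", {
  expect_error(triangulate_leaf(point_cloud(matrix(runif(9), 3))),
               "min_points")
  line <- point_cloud(cbind(seq(0, 1, length.out = 20), 0, 0))
  expect_error(triangulate_leaf(line, meshing_params(min_points = 3L)),
               "collinear")
})
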