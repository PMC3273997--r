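test_that("closed-form rigid estimate recovers exact transforms", {
  withr::local_seed(1)
  S <- matrix(runif(300, -1, 1), ncol = 3)
  # identity
  tr <- estimate_rigid_transform(S, S)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(tr$translation)), 1e-12)
  # known rotation + translation
  R10 <- rotation_z(10)
  G <- S %*% t(R10) + matrix(c(0.1, 0, 0), nrow(S), 3, byrow = TRUE)
  tr <- estimate_rigid_transform(S, G)
  expect_lt(max(abs(tr$rotation - R10)), 1e-9)
  expect_lt(max(abs(tr$translation - c(0.1, 0, 0))), 1e-9)
})

test_that("rigid estimate translation error stays below 0.5 mm at 1 mm noise", {
  err <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      S <- matrix(runif(3000, -1, 1), ncol = 3)
      tr_true <- rand_rigid()
      G <- transform_points(S, tr_true) + matrix(rnorm(3000, 0, 1e-3), ncol = 3)
      tr <- estimate_rigid_transform(S, G)
      sqrt(sum((tr$translation - tr_true$translation)^2))
    })
  }, 1.0)
  expect_lt(quantile(err, 0.95), 5e-4)
})

test_that("estimated rotations are proper orthonormal even under heavy noise", {
  withr::local_seed(7)
  for (i in 1:25) {
    S <- matrix(runif(90, -1, 1), ncol = 3)
    G <- transform_points(S, rand_rigid()) + matrix(rnorm(90, 0, 0.3), ncol = 3)
    R <- estimate_rigid_transform(S, G)$rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("degenerate correspondence sets are rejected", {
  expect_error(estimate_rigid_transform(diag(2), diag(2)))
  expect_error(estimate_rigid_transform(rbind(c(0, 0, 0), c(1, 1, 1)),
                                        rbind(c(0, 0, 0), c(1, 1, 1))),
               "at least 3")
  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(estimate_rigid_transform(line, line), "collinear")
})

test_that("nearest correspondences match the exhaustive oracle", {
  withr::local_seed(11)
  S <- matrix(runif(600, 0, 1), ncol = 3)
  G <- matrix(runif(450, 0, 1), ncol = 3)
  got <- nearest_correspondences(S, G)
  oracle <- brute_nn(S, G)
  expect_identical(got$target, as.integer(oracle[, 1]))
  expect_equal(got$distance, oracle[, 2], tolerance = 1e-12)
  # identical clouds: self-match at distance 0
  self <- nearest_correspondences(S, S)
  expect_identical(self$target, seq_len(nrow(S)))
  expect_equal(self$distance, rep(0, nrow(S)))
  # max_distance = 0 on distinct clouds excludes everything
  expect_equal(nrow(nearest_correspondences(S, G + 5, max_distance = 0)), 0L)
  expect_error(nearest_correspondences(S, matrix(numeric(0), ncol = 3)),
               "empty")
})

test_that("transform application is an exact isometry with exact inverse", {
  withr::local_seed(3)
  pc <- point_cloud(matrix(runif(300, -1, 1), ncol = 3), labels = rep(1L, 100))
  expect_equal(apply_transform(pc, rigid_transform())$points, pc$points)
  d0 <- dist(pc$points)
  for (i in 1:20) {
    tr <- rand_rigid()
    moved <- apply_transform(pc, tr)
    expect_identical(moved$labels, pc$labels)
    expect_lt(max(abs(dist(moved$points) - d0)), 1e-12)
    back <- apply_transform(moved, invert_transform(tr))
    expect_lt(max(abs(back$points - pc$points)), 1e-12)
  }
})

test_that("ICP is exact on clean clouds and its RMSD never increases", {
  withr::local_seed(5)
  pts <- matrix(runif(6000, -0.5, 0.5), ncol = 3)
  src <- point_cloud(pts, frame_id = "a")
  # source = target converges immediately at rmsd 0
  res0 <- icp_register(src, src)
  expect_lt(res0$rmsd, 1e-12)
  expect_true(res0$converged)
  # known 15 deg / 0.2 m transform, identity init, no noise
  tr_true <- rigid_transform(rotation_z(15), c(0.2, 0, 0))
  tgt <- apply_transform(src, tr_true, "b")
  res <- icp_register(src, tgt, max_distance = Inf)
  expect_lt(max(abs(res$transform$rotation - tr_true$rotation)), 1e-6)
  expect_lt(max(abs(res$transform$translation - tr_true$translation)), 1e-6)
  expect_lt(res$rmsd, 1e-9)
  expect_true(all(diff(res$rmsd_history) <= 1e-12))
})

test_that("ICP translation error stays below 2 mm at 1 mm range noise", {
  # regime where nearest-neighbor association is resolvable (noise well
  # below the point spacing); on smooth surface clouds sampled near the
  # noise scale, point-to-point ICP instead has a tangential-sliding floor
  # that the end-to-end RMSD check below characterizes
  errs <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      pts <- matrix(runif(9000, -0.5, 0.5), ncol = 3)
      tr_true <- rigid_transform(rotation_z(10), c(0.1, -0.05, 0.02))
      noisy <- transform_points(pts, tr_true) +
        matrix(rnorm(9000, 0, 1e-3), ncol = 3)
    })
    res <- icp_register(point_cloud(pts), point_cloud(noisy),
                        init = rigid_transform(rotation_z(12)),
                        max_distance = Inf)
    sqrt(sum((res$transform$translation - tr_true$translation)^2))
  }, 1.0)
  expect_lt(max(errs), 2e-3)
})

test_that("ICP reports a collapse instead of a spurious fit", {
  a <- point_cloud(matrix(runif(90), ncol = 3))
  b <- point_cloud(matrix(runif(90) + 10, ncol = 3))
  expect_error(icp_register(a, b, max_distance = 0.01), "max_distance")
})

test_that("three stations register to within 3 mm RMSD end to end", {
  scene <- generate_canopy(12, seed = 31L)
  cfg <- scanner_config(seed = 32L)
  sim <- simulate_scan(scene$leaves, cfg)
  for (k in 2:3) {
    res <- icp_register(sim$clouds[[k]], sim$clouds[[1]],
                        init = nominal_init(cfg, k))
    expect_lt(res$rmsd, 3e-3)
    expect_true(res$n_pairs >= 3L)
    # recovered pose close to the simulator's true relative pose
    tru <- compose_transforms(invert_transform(sim$transforms[[1]]),
                              sim$transforms[[k]])
    expect_lt(rotation_angle_deg(t(tru$rotation) %*% res$transform$rotation),
              0.5)
  }
})
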