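# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately naive (exhaustive, closed-form) so they cannot
# share a failure mode with the implementations they check.

# random proper rotation via QR of a Gaussian matrix
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rand_rigid <- function() {
  rigid_transform(rand_rotation(), rnorm(3, sd = 0.5))
}

# exhaustive O(n^2) nearest neighbor
brute_nn <- function(S, G) {
  t(vapply(seq_len(nrow(S)), function(i) {
    d2 <- (G[, 1] - S[i, 1])^2 + (G[, 2] - S[i, 2])^2 + (G[, 3] - S[i, 3])^2
    j <- which.min(d2)
    c(j, sqrt(d2[j]))
  }, numeric(2)))
}

# exhaustive Delaunay: every triple whose circumcircle is empty
brute_delaunay <- function(x, y) {
  n <- length(x)
  out <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    o <- (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
    if (abs(o) < 1e-12) next
    a <- if (o > 0) c(i, j, k) else c(i, k, j)
    ax <- x[a[1]]; ay <- y[a[1]]
    bx <- x[a[2]]; by <- y[a[2]]
    cx <- x[a[3]]; cy <- y[a[3]]
    empty <- TRUE
    for (p in setdiff(1:n, a)) {
      m <- rbind(c(ax - x[p], ay - y[p], (ax - x[p])^2 + (ay - y[p])^2),
                 c(bx - x[p], by - y[p], (bx - x[p])^2 + (by - y[p])^2),
                 c(cx - x[p], cy - y[p], (cx - x[p])^2 + (cy - y[p])^2))
      if (det(m) > 1e-12) {
        empty <- FALSE
        break
      }
    }
    if (empty) out[[length(out) + 1L]] <- sort(a)
  }
  sort(vapply(out, paste, "", collapse = "-"))
}

face_key <- function(faces) {
  sort(apply(faces, 1, function(f) paste(sort(f), collapse = "-")))
}

# closed-form barycentric ray-triangle oracle; unit direction assumed
oracle_ray_tri <- function(origin, dir, tri) {
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  M <- cbind(e1, e2, -dir)
  if (abs(det(M)) < 1e-14) return(NA_real_)
  x <- unname(solve(M, origin - tri[1, ]))
  b1 <- x[1]; b2 <- x[2]; tt <- x[3]
  if (tt > 1e-9 && b1 >= -1e-10 && b2 >= -1e-10 && b1 + b2 <= 1 + 1e-10) {
    tt
  } else {
    NA_real_
  }
}

brute_nearest_hit <- function(origin, dir, verts, faces) {
  best <- Inf
  for (f in seq_len(nrow(faces))) {
    t <- oracle_ray_tri(origin, dir, verts[faces[f, ], , drop = FALSE])
    if (!is.na(t) && t < best) best <- t
  }
  if (is.finite(best)) best else NA_real_
}

# planar grid leaf: (n x n) points spanning side s, tilted about x by theta
grid_cloud <- function(n = 21, side = 0.1, tilt_deg = 0, label = 1L) {
  g <- expand.grid(u = seq(0, side, length.out = n),
                   v = seq(0, side, length.out = n))
  a <- tilt_deg * pi / 180
  pts <- cbind(g$u, g$v * cos(a), g$v * sin(a))
  point_cloud(pts, labels = rep(label, nrow(pts)), frame_id = "test")
}

# points sampled on a parametric leaf surface at ~`spacing`, incl. boundary
leaf_surface_cloud <- function(leaf, spacing = 0.002) {
  n_u <- max(4L, ceiling(leaf$length / spacing))
  n_t <- max(4L, ceiling(leaf$width / spacing))
  alpha <- seq(0, pi, length.out = n_u)
  tt <- seq(-1, 1, length.out = n_t)
  u <- leaf$length * (1 - cos(alpha)) / 2
  pts <- leaf_surface_points(leaf, rep(u, times = n_t), rep(tt, each = n_u))
  pts <- unique(round(pts, 12))
  point_cloud(pts, labels = rep(leaf$leaf_id, nrow(pts)), frame_id = "test")
}

# relative transform mapping station k's frame onto station 1's, from the
# nominal (error-free) scan geometry -- the standard ICP initialization
nominal_init <- function(config, k) {
  compose_transforms(
    invert_transform(canopy3d:::nominal_station_transform(config, 1L)),
    canopy3d:::nominal_station_transform(config, k))
}

# simulate + ICP-register + merge; returns clouds merged in station-1 frame
register_scene <- function(sim, config) {
  merged <- list(sim$clouds[[1]])
  for (k in 2:length(sim$clouds)) {
    res <- icp_register(sim$clouds[[k]], sim$clouds[[1]],
                        init = nominal_init(config, k))
    merged[[k]] <- apply_transform(sim$clouds[[k]], res$transform,
                                   new_frame = sim$clouds[[1]]$frame_id)
  }
  merge_clouds(merged, frame_id = sim$clouds[[1]]$frame_id)
}

# combined mesh over several leaves for area-weighted sampling
combine_meshes <- function(meshes) {
  offs <- c(0L, cumsum(vapply(meshes, function(x) nrow(x$vertices), 1L)))
  comb <- triangle_mesh(
    do.call(rbind, lapply(meshes, function(x) x$vertices)),
    do.call(rbind, lapply(seq_along(meshes), function(i) {
      meshes[[i]]$faces + offs[i]
    })),
    leaf_id = 0L, check_area = FALSE)
  attr(comb, "face_leaf") <- unlist(lapply(meshes, function(x) {
    rep(x$leaf_id, nrow(x$faces))
  }))
  comb
}

# dense multi-leaf surface cloud (~2 mm spacing), the sampling regime the
# registration basin property is stated for
dense_surface_cloud <- function(seed = 1L) {
  scene <- generate_canopy(3, seed = seed)
  pts <- do.call(rbind, lapply(scene$leaves, function(l) {
    leaf_surface_cloud(l, spacing = 0.002)$points
  }))
  point_cloud(pts, frame_id = "dense")
}

# count strict empty-circumcircle violations of a triangulation; `tol` is
# the incircle determinant slack for near-cocircular ties
circumcircle_violations <- function(x, y, faces, tol = 1e-9) {
  n_bad <- 0L
  for (f in seq_len(nrow(faces))) {
    a <- faces[f, 1]; b <- faces[f, 2]; c <- faces[f, 3]
    o <- (x[b] - x[a]) * (y[c] - y[a]) - (y[b] - y[a]) * (x[c] - x[a])
    if (o < 0) { tmp <- b; b <- c; c <- tmp }
    adx <- x[a] - x; ady <- y[a] - y
    bdx <- x[b] - x; bdy <- y[b] - y
    cdx <- x[c] - x; cdy <- y[c] - y
    ad <- adx^2 + ady^2; bd <- bdx^2 + bdy^2; cd <- cdx^2 + cdy^2
    inc <- adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
      ad * (bdx * cdy - bdy * cdx)
    inc[c(a, b, c)] <- 0
    n_bad <- n_bad + sum(inc > tol)
  }
  n_bad
}
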