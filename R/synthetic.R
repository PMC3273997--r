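#' Construct a parametric leaf
#'
#' The synthetic leaf is an elliptical planform bent sinusoidally along its
#' midrib: in leaf-local coordinates (u along the midrib, v across it),
#' \deqn{S(u, v) = (u, v, A sin(pi u / L)), |v| <= w(u),}
#' with half-width `w(u) = (W/2) sqrt(1 - (2u/L - 1)^2)`. The local surface
#' is rotated by the base inclination (midrib tilt from horizontal) about
#' the cross-midrib axis, then by the midrib azimuth about z, and shifted to
#' `base`. This is the simplest family with closed-form normals, nonzero
#' curvature and a cheap quadrature area oracle; compound leaflets of real
#' crops are not modeled.
#'
#' The true one-sided area and the analytic normal's zenith angle over the
#' surface come from [leaf_quadrature()].
#'
#' @param leaf_id positive integer id.
#' @param base length-3 base position (m).
#' @param azimuth_deg midrib azimuth, degrees counter-clockwise from +x.
#' @param inclination_deg base inclination of the midrib from horizontal,
#'   degrees.
#' @param length,width planform length and width (m).
#' @param curvature sinusoidal bend amplitude `A` (m); 0 = flat.
#' @return An object of class `parametric_leaf` with `true_area` (m^2, by
#'   200 x 200 quadrature) among its fields.
#' @export
parametric_leaf <- function(leaf_id, base = c(0, 0, 0), azimuth_deg = 0,
                            inclination_deg = 0, length = 0.15,
                            width = 0.09, curvature = 0) {
  stopifnot(length > 0, width > 0, curvature >= 0)
  rot <- rotation_z(azimuth_deg) %*% rotation_y_up(inclination_deg)
  leaf <- structure(list(leaf_id = as.integer(leaf_id), base = as.numeric(base),
                         azimuth_deg = azimuth_deg,
                         inclination_deg = inclination_deg,
                         length = length, width = width,
                         curvature = curvature, rotation = rot),
                    class = "parametric_leaf")
  q <- leaf_quadrature(leaf, 200L, 200L)
  leaf$true_area <- sum(q$dA)
  leaf$mean_inclination_deg <- sum(q$angle_deg * q$dA) / sum(q$dA)
  leaf
}

# rotation about y mapping +x upward by `degrees`
rotation_y_up <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
}

#' Evaluate leaf surface points in world coordinates
#'
#' @param leaf a [parametric_leaf()].
#' @param u distance along the midrib, in `[0, length]`.
#' @param t normalized cross-midrib coordinate in `[-1, 1]` (v = t w(u)).
#' @return n x 3 matrix of world coordinates.
#' @export
leaf_surface_points <- function(leaf, u, t) {
  L <- leaf$length
  hw <- (leaf$width / 2) * sqrt(pmax(0, 1 - (2 * u / L - 1)^2))
  local <- cbind(u, t * hw, leaf$curvature * sin(pi * u / L))
  sweep(local %*% t(leaf$rotation), 2, leaf$base, "+")
}

#' Analytic unit surface normals of a parametric leaf
#'
#' In leaf-local coordinates the normal at midrib position `u` is
#' `(-z'(u), 0, 1) / sqrt(1 + z'(u)^2)` with
#' `z'(u) = A (pi / L) cos(pi u / L)`; it does not depend on the
#' cross-midrib coordinate. Returned in world coordinates, folded upward.
#'
#' @param leaf a [parametric_leaf()].
#' @param u midrib positions.
#' @return n x 3 matrix of upward-folded unit normals.
#' @export
leaf_surface_normals <- function(leaf, u) {
  zp <- leaf$curvature * (pi / leaf$length) * cos(pi * u / leaf$length)
  nl <- cbind(-zp, 0, 1) / sqrt(1 + zp^2)
  nw <- nl %*% t(leaf$rotation)
  flip <- nw[, 3] < 0
  nw[flip, ] <- -nw[flip, , drop = FALSE]
  nw
}

#' Quadrature grid over a parametric leaf surface
#'
#' Midpoint quadrature on the substituted coordinates
#' `u = L (1 - cos alpha) / 2`, `alpha` in `[0, pi]` (which removes the
#' square-root edge singularity of the elliptical planform) and the
#' normalized cross coordinate `t` in `[-1, 1]`. Each patch carries its world
#' midpoint, its exact area element
#' `dA = w(u) sqrt(1 + z'(u)^2) (L/2) sin(alpha) dalpha dt`, and the
#' analytic normal zenith angle there.
#'
#' @param leaf a [parametric_leaf()].
#' @param n_u,n_t number of quadrature nodes along and across the midrib.
#' @return list with `points` (n x 3, world), `dA` (m^2) and `angle_deg`.
#' @export
leaf_quadrature <- function(leaf, n_u = 200L, n_t = 200L) {
  L <- leaf$length
  alpha <- (seq_len(n_u) - 0.5) * pi / n_u
  tt <- -1 + (seq_len(n_t) - 0.5) * 2 / n_t
  u <- L * (1 - cos(alpha)) / 2
  zp <- leaf$curvature * (pi / L) * cos(pi * u / L)
  w_u <- (leaf$width / 2) * sin(alpha)
  dA_u <- w_u * sqrt(1 + zp^2) * (L / 2) * sin(alpha) * (pi / n_u) * (2 / n_t)
  ang_u <- acos(pmin(1, abs(leaf_surface_normals(leaf, u)[, 3]))) * 180 / pi
  uu <- rep(u, times = n_t)
  tj <- rep(tt, each = n_u)
  list(points = leaf_surface_points(leaf, uu, tj),
       dA = rep(dA_u, times = n_t),
       angle_deg = rep(ang_u, times = n_t))
}

#' Tessellate a parametric leaf into ground-truth triangles
#'
#' Fine triangulation of the exact surface used as the target geometry for
#' the virtual scanner. Resolution defaults keep the chordal error far below
#' the scanner's range noise.
#'
#' @param leaf a [parametric_leaf()].
#' @param n_u,n_t grid resolution along / across the midrib.
#' @return A [triangle_mesh()] carrying the leaf id.
#' @export
tessellate_leaf <- function(leaf, n_u = 80L, n_t = 40L) {
  alpha <- seq(0, pi, length.out = n_u + 1L)
  tt <- seq(-1, 1, length.out = n_t + 1L)
  u <- leaf$length * (1 - cos(alpha)) / 2
  uu <- rep(u, times = n_t + 1L)
  tj <- rep(tt, each = n_u + 1L)
  verts <- leaf_surface_points(leaf, uu, tj)
  idx <- function(i, j) (j - 1L) * (n_u + 1L) + i
  i <- rep(seq_len(n_u), times = n_t)
  j <- rep(seq_len(n_t), each = n_u)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  faces <- rbind(f1, f2)
  areas <- face_areas_matrix(verts, faces)
  faces <- faces[areas > 1e-14, , drop = FALSE]
  triangle_mesh(verts, faces, leaf_id = leaf$leaf_id, check_area = FALSE)
}

#' Generate a ground-truthed synthetic canopy
#'
#' Places `n_leaves` parametric leaves uniformly in a rectangular footprint
#' and over the canopy height. Defaults emulate a row-crop canopy about
#' 1.8 m tall within an analysis region of about 0.34 m^3. Leaf dimension
#' and orientation laws (documented defaults): length U(0.05, 0.25) m,
#' width/length U(0.5, 0.7), bend amplitude/length U(0.05, 0.25), base
#' inclination U(0, 75) degrees, midrib azimuth U(0, 360) degrees; base
#' heights uniform subject to the leaf fitting below the canopy top.
#'
#' @param n_leaves number of leaves (>= 1).
#' @param height canopy height (m).
#' @param footprint length-2 footprint extent (m) in x and y.
#' @param seed integer seed; scenes are reproducible bit-for-bit.
#' @param layer_thickness layer height (m) for the true LAD profile.
#' @return list with `leaves` (list of [parametric_leaf()]) and `truth`, a
#'   `scene_truth` list: per-leaf table (`leaf_id`, `true_area`,
#'   `mean_inclination_deg`), `footprint_area`, true `lad` profile
#'   data.frame, `lai` and the generation parameters.
#' @export
generate_canopy <- function(n_leaves, height = 1.8,
                            footprint = c(0.435, 0.435), seed = 1L,
                            layer_thickness = 0.2) {
  stopifnot(n_leaves >= 1L, height > 0, all(footprint > 0))
  draws <- withr::with_seed(as.integer(seed), {
    data.frame(
      length = runif(n_leaves, 0.05, 0.25),
      w_ratio = runif(n_leaves, 0.5, 0.7),
      c_ratio = runif(n_leaves, 0.05, 0.25),
      incl = runif(n_leaves, 0, 75),
      az = runif(n_leaves, 0, 360),
      bx = runif(n_leaves, -footprint[1] / 2, footprint[1] / 2),
      by = runif(n_leaves, -footprint[2] / 2, footprint[2] / 2),
      zfrac = runif(n_leaves)
    )
  })
  leaves <- vector("list", n_leaves)
  for (i in seq_len(n_leaves)) {
    d <- draws[i, ]
    vert_extent <- d$length * sin(d$incl * pi / 180) + d$length * d$c_ratio
    bz <- d$zfrac * max(height - vert_extent - 0.01, 0.01)
    leaves[[i]] <- parametric_leaf(
      leaf_id = i, base = c(d$bx, d$by, bz), azimuth_deg = d$az,
      inclination_deg = d$incl, length = d$length,
      width = d$length * d$w_ratio, curvature = d$length * d$c_ratio)
  }
  footprint_area <- footprint[1] * footprint[2]
  n_layers <- ceiling(height / layer_thickness - 1e-9)
  layer_area <- numeric(n_layers)
  for (lf in leaves) {
    q <- leaf_quadrature(lf, 200L, 200L)
    li <- pmin(n_layers, pmax(1L, floor(q$points[, 3] / layer_thickness) + 1L))
    agg <- rowsum(q$dA, li)
    layer_area[as.integer(rownames(agg))] <-
      layer_area[as.integer(rownames(agg))] + agg[, 1]
  }
  truth <- structure(list(
    leaf_table = data.frame(
      leaf_id = vapply(leaves, function(l) l$leaf_id, 1L),
      true_area = vapply(leaves, function(l) l$true_area, 1.0),
      mean_inclination_deg =
        vapply(leaves, function(l) l$mean_inclination_deg, 1.0)),
    footprint_area = footprint_area,
    lad = data.frame(
      layer_bottom_z = layer_thickness * (seq_len(n_layers) - 1L),
      lad = layer_area / (footprint_area * layer_thickness)),
    lai = sum(layer_area) / footprint_area,
    layer_thickness = layer_thickness,
    height = height, footprint = footprint, seed = as.integer(seed)),
    class = "scene_truth")
  list(leaves = leaves, truth = truth)
}

#' Virtual scanner configuration
#'
#' Defaults emulate a portable triangulation scanner measuring a crop canopy
#' from three tripod stations 120 degrees apart at about 5 m range: beam
#' zenith span 94 +/- 13 degrees, angular step giving ~2 mm point spacing at
#' range, and 1 mm Gaussian range noise. Station poses get small random
#' set-up errors (azimuth, position, height) so that registration has real
#' work to do; tripods are assumed leveled, so no tilt error is modeled.
#'
#' @param n_stations number of stations.
#' @param azimuths_deg nominal station azimuths (degrees, distinct).
#' @param range nominal horizontal canopy-to-station distance (m).
#' @param station_height nominal scanner height (m).
#' @param zenith_span_deg beam zenith span, degrees.
#' @param angular_step beam grid step (radians) in both axes; the default
#'   `0.002 / range` gives ~2 mm spacing on a fronto-parallel target.
#' @param range_noise_sd Gaussian noise sigma along the beam (m).
#' @param azimuth_jitter_deg,position_jitter,height_jitter half-widths of
#'   the uniform station set-up errors (degrees, m, m).
#' @param seed integer seed for set-up errors and range noise.
#' @return An object of class `scanner_config`.
#' @export
scanner_config <- function(n_stations = 3L, azimuths_deg = c(0, 120, 240),
                           range = 5.0, station_height = 1.5,
                           zenith_span_deg = c(81, 107),
                           angular_step = 0.002 / range,
                           range_noise_sd = 0.001,
                           azimuth_jitter_deg = 2, position_jitter = 0.03,
                           height_jitter = 0.02, seed = 1L) {
  stopifnot(n_stations >= 1L, length(azimuths_deg) == n_stations,
            !anyDuplicated(azimuths_deg), angular_step > 0,
            range_noise_sd >= 0, range > 0)
  structure(list(n_stations = as.integer(n_stations),
                 azimuths_deg = azimuths_deg, range = range,
                 station_height = station_height,
                 zenith_span_deg = zenith_span_deg,
                 angular_step = angular_step,
                 range_noise_sd = range_noise_sd,
                 azimuth_jitter_deg = azimuth_jitter_deg,
                 position_jitter = position_jitter,
                 height_jitter = height_jitter,
                 seed = as.integer(seed)),
            class = "scanner_config")
}

# nominal station pose (no set-up error): local frame +x looks at the canopy
# center, z up; returns the rigid transform mapping station-local -> world
nominal_station_transform <- function(config, k) {
  az <- config$azimuths_deg[k]
  pos <- c(config$range * cos(az * pi / 180),
           config$range * sin(az * pi / 180),
           config$station_height)
  rigid_transform(rotation_z(az + 180), pos)
}

#' Simulate a multi-station lidar scan of a synthetic canopy
#'
#' For every station, every beam on the regular (zenith x azimuth) angular
#' grid is cast against the finely tessellated leaf surfaces; the nearest
#' ray-triangle hit (first return) becomes a point, which models occlusion.
#' Gaussian range noise is added along the beam. Points are labeled with the
#' hit leaf's id and expressed in the station's own frame, so registration
#' can be validated against the true station transforms.
#'
#' @param leaves list of [parametric_leaf()] (e.g. from [generate_canopy()]).
#' @param config a [scanner_config()].
#' @param tessellation_n_u,tessellation_n_t ground-truth tessellation
#'   resolution per leaf.
#' @param occluders optional list of extra [triangle_mesh()]es (e.g.
#'   [stem_cylinder()]s) that block beams; their returns are labeled with
#'   the mesh's own `leaf_id` (0 for stems/unassigned).
#' @return list with `clouds` (one labeled [point_cloud()] per station, in
#'   station-local frames), `transforms` (true [rigid_transform()]s mapping
#'   each station frame to world) and `config`.
#' @export
simulate_scan <- function(leaves, config = scanner_config(),
                          tessellation_n_u = 80L, tessellation_n_t = 40L,
                          occluders = list()) {
  stopifnot(length(leaves) >= 1L, inherits(config, "scanner_config"))
  tess <- lapply(leaves, tessellate_leaf, n_u = tessellation_n_u,
                 n_t = tessellation_n_t)
  tess <- c(tess, occluders)
  offs <- c(0L, cumsum(vapply(tess, function(m) nrow(m$vertices), 1L)))
  V <- do.call(rbind, lapply(tess, function(m) m$vertices))
  F_ <- do.call(rbind, lapply(seq_along(tess), function(i) {
    tess[[i]]$faces + offs[i]
  }))
  face_leaf <- unlist(lapply(tess, function(m) {
    rep(m$leaf_id, nrow(m$faces))
  }))

  th0 <- config$zenith_span_deg[1] * pi / 180
  th1 <- config$zenith_span_deg[2] * pi / 180
  ntheta <- floor((th1 - th0) / config$angular_step) + 1L

  withr::with_seed(config$seed, {
    jit <- data.frame(
      az = runif(config$n_stations, -1, 1) * config$azimuth_jitter_deg,
      px = runif(config$n_stations, -1, 1) * config$position_jitter,
      py = runif(config$n_stations, -1, 1) * config$position_jitter,
      pz = runif(config$n_stations, -1, 1) * config$height_jitter)
    clouds <- vector("list", config$n_stations)
    transforms <- vector("list", config$n_stations)
    for (k in seq_len(config$n_stations)) {
      az <- config$azimuths_deg[k] + jit$az[k]
      pos <- c(config$range * cos(az * pi / 180) + jit$px[k],
               config$range * sin(az * pi / 180) + jit$py[k],
               config$station_height + jit$pz[k])
      tr <- rigid_transform(rotation_z(az + 180), pos)
      transforms[[k]] <- tr
      inv <- invert_transform(tr)
      V_local <- transform_points(V, inv)
      phis <- atan2(V_local[, 2], V_local[, 1])
      phi0 <- min(phis) - 2 * config$angular_step
      nphi <- floor((max(phis) + 2 * config$angular_step - phi0) /
                      config$angular_step) + 1L
      res <- scan_grid_cpp(V_local, F_, as.integer(face_leaf),
                           th0, config$angular_step, ntheta,
                           phi0, config$angular_step, nphi)
      h <- res$hits
      if (nrow(h) == 0L) {
        warning("simulate_scan: no beam from station ", k, " hit the canopy",
                call. = FALSE)
        clouds[[k]] <- point_cloud(matrix(numeric(0), ncol = 3),
                                   labels = integer(0),
                                   frame_id = paste0("station", k))
        next
      }
      t_noisy <- h[, 1] + rnorm(nrow(h), 0, config$range_noise_sd)
      clouds[[k]] <- point_cloud(h[, 2:4] * t_noisy, labels = res$label,
                                 frame_id = paste0("station", k))
    }
  })
  list(clouds = clouds, transforms = transforms, config = config)
}

#' Opaque stem cylinder for the virtual scanner
#'
#' A vertical open cylinder tessellated into triangles, used as an occluder
#' in [simulate_scan()]. Beams hitting it return points labeled 0
#' (not-a-leaf), as a scanned stem would.
#'
#' @param center_xy length-2 horizontal position of the axis (m).
#' @param radius cylinder radius (m).
#' @param z_bottom,z_top vertical extent (m).
#' @param n_seg number of angular segments.
#' @return A [triangle_mesh()] with `leaf_id = 0`.
#' @export
stem_cylinder <- function(center_xy = c(0, 0), radius = 0.01,
                          z_bottom = 0, z_top = 1.8, n_seg = 24L) {
  stopifnot(radius > 0, z_top > z_bottom, n_seg >= 3L)
  a <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  ring <- cbind(center_xy[1] + radius * cos(a), center_xy[2] + radius * sin(a))
  verts <- rbind(cbind(ring, z_bottom), cbind(ring, z_top))
  i <- seq_len(n_seg)
  j <- c(seq_len(n_seg - 1L) + 1L, 1L)
  faces <- rbind(cbind(i, j, j + n_seg), cbind(i, j + n_seg, i + n_seg))
  triangle_mesh(verts, faces, leaf_id = 0L)
}

#' Ray-triangle intersection (Moller-Trumbore)
#'
#' Distance along the (normalized) ray direction to the triangle, counting
#' interior and edge hits, or `NA` on a miss. The same kernel the virtual
#' scanner uses; exposed for verification against independent oracles.
#'
#' @param origin,direction length-3 numerics; direction need not be unit.
#' @param triangle 3 x 3 matrix, one vertex per row.
#' @return Hit distance in meters, or `NA` if the ray misses.
#' @export
ray_triangle_intersect <- function(origin, direction, triangle) {
  stopifnot(length(origin) == 3L, length(direction) == 3L)
  if (sum(direction^2) == 0) {
    stop("ray_triangle_intersect: direction must be non-zero", call. = FALSE)
  }
  t <- ray_triangle_cpp(as.numeric(origin), as.numeric(direction),
                        as.matrix(triangle))
  if (t < 0) NA_real_ else t
}
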