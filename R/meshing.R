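#' Meshing parameters
#'
#' Controls how a leaf point cloud is turned into a triangle mesh by
#' [triangulate_leaf()].
#'
#' @param edge_factor dimensionless; faces with an edge longer than
#'   `edge_factor` times the median triangulation edge length are removed
#'   after triangulation, trimming convex-hull bridges across the concave
#'   gaps of lobed planforms. Must be > 1. The default `Inf` keeps every
#'   face: an individually segmented leaf has a convex planform, and scan
#'   sampling is strongly anisotropic at grazing beam incidence, so gaps
#'   between sampled rows are real surface that the triangulation should
#'   interpolate, not spurious bridges. The median triangulation edge (not
#'   the nearest-neighbor spacing) is the reference scale because it sees
#'   both the dense and the sparse sampling direction.
#' @param min_points minimum number of points required to mesh a leaf.
#' @param smooth if `TRUE` (default) denoise the cloud before triangulation
#'   by moving-least-squares projection: each point's height above the
#'   fitted leaf plane is replaced by a Gaussian-weighted local polynomial
#'   fit.
#'   Without this, triangulating points carrying range noise comparable to
#'   the point spacing inflates the surface area of the reconstructed sheet.
#'   The smoother is exact on planar clouds.
#' @param smooth_factor smoothing radius as a multiple of the median
#'   nearest-neighbor spacing.
#' @param smooth_degree polynomial degree of the local fit, 1 or 2. Degree 2
#'   (default) is unbiased on locally quadratic surfaces, so the radius can
#'   be generous without flattening leaf bends; degree 1 trades curvature
#'   fidelity for robustness on very sparse leaves.
#' @return An object of class `meshing_params`.
#' @export
meshing_params <- function(edge_factor = Inf, min_points = 10L,
                           smooth = TRUE, smooth_factor = 8,
                           smooth_degree = 2L) {
  stopifnot(edge_factor > 1, min_points >= 3L, smooth_factor > 0,
            smooth_degree %in% c(1L, 2L))
  structure(list(edge_factor = edge_factor,
                 min_points = as.integer(min_points),
                 smooth = isTRUE(smooth), smooth_factor = smooth_factor,
                 smooth_degree = as.integer(smooth_degree)),
            class = "meshing_params")
}

#' Triangulate one leaf's point cloud into a surface mesh
#'
#' Fits the least-squares plane through the points (principal axes of the
#' centered cloud), projects the points onto it, Delaunay-triangulates the
#' 2-D projection, and lifts the faces back to 3-D. With a finite
#' `edge_factor`, faces with an edge longer than `edge_factor` x the median
#' triangulation edge length are then removed; degenerate faces
#' (area < 1e-12 m^2) always are. Every input point appears as a vertex;
#' vertices isolated by the face filter are permitted.
#'
#' Valid for segmented leaves that are near-2.5-D sheets, i.e. whose surface
#' normals stay within ~60 degrees of the fitted plane normal.
#'
#' @param leaf_points a [point_cloud()] whose points all belong to one leaf
#'   (at most one positive label).
#' @param params a [meshing_params()].
#' @param leaf_id id for the resulting mesh; defaults to the cloud's label.
#' @param plane optional projection plane override, a list with unit `normal`
#'   and `origin`; default is the principal-axes fit.
#' @return A [triangle_mesh()].
#' @export
triangulate_leaf <- function(leaf_points, params = meshing_params(),
                             leaf_id = NULL, plane = NULL) {
  stopifnot(inherits(leaf_points, "point_cloud"),
            inherits(params, "meshing_params"))
  P <- leaf_points$points
  n <- nrow(P)
  if (n < params$min_points) {
    stop("triangulate_leaf: ", n, " points < min_points = ",
         params$min_points, call. = FALSE)
  }
  lab <- unique(setdiff(leaf_points$labels, 0L))
  if (length(lab) > 1L) {
    stop("triangulate_leaf: cloud carries ", length(lab),
         " distinct leaf labels; split it first", call. = FALSE)
  }
  if (is.null(leaf_id)) leaf_id <- if (length(lab)) lab else 0L

  # principal-axes plane fit
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  if (is.null(plane)) {
    dec <- svd(Pc, nu = 0)
    if (dec$d[2] <= 1e-10 * max(dec$d[1], .Machine$double.eps)) {
      stop("triangulate_leaf: degenerate geometry (points are collinear)",
           call. = FALSE)
    }
    basis <- dec$v  # columns: in-plane e1, e2, normal
  } else {
    nrm <- plane$normal / sqrt(sum(plane$normal^2))
    e1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * nrm) * nrm
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    basis <- cbind(e1, e2, nrm)
    Pc <- sweep(P, 2, plane$origin %||% ctr)
    ctr <- plane$origin %||% ctr
  }
  uvw <- Pc %*% basis
  if (sd(uvw[, 2]) <= 1e-10 * max(sd(uvw[, 1]), .Machine$double.eps)) {
    stop("triangulate_leaf: degenerate geometry (points are collinear)",
         call. = FALSE)
  }

  # median nearest-neighbor spacing in the projection plane
  nn <- RANN::nn2(uvw[, 1:2, drop = FALSE], k = 2L)
  spacing2d <- median(nn$nn.dists[, 2])

  w <- uvw[, 3]
  if (params$smooth && spacing2d > 0) {
    radius <- params$smooth_factor * spacing2d
    # enough neighbors to fill the radius disc at the observed density
    k_cap <- min(256L, as.integer(ceiling(1.3 * pi * params$smooth_factor^2)))
    nnr <- RANN::nn2(uvw[, 1:2, drop = FALSE], k = min(n, max(16L, k_cap)),
                     searchtype = "radius", radius = radius)
    w <- smooth_heights_cpp(uvw[, 1], uvw[, 2], w, nnr$nn.idx, radius / 2,
                            params$smooth_degree)
  }
  verts <- sweep(cbind(uvw[, 1:2, drop = FALSE], w) %*% t(basis), 2, ctr, "+")

  faces <- delaunay_cpp(uvw[, 1], uvw[, 2])

  if (is.finite(params$edge_factor) && nrow(faces)) {
    e1l <- rowSums((verts[faces[, 1], , drop = FALSE] -
                    verts[faces[, 2], , drop = FALSE])^2)
    e2l <- rowSums((verts[faces[, 2], , drop = FALSE] -
                    verts[faces[, 3], , drop = FALSE])^2)
    e3l <- rowSums((verts[faces[, 3], , drop = FALSE] -
                    verts[faces[, 1], , drop = FALSE])^2)
    limit <- params$edge_factor * median(sqrt(c(e1l, e2l, e3l)))
    keep <- pmax(e1l, e2l, e3l) <= limit^2
    faces <- faces[keep, , drop = FALSE]
  }
  if (nrow(faces)) {
    a <- face_areas_matrix(verts, faces)
    faces <- faces[a > 1e-12, , drop = FALSE]
  }
  triangle_mesh(verts, faces, leaf_id = leaf_id, check_area = FALSE)
}

#' One-sided surface area of a mesh
#'
#' Sum over faces of half the cross-product norm,
#' `sum .5 * ||(v1 - v0) x (v2 - v0)||`. A leaf is modeled as a
#' zero-thickness sheet, so this is its one-sided area. Invariant under
#' rigid motion.
#'
#' @param mesh a [triangle_mesh()].
#' @return Area in square meters (0 for an empty face list).
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  sum(face_areas_matrix(mesh$vertices, mesh$faces))
}

#' Per-face areas
#' @param mesh a [triangle_mesh()].
#' @return Numeric vector of face areas (m^2).
#' @export
face_areas <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  face_areas_matrix(mesh$vertices, mesh$faces)
}

#' Upward-folded unit face normals
#'
#' Unit normals from the face edge cross product, with orientation folded so
#' the z component is >= 0. Scanned leaf sheets have no consistent
#' inside/outside, and inclination is defined against the zenith, so the
#' upward convention loses nothing.
#'
#' @param mesh a [triangle_mesh()].
#' @return n_faces x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  v <- mesh$vertices
  if (!nrow(f)) return(matrix(numeric(0), ncol = 3))
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  if (any(len <= 0)) {
    stop("face_normals: face ", which(len <= 0)[1], " has zero area",
         call. = FALSE)
  }
  n <- cbind(nx, ny, nz) / len
  flip <- n[, 3] < 0
  n[flip, ] <- -n[flip, , drop = FALSE]
  colnames(n) <- c("x", "y", "z")
  n
}

#' Per-vertex normals (area-weighted) and inclination angles
#'
#' The normal at a vertex is the renormalized area-weighted average of the
#' upward-folded normals of its adjacent faces. The leaf inclination angle
#' at the vertex is the zenith angle of that normal,
#' `theta = acos(|n_z|)` in degrees, in `[0, 90]`: 0 for a horizontal leaf
#' surface, 90 for a vertical one. Vertices with no adjacent face get `NA`
#' (flagged missing, not 0).
#'
#' @param mesh a [triangle_mesh()].
#' @return Numeric vector, one angle in degrees (or `NA`) per vertex. The
#'   per-vertex normals are attached as attribute `"normals"`.
#' @export
point_inclination_angles <- function(mesh) {
  vn <- vertex_normals(mesh)
  ang <- acos(pmin(1, abs(vn[, 3]))) * 180 / pi
  attr(ang, "normals") <- vn
  ang
}

#' Per-vertex unit normals (area-weighted average of folded face normals)
#' @param mesh a [triangle_mesh()].
#' @return n_vertices x 3 matrix; rows of `NA` for isolated vertices.
#' @export
vertex_normals <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  nv <- nrow(mesh$vertices)
  fn <- face_normals(mesh)
  fa <- face_areas(mesh)
  acc <- matrix(0, nv, 3)
  wsum <- numeric(nv)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    acc[, 1] <- acc[, 1] + unname(tapply_add(idx, fn[, 1] * fa, nv))
    acc[, 2] <- acc[, 2] + unname(tapply_add(idx, fn[, 2] * fa, nv))
    acc[, 3] <- acc[, 3] + unname(tapply_add(idx, fn[, 3] * fa, nv))
    wsum <- wsum + tapply_add(idx, fa, nv)
  }
  len <- sqrt(rowSums(acc^2))
  out <- acc / ifelse(len > 0, len, 1)
  out[wsum == 0, ] <- NA_real_
  # fold upward for a well-defined zenith angle
  flip <- !is.na(out[, 3]) & out[, 3] < 0
  out[flip, ] <- -out[flip, , drop = FALSE]
  out
}

tapply_add <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' 2-D Delaunay triangulation (internal engine, exposed for verification)
#'
#' Incremental Bowyer-Watson triangulation used by [triangulate_leaf()].
#' @param x,y coordinates of at least 3 non-collinear points.
#' @return Integer matrix of triangles (1-based vertex indices, CCW).
#' @export
delaunay_triangles <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  delaunay_cpp(as.numeric(x), as.numeric(y))
}
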