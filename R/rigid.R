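#' Construct a rigid transform
#'
#' A proper rigid-body transform: `p -> R p + t` with `R` a 3x3 rotation
#' (orthonormal, det +1) and `t` a translation in meters.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation (m).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  err_orth <- max(abs(crossprod(rotation) - diag(3)))
  if (err_orth > 1e-9) {
    stop("rigid_transform: rotation is not orthonormal (max |R'R - I| = ",
         format(err_orth), ")", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rigid_transform: rotation must have det +1 (no reflections)",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform: rotation %.3f deg, translation (%.4g, %.4g, %.4g) m>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param rotation 3x3 rotation matrix.
#' @return Angle in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(rotation) {
  c_ang <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

#' Rotation about the z (zenith) axis
#' @param degrees rotation angle, counter-clockwise looking down the z axis.
#' @return 3x3 rotation matrix.
#' @export
rotation_z <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first, then
#' `a`: `p -> Ra (Rb p + tb) + ta`.
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation))
}

#' Apply a rigid transform to a point cloud
#'
#' Maps every point `p -> R p + t`. Labels are preserved; `frame_id` is
#' replaced by `new_frame`.
#'
#' @param cloud a [point_cloud()] (or a bare n x 3 matrix, in which case a
#'   matrix is returned).
#' @param transform a [rigid_transform()].
#' @param new_frame frame tag of the result.
#' @return Transformed `point_cloud` (or matrix).
#' @export
apply_transform <- function(cloud, transform, new_frame = NULL) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.matrix(cloud)) {
    return(transform_points(cloud, transform))
  }
  stopifnot(inherits(cloud, "point_cloud"))
  point_cloud(transform_points(cloud$points, transform),
              labels = cloud$labels,
              frame_id = new_frame %||% paste0(cloud$frame_id, "*"))
}

transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Least-squares rigid transform between paired point sets
#'
#' Closed-form solution of `argmin_{R,t} sum_i || R s_i + t - g_i ||^2` via
#' singular value decomposition of the cross-covariance matrix
#' (Kabsch/Horn), with the reflection correction that guarantees a proper
#' rotation (det +1) even for adversarial or noisy input.
#'
#' @param source_points,target_points equal-length n x 3 matrices (or
#'   [point_cloud()]s) of corresponding points, n >= 3, not all collinear.
#' @return A [rigid_transform()] mapping source onto target.
#' @export
estimate_rigid_transform <- function(source_points, target_points) {
  S <- if (inherits(source_points, "point_cloud")) source_points$points else
    as.matrix(source_points)
  G <- if (inherits(target_points, "point_cloud")) target_points$points else
    as.matrix(target_points)
  if (nrow(S) != nrow(G)) {
    stop("estimate_rigid_transform: source and target must pair up (",
         nrow(S), " vs ", nrow(G), " points)", call. = FALSE)
  }
  if (nrow(S) < 3L) {
    stop("estimate_rigid_transform: need at least 3 correspondence pairs",
         call. = FALSE)
  }
  cs <- colMeans(S)
  cg <- colMeans(G)
  Sc <- sweep(S, 2, cs)
  Gc <- sweep(G, 2, cg)
  sv_src <- svd(Sc, nu = 0, nv = 0)$d
  if (sv_src[2] <= 1e-12 * max(sv_src[1], .Machine$double.eps)) {
    stop("estimate_rigid_transform: degenerate (collinear) configuration",
         call. = FALSE)
  }
  H <- crossprod(Sc, Gc)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  rigid_transform(R, cg - as.vector(R %*% cs))
}

# JSON (de)serialization used by the CLI and the pipeline report
transform_to_list <- function(transform) {
  list(rotation = as.vector(t(transform$rotation)),
       translation = transform$translation)
}

transform_from_list <- function(x) {
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
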