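#' Construct a point cloud
#'
#' A `point_cloud` holds 3-D points in meters, an optional per-point integer
#' leaf label (0 = unassigned / not a leaf; leaf ids start at 1), and a
#' `frame_id` naming the coordinate frame the points live in (e.g. one scan
#' station, or `"world"` after registration). The z axis points up (zenith);
#' the frame is right-handed.
#'
#' @param points numeric matrix with 3 columns (x, y, z) in meters; 0 rows
#'   allowed.
#' @param labels optional integer vector, one non-negative label per point.
#' @param frame_id character tag naming the coordinate frame.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3), labels = rep(1L, 10))
#' n_points(pc)
#' @export
point_cloud <- function(points, labels = NULL, frame_id = "unknown") {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (anyNA(points) || any(!is.finite(points))) {
    bad <- which(!is.finite(points), arr.ind = TRUE)[1, 1]
    stop("point_cloud: non-finite coordinate at point ", bad, call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(points)) {
      stop("point_cloud: labels must have exactly one entry per point (",
           length(labels), " labels for ", nrow(points), " points)",
           call. = FALSE)
    }
    if (anyNA(labels) || any(labels < 0L)) {
      stop("point_cloud: labels must be non-negative integers", call. = FALSE)
    }
  }
  structure(list(points = points, labels = labels,
                 frame_id = as.character(frame_id)[1]),
            class = "point_cloud")
}

#' Number of points in a point cloud
#' @param cloud a [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points, frame '%s'%s>\n",
              nrow(x$points), x$frame_id,
              if (is.null(x$labels)) "" else
                sprintf(", %d labeled leaves",
                        length(setdiff(unique(x$labels), 0L)))))
  invisible(x)
}

#' Split a labeled cloud into per-leaf clouds
#'
#' Points with label 0 (unassigned / stem) are dropped. This mirrors the
#' manual leaf extraction step of the field workflow: segmentation itself is
#' taken as given (simulator truth or user annotation), not computed.
#'
#' @param cloud a labeled [point_cloud()].
#' @param min_points leaves with fewer points than this are dropped (with a
#'   warning naming them).
#' @return Named list of `point_cloud` objects, names `"leaf_<id>"`, sorted
#'   by leaf id.
#' @export
split_leaves <- function(cloud, min_points = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$labels)) {
    stop("split_leaves: cloud has no leaf labels", call. = FALSE)
  }
  ids <- sort(setdiff(unique(cloud$labels), 0L))
  out <- list()
  small <- integer(0)
  for (id in ids) {
    sel <- cloud$labels == id
    if (sum(sel) < min_points) {
      small <- c(small, id)
      next
    }
    out[[paste0("leaf_", id)]] <- point_cloud(
      cloud$points[sel, , drop = FALSE],
      labels = cloud$labels[sel],
      frame_id = cloud$frame_id)
  }
  if (length(small)) {
    warning("split_leaves: dropped leaves with < ", min_points, " points: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  out
}

#' Merge point clouds into one
#'
#' All clouds must share a frame. Labels are kept if every cloud has them.
#' @param clouds list of [point_cloud()] objects.
#' @param frame_id frame tag of the result; defaults to the common frame.
#' @return A merged `point_cloud`.
#' @export
merge_clouds <- function(clouds, frame_id = NULL) {
  stopifnot(length(clouds) >= 1L)
  frames <- unique(vapply(clouds, function(c) c$frame_id, ""))
  if (is.null(frame_id)) {
    if (length(frames) > 1L) {
      stop("merge_clouds: clouds are in different frames (",
           paste(frames, collapse = ", "),
           "); register them first or pass frame_id explicitly",
           call. = FALSE)
    }
    frame_id <- frames[1]
  }
  pts <- do.call(rbind, lapply(clouds, function(c) c$points))
  labs <- NULL
  if (all(vapply(clouds, function(c) !is.null(c$labels), TRUE))) {
    labs <- unlist(lapply(clouds, function(c) c$labels), use.names = FALSE)
  }
  point_cloud(pts, labels = labs, frame_id = frame_id)
}

#' Construct a triangle mesh
#'
#' Represents one reconstructed leaf sheet: vertices in meters and triangular
#' faces as 1-based vertex index triples (R convention; file formats with
#' 0-based indices are converted on read/write). Faces with out-of-range
#' indices, repeated vertices, or (optionally) zero area are rejected.
#'
#' @param vertices numeric matrix, 3 columns, meters.
#' @param faces integer matrix, 3 columns, 1-based vertex indices; 0 rows
#'   allowed.
#' @param leaf_id integer id of the leaf this mesh represents.
#' @param check_area if `TRUE`, error on any face with area below
#'   `.Machine$double.eps`-scale (degenerate) rather than keeping it.
#' @return An object of class `triangle_mesh`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'                    rbind(c(1, 2, 3), c(1, 3, 4)), leaf_id = 1)
#' mesh_area(m)
#' @export
triangle_mesh <- function(vertices, faces, leaf_id = 0L, check_area = TRUE) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  if (length(vertices) && any(!is.finite(vertices))) {
    stop("triangle_mesh: non-finite vertex coordinate", call. = FALSE)
  }
  if (is.null(dim(faces))) faces <- matrix(as.integer(faces), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces)) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("triangle_mesh: face index out of range (vertex count ",
           nrow(vertices), ")", call. = FALSE)
    }
    rep_v <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(rep_v)) {
      stop("triangle_mesh: face ", which(rep_v)[1],
           " has a repeated vertex", call. = FALSE)
    }
    if (check_area) {
      a <- face_areas_matrix(vertices, faces)
      if (any(a <= 0)) {
        stop("triangle_mesh: face ", which(a <= 0)[1],
             " has zero area", call. = FALSE)
      }
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 leaf_id = as.integer(leaf_id)[1]),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: leaf %d, %d vertices, %d faces, area %.6g m^2>\n",
              x$leaf_id, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

# per-face areas from raw matrices (shared by constructor and mesh_area)
face_areas_matrix <- function(vertices, faces) {
  if (!nrow(faces)) return(numeric(0))
  v0 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v0
  e2 <- vertices[faces[, 3], , drop = FALSE] - v0
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}
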