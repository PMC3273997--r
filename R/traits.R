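#' Per-leaf summary records
#'
#' One row per mesh: leaf id, one-sided area, area-weighted face-centroid
#' height, and face count.
#'
#' @param meshes list of [triangle_mesh()]es with unique, positive leaf ids.
#' @return data.frame with columns `leaf_id`, `area` (m^2), `centroid_z`
#'   (m), `n_faces`.
#' @export
leaf_records <- function(meshes) {
  if (!length(meshes)) {
    return(data.frame(leaf_id = integer(0), area = numeric(0),
                      centroid_z = numeric(0), n_faces = integer(0)))
  }
  ids <- vapply(meshes, function(m) m$leaf_id, 1L)
  if (anyDuplicated(ids)) {
    stop("leaf_records: duplicate leaf_id ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  rec <- lapply(meshes, function(m) {
    fa <- face_areas(m)
    cz <- face_centroids_z(m)
    data.frame(leaf_id = m$leaf_id,
               area = sum(fa),
               centroid_z = if (length(fa)) sum(cz * fa) / sum(fa) else NA_real_,
               n_faces = nrow(m$faces))
  })
  out <- do.call(rbind, rec)
  out[order(out$leaf_id), , drop = FALSE]
}

face_centroids_z <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(numeric(0))
  (mesh$vertices[f[, 1], 3] + mesh$vertices[f[, 2], 3] +
     mesh$vertices[f[, 3], 3]) / 3
}

#' Vertical leaf area density (LAD) profile
#'
#' Assigns every mesh face to the horizontal layer containing its centroid's
#' z (layers are half-open `[bottom, top)`; the top layer is closed), sums
#' one-sided face areas per layer, and divides by the layer volume
#' `footprint_area * layer_thickness`. Faces whose centroid falls outside
#' `[z_min, z_max]` are counted in the `overflow_area` diagnostic, never
#' silently dropped.
#'
#' @param meshes list of [triangle_mesh()]es.
#' @param footprint_area horizontal cross-section of the analyzed region
#'   (m^2); required because it cannot be inferred from the clouds.
#' @param layer_thickness layer height in meters (default 0.20).
#' @param z_min,z_max vertical extent of the profile (m).
#' @return An object of class `lad_profile`: data.frame with
#'   `layer_bottom_z` and `lad` (m^2 m^-3), plus attributes
#'   `footprint_area`, `layer_thickness`, `lai` and `overflow_area`.
#' @seealso [lai()]
#' @export
lad_profile <- function(meshes, footprint_area, layer_thickness = 0.2,
                        z_min = 0, z_max = 1.8) {
  if (footprint_area <= 0) {
    stop("lad_profile: footprint_area must be positive", call. = FALSE)
  }
  if (layer_thickness <= 0) {
    stop("lad_profile: layer_thickness must be positive", call. = FALSE)
  }
  if (z_max <= z_min) stop("lad_profile: z_max must exceed z_min",
                           call. = FALSE)
  n_layers <- ceiling((z_max - z_min) / layer_thickness - 1e-9)
  bottoms <- z_min + layer_thickness * (seq_len(n_layers) - 1L)
  layer_area <- numeric(n_layers)
  overflow <- 0
  for (m in meshes) {
    fa <- face_areas(m)
    if (!length(fa)) next
    cz <- face_centroids_z(m)
    idx <- floor((cz - z_min) / layer_thickness) + 1L
    idx[cz == z_min + n_layers * layer_thickness] <- n_layers  # closed top
    out_of_range <- idx < 1L | idx > n_layers
    overflow <- overflow + sum(fa[out_of_range])
    if (any(!out_of_range)) {
      agg <- rowsum(fa[!out_of_range], idx[!out_of_range])
      layer_area[as.integer(rownames(agg))] <-
        layer_area[as.integer(rownames(agg))] + agg[, 1]
    }
  }
  prof <- data.frame(layer_bottom_z = bottoms,
                     lad = layer_area / (footprint_area * layer_thickness))
  structure(prof,
            footprint_area = footprint_area,
            layer_thickness = layer_thickness,
            overflow_area = overflow,
            lai = sum(layer_area) / footprint_area,
            class = c("lad_profile", "data.frame"))
}

#' Leaf area index from a LAD profile
#'
#' Vertical integral of the LAD profile:
#' `LAI = sum_k LAD_k * layer_thickness`, which equals total assigned leaf
#' area divided by footprint area exactly.
#'
#' @param profile a [lad_profile()].
#' @return LAI in m^2 m^-2.
#' @export
lai <- function(profile) {
  stopifnot(inherits(profile, "lad_profile"))
  sum(profile$lad) * attr(profile, "layer_thickness")
}

#' @export
print.lad_profile <- function(x, ...) {
  cat(sprintf("<lad_profile: %d layers of %.2f m, footprint %.4g m^2, LAI %.4g m^2 m^-2>\n",
              nrow(x), attr(x, "layer_thickness"), attr(x, "footprint_area"),
              lai(x)))
  if (attr(x, "overflow_area") > 0) {
    cat(sprintf("  overflow: %.4g m^2 of leaf area outside [z_min, z_max]\n",
                attr(x, "overflow_area")))
  }
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Sample points uniformly by area over a mesh surface
#'
#' Faces are drawn with probability proportional to their area, then a point
#' is placed uniformly inside each drawn face (barycentric sampling).
#' Reproducible for a fixed seed; the global RNG state is left untouched.
#'
#' @param mesh a [triangle_mesh()] with at least one face.
#' @param n number of samples.
#' @param seed integer seed.
#' @return list with `points` (n x 3), `face` (face index per sample) and
#'   `bary` (n x 3 barycentric coordinates).
#' @export
sample_mesh_points <- function(mesh, n, seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"), nrow(mesh$faces) >= 1L, n >= 1L)
  fa <- face_areas(mesh)
  withr::with_seed(as.integer(seed), {
    fi <- sample.int(length(fa), n, replace = TRUE, prob = fa)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
  })
  b <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
  f <- mesh$faces[fi, , drop = FALSE]
  pts <- b[, 1] * mesh$vertices[f[, 1], , drop = FALSE] +
    b[, 2] * mesh$vertices[f[, 2], , drop = FALSE] +
    b[, 3] * mesh$vertices[f[, 3], , drop = FALSE]
  list(points = pts, face = fi, bary = b)
}

#' Leaf inclination statistics from randomly sampled surface points
#'
#' Samples `n_samples` points on the mesh uniformly by face area (seeded,
#' reproducible) and evaluates the inclination angle at each sampled point.
#' With `use = "face"` the angle is the zenith angle of the containing
#' face's folded normal; with `use = "vertex"` the folded barycentric
#' interpolation of the per-vertex normals is used (smoother on noisy
#' reconstructions). The standard deviation is the population form.
#'
#' @param mesh a [triangle_mesh()] with at least one face.
#' @param n_samples number of sampled points (default 20).
#' @param seed integer seed.
#' @param use `"face"` or `"vertex"` normal evaluation.
#' @return An `inclination_stats` list: `leaf_id`, `sampled_angles`
#'   (degrees), `mean`, `std_dev`.
#' @export
inclination_stats <- function(mesh, n_samples = 20L, seed = 1L,
                              use = c("face", "vertex")) {
  use <- match.arg(use)
  smp <- sample_mesh_points(mesh, n_samples, seed)
  if (use == "face") {
    fn <- face_normals(mesh)
    nz <- abs(fn[smp$face, 3])
  } else {
    vn <- vertex_normals(mesh)
    f <- mesh$faces[smp$face, , drop = FALSE]
    nvec <- smp$bary[, 1] * vn[f[, 1], , drop = FALSE] +
      smp$bary[, 2] * vn[f[, 2], , drop = FALSE] +
      smp$bary[, 3] * vn[f[, 3], , drop = FALSE]
    nz <- abs(nvec[, 3]) / sqrt(rowSums(nvec^2))
  }
  ang <- acos(pmin(1, nz)) * 180 / pi
  structure(list(leaf_id = mesh$leaf_id, sampled_angles = ang,
                 mean = mean(ang),
                 std_dev = sqrt(mean((ang - mean(ang))^2))),
            class = "inclination_stats")
}

#' @export
print.inclination_stats <- function(x, ...) {
  cat(sprintf("<inclination_stats: leaf %d, n = %d, mean %.2f deg, sd %.2f deg>\n",
              x$leaf_id, length(x$sampled_angles), x$mean, x$std_dev))
  invisible(x)
}

#' Mean absolute percent error
#'
#' `MAPE = (100 / n) * sum |estimated_i - actual_i| / actual_i`, the
#' standard leaf-area accuracy metric for lidar-derived areas against
#' reference measurements.
#'
#' @param estimated,actual equal-length numeric vectors; all `actual` > 0.
#' @return MAPE in percent.
#' @export
mape <- function(estimated, actual) {
  if (length(estimated) != length(actual) || length(actual) < 1L) {
    stop("mape: estimated and actual must have equal length >= 1",
         call. = FALSE)
  }
  if (any(actual <= 0)) {
    stop("mape: all actual values must be positive", call. = FALSE)
  }
  100 * mean(abs(estimated - actual) / actual)
}
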