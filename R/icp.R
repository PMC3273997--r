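#' Nearest-neighbor correspondences between two clouds
#'
#' For every source point, find its nearest target point (kd-tree search);
#' pairs farther apart than `max_distance` are excluded.
#'
#' @param source,target [point_cloud()]s (or n x 3 matrices); target must be
#'   non-empty.
#' @param max_distance pairs with distance > `max_distance` (m) are dropped;
#'   `Inf` keeps all.
#' @param method `"kdtree"` (default, [RANN::nn2()]) or `"brute"`
#'   (exhaustive O(n^2); used as an oracle in tests).
#' @return A data.frame with columns `source` (index into source), `target`
#'   (index of its nearest target point) and `distance` (m).
#' @export
nearest_correspondences <- function(source, target, max_distance = Inf,
                                    method = c("kdtree", "brute")) {
  method <- match.arg(method)
  S <- if (inherits(source, "point_cloud")) source$points else as.matrix(source)
  G <- if (inherits(target, "point_cloud")) target$points else as.matrix(target)
  if (nrow(G) == 0L) {
    stop("nearest_correspondences: target cloud is empty", call. = FALSE)
  }
  if (nrow(S) == 0L) {
    return(data.frame(source = integer(0), target = integer(0),
                      distance = numeric(0)))
  }
  if (method == "kdtree") {
    nn <- RANN::nn2(G, S, k = 1)
    idx <- nn$nn.idx[, 1]
    dist <- nn$nn.dists[, 1]
  } else {
    idx <- integer(nrow(S))
    dist <- numeric(nrow(S))
    for (i in seq_len(nrow(S))) {
      d2 <- (G[, 1] - S[i, 1])^2 + (G[, 2] - S[i, 2])^2 + (G[, 3] - S[i, 3])^2
      idx[i] <- which.min(d2)
      dist[i] <- sqrt(d2[idx[i]])
    }
  }
  keep <- dist <= max_distance
  data.frame(source = which(keep), target = idx[keep],
             distance = dist[keep])
}

#' Register one scan onto another by point-to-point ICP
#'
#' Classic iterative closest point: starting from `init`, alternate
#' (a) nearest-neighbor correspondence assignment from the transformed
#' source into the target and (b) the closed-form least-squares rigid update
#' ([estimate_rigid_transform()]), until the RMS correspondence distance
#' improves by less than `tolerance` or `max_iterations` is reached.
#'
#' Outlier handling for partially overlapping scans: correspondences beyond
#' `max_distance` are dropped each iteration, and surviving pairs farther
#' than `trim_factor` times the median pair distance are trimmed.
#'
#' @param source,target [point_cloud()]s with at least 3 points; the result
#'   maps the source frame onto the target frame.
#' @param init initial [rigid_transform()] guess (e.g. from nominal scan
#'   geometry via [rotation_z()]). The identity is allowed but fragile when
#'   the true rotation is large.
#' @param max_iterations iteration cap.
#' @param tolerance convergence threshold on the RMSD improvement (m).
#' @param max_distance correspondence rejection radius (m).
#' @param trim_factor robust trim multiple of the median pair distance.
#' @param subsample use at most this many (evenly strided) source points for
#'   correspondence search; the closed-form update uses the same subset.
#' @return An `icp_result`: list with `transform` ([rigid_transform()]),
#'   `rmsd` (m, over accepted pairs after the final update), `iterations`,
#'   `converged`, `n_pairs`, and `rmsd_history`.
#' @export
icp_register <- function(source, target, init = rigid_transform(),
                         max_iterations = 50L, tolerance = 1e-6,
                         max_distance = 0.05, trim_factor = 3,
                         subsample = 5000L) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  if (n_points(source) < 3L || n_points(target) < 3L) {
    stop("icp_register: both clouds need at least 3 points", call. = FALSE)
  }
  S_all <- source$points
  if (nrow(S_all) > subsample) {
    S <- S_all[unique(round(seq(1L, nrow(S_all), length.out = subsample))), ,
               drop = FALSE]
  } else {
    S <- S_all
  }
  G <- target$points
  transform <- init
  rmsd_prev <- Inf
  rmsd <- Inf
  n_pairs <- 0L
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    S_t <- transform_points(S, transform)
    cor <- nearest_correspondences(S_t, G, max_distance = max_distance)
    if (nrow(cor) >= 3L && is.finite(trim_factor)) {
      cutoff <- trim_factor * median(cor$distance)
      cor <- cor[cor$distance <= cutoff, , drop = FALSE]
    }
    if (nrow(cor) < 3L) {
      stop("icp_register: correspondence set collapsed to ", nrow(cor),
           " pairs; increase max_distance or provide a better init",
           call. = FALSE)
    }
    # solve directly on the original source subset -> composed transform
    transform <- estimate_rigid_transform(S[cor$source, , drop = FALSE],
                                          G[cor$target, , drop = FALSE])
    resid <- transform_points(S[cor$source, , drop = FALSE], transform) -
      G[cor$target, , drop = FALSE]
    rmsd <- sqrt(mean(rowSums(resid^2)))
    n_pairs <- nrow(cor)
    history <- c(history, rmsd)
    if (abs(rmsd_prev - rmsd) < tolerance) {
      converged <- TRUE
      break
    }
    rmsd_prev <- rmsd
  }
  structure(list(transform = transform, rmsd = rmsd, iterations = iter,
                 converged = converged, n_pairs = n_pairs,
                 rmsd_history = history),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result: rmsd %.3g m over %d pairs, %d iterations%s>\n",
              x$rmsd, x$n_pairs, x$iterations,
              if (x$converged) ", converged" else ""))
  print(x$transform)
  invisible(x)
}
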