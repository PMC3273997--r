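#' Read a point cloud from disk
#'
#' Supported dialects:
#' \describe{
#'   \item{ply}{ASCII PLY 1.0, `element vertex` with `x y z` and an optional
#'     integer `leaf_id` property.}
#'   \item{xyz}{whitespace-separated `x y z` per line, no header.}
#'   \item{csv}{comma-separated with header `x,y,z` and optional `leaf_id`.}
#' }
#' Coordinates are meters. Non-finite coordinates are rejected, never
#' silently dropped.
#'
#' @param path file to read.
#' @param format one of `"ply"`, `"xyz"`, `"csv"`; default guesses from the
#'   file extension.
#' @param frame_id frame tag for the returned cloud; defaults to the file's
#'   base name.
#' @return A [point_cloud()].
#' @seealso [write_point_cloud()]
#' @export
read_point_cloud <- function(path, format = NULL, frame_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path, c("ply", "xyz", "csv"))
  if (is.null(frame_id)) frame_id <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
    ply = read_ply_points(path, frame_id),
    xyz = read_xyz(path, frame_id),
    csv = read_csv_points(path, frame_id),
    stop("unknown point cloud format: ", format, call. = FALSE))
}

#' Write a point cloud to disk
#'
#' Files written here round-trip through [read_point_cloud()] bit-faithfully
#' to better than 1e-6 m (coordinates are printed with 10 significant
#' digits).
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format one of `"ply"`, `"xyz"`, `"csv"`; default guesses from the
#'   extension. `xyz` cannot carry labels; writing a labeled cloud to `xyz`
#'   warns.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- format %||% guess_format(path, c("ply", "xyz", "csv"))
  switch(format,
    ply = write_ply_points(cloud, path),
    xyz = {
      if (!is.null(cloud$labels)) {
        warning("xyz format cannot carry leaf labels; labels not written",
                call. = FALSE)
      }
      writeLines(sprintf("%.10g %.10g %.10g", cloud$points[, 1],
                         cloud$points[, 2], cloud$points[, 3]), path)
    },
    csv = {
      if (is.null(cloud$labels)) {
        writeLines(c("x,y,z",
                     sprintf("%.10g,%.10g,%.10g", cloud$points[, 1],
                             cloud$points[, 2], cloud$points[, 3])), path)
      } else {
        writeLines(c("x,y,z,leaf_id",
                     sprintf("%.10g,%.10g,%.10g,%d", cloud$points[, 1],
                             cloud$points[, 2], cloud$points[, 3],
                             cloud$labels)), path)
      }
    },
    stop("unknown point cloud format: ", format, call. = FALSE))
  invisible(path)
}

#' Read a triangle mesh (ASCII PLY or OBJ)
#'
#' PLY faces are 0-based on disk, OBJ faces 1-based; both are converted to
#' the internal 1-based convention. OBJ parsing handles `v` and `f` records
#' only (`f` entries of the form `i`, `i/..` or `i//..`).
#'
#' @param path file to read.
#' @param format `"ply"` or `"obj"`; default guesses from the extension.
#' @param leaf_id leaf id to attach; for PLY files written by [write_mesh()]
#'   the id stored in the file comment is recovered automatically.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL, leaf_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path, c("ply", "obj"))
  switch(format,
    ply = read_ply_mesh(path, leaf_id),
    obj = read_obj_mesh(path, leaf_id %||% 0L),
    stop("unknown mesh format: ", format, call. = FALSE))
}

#' Write a triangle mesh (ASCII PLY or OBJ)
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file.
#' @param format `"ply"` or `"obj"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- format %||% guess_format(path, c("ply", "obj"))
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("comment canopy3d mesh leaf_id=%d", mesh$leaf_id),
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    body <- c(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
              if (nrow(f)) sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L,
                                   f[, 3] - 1L))
    writeLines(c(hdr, body), path)
  } else if (format == "obj") {
    body <- c(sprintf("# canopy3d mesh leaf_id=%d", mesh$leaf_id),
              sprintf("v %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
              if (nrow(f)) sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
    writeLines(body, path)
  } else {
    stop("unknown mesh format: ", format, call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path, allowed) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (!ext %in% allowed) {
    stop("cannot guess format of '", basename(path), "'; pass format = one of ",
         paste(allowed, collapse = "/"), call. = FALSE)
  }
  ext
}

# --- PLY ---------------------------------------------------------------

parse_ply_header <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!identical(trimws(first), "ply")) {
    stop("parse error at line 1 of ", basename(path), ": not a PLY file",
         call. = FALSE)
  }
  elements <- list()
  cur <- NULL
  n_line <- 1L
  repeat {
    line <- readLines(con, n = 1)
    n_line <- n_line + 1L
    if (!length(line)) {
      stop("parse error in ", basename(path), ": unterminated PLY header",
           call. = FALSE)
    }
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "end_header") break
    if (tok[1] == "format") {
      if (tok[2] != "ascii") {
        stop("only ASCII PLY is supported (", basename(path), " is ", tok[2],
             ")", call. = FALSE)
      }
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = character(0))
    } else if (tok[1] == "property" && !is.null(cur)) {
      elements[[cur]]$props <- c(elements[[cur]]$props, tok[length(tok)])
    }
  }
  list(elements = elements, header_lines = n_line)
}

read_ply_points <- function(path, frame_id) {
  h <- parse_ply_header(path)
  ve <- h$elements[["vertex"]]
  if (is.null(ve)) {
    stop("parse error in ", basename(path), ": no vertex element",
         call. = FALSE)
  }
  if (!all(c("x", "y", "z") %in% ve$props)) {
    stop("parse error in ", basename(path), ": vertex element lacks x/y/z",
         call. = FALSE)
  }
  if (ve$count == 0L) {
    return(point_cloud(matrix(numeric(0), ncol = 3), frame_id = frame_id))
  }
  dt <- data.table::fread(path, skip = h$header_lines, nrows = ve$count,
                          header = FALSE, sep = " ", data.table = FALSE)
  if (ncol(dt) < length(ve$props)) {
    stop("parse error at line ", h$header_lines + 1L, " of ", basename(path),
         ": expected ", length(ve$props), " vertex properties", call. = FALSE)
  }
  colnames(dt)[seq_along(ve$props)] <- ve$props
  labels <- if ("leaf_id" %in% ve$props) as.integer(dt$leaf_id) else NULL
  point_cloud(as.matrix(dt[, c("x", "y", "z")]), labels = labels,
              frame_id = frame_id)
}

write_ply_points <- function(cloud, path) {
  n <- nrow(cloud$points)
  has_lab <- !is.null(cloud$labels)
  hdr <- c("ply", "format ascii 1.0", "comment canopy3d point cloud",
           sprintf("comment frame_id=%s", cloud$frame_id),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           if (has_lab) "property int leaf_id",
           "element face 0",
           "property list uchar int vertex_indices", "end_header")
  body <- if (n == 0L) character(0) else if (has_lab) {
    sprintf("%.10g %.10g %.10g %d", cloud$points[, 1], cloud$points[, 2],
            cloud$points[, 3], cloud$labels)
  } else {
    sprintf("%.10g %.10g %.10g", cloud$points[, 1], cloud$points[, 2],
            cloud$points[, 3])
  }
  writeLines(c(hdr, body), path)
}

read_ply_mesh <- function(path, leaf_id) {
  h <- parse_ply_header(path)
  ve <- h$elements[["vertex"]]
  fe <- h$elements[["face"]]
  if (is.null(ve)) {
    stop("parse error in ", basename(path), ": no vertex element",
         call. = FALSE)
  }
  if (is.null(leaf_id)) {
    cm <- grep("^comment .*leaf_id=", readLines(path, n = h$header_lines),
               value = TRUE)
    leaf_id <- if (length(cm)) as.integer(sub(".*leaf_id=", "", cm[1])) else 0L
  }
  all_lines <- readLines(path)
  body <- all_lines[-seq_len(h$header_lines)]
  vlines <- body[seq_len(ve$count)]
  vv <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
               ncol = length(ve$props), byrow = TRUE)
  faces <- matrix(integer(0), ncol = 3)
  if (!is.null(fe) && fe$count > 0L) {
    flines <- body[ve$count + seq_len(fe$count)]
    ftok <- strsplit(trimws(flines), "\\s+")
    sizes <- vapply(ftok, function(t) as.integer(t[1]), 1L)
    if (any(sizes != 3L)) {
      stop("non-triangular face at face ", which(sizes != 3L)[1], " of ",
           basename(path), call. = FALSE)
    }
    faces <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))),
                    ncol = 3, byrow = TRUE) + 1L
  }
  triangle_mesh(vv[, 1:3, drop = FALSE], faces, leaf_id = leaf_id,
                check_area = FALSE)
}

read_obj_mesh <- function(path, leaf_id) {
  lines <- readLines(path)
  tok <- strsplit(trimws(lines), "\\s+")
  kind <- vapply(tok, function(t) if (length(t)) t[1] else "", "")
  vi <- which(kind == "v")
  fi <- which(kind == "f")
  v <- matrix(numeric(0), ncol = 3)
  if (length(vi)) {
    v <- t(vapply(tok[vi], function(t) {
      val <- suppressWarnings(as.numeric(t[2:4]))
      if (anyNA(val)) {
        stop("parse error in OBJ ", basename(path), ": bad vertex record",
             call. = FALSE)
      }
      val
    }, numeric(3)))
  }
  f <- matrix(integer(0), ncol = 3)
  if (length(fi)) {
    f <- t(vapply(tok[fi], function(t) {
      idx <- suppressWarnings(as.integer(sub("/.*", "", t[2:4])))
      if (anyNA(idx)) {
        stop("parse error in OBJ ", basename(path), ": bad face record",
             call. = FALSE)
      }
      idx
    }, integer(3)))
  }
  triangle_mesh(v, f, leaf_id = leaf_id, check_area = FALSE)
}

read_xyz <- function(path, frame_id) {
  if (file.size(path) == 0L) {
    return(point_cloud(matrix(numeric(0), ncol = 3), frame_id = frame_id))
  }
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 3L) {
    stop("parse error in ", basename(path),
         ": expected 3 whitespace-separated columns", call. = FALSE)
  }
  point_cloud(as.matrix(dt[, 1:3]), frame_id = frame_id)
}

read_csv_points <- function(path, frame_id) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) {
    return(point_cloud(matrix(numeric(0), ncol = 3), frame_id = frame_id))
  }
  if (!all(c("x", "y", "z") %in% names(dt))) {
    stop("parse error in ", basename(path), ": header must name x,y,z",
         call. = FALSE)
  }
  labels <- if ("leaf_id" %in% names(dt)) as.integer(dt$leaf_id) else NULL
  point_cloud(as.matrix(dt[, c("x", "y", "z")]), labels = labels,
              frame_id = frame_id)
}
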