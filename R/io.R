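#' Write / read a surface mesh as ASCII PLY
#'
#' Optional per-vertex properties (e.g. thickness and a converged quality
#' flag) are written as extra float properties.
#'
#' @param mesh a [cbt_mesh].
#' @param path output `.ply` path.
#' @param vertex_props optional named list of per-vertex numeric vectors.
#' @return `write_ply` returns `path` invisibly; `read_ply` returns a list
#'   with `vertices`, `faces`, `normals` (if present) and any extra
#'   properties.
#' @export
write_ply <- function(mesh, path, vertex_props = list()) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  props <- c("x", "y", "z", "nx", "ny", "nz", names(vertex_props))
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nv),
              paste("property float", props),
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  vmat <- cbind(mesh$vertices, mesh$normals)
  for (p in vertex_props) vmat <- cbind(vmat, p)
  vlines <- apply(vmat, 1, function(r) paste(format(r, trim = TRUE,
                                                    digits = 9),
                                             collapse = " "))
  flines <- apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " "))
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)))
  pnames <- sub("^property float ", "",
                grep("^property float", header, value = TRUE))
  vdat <- utils::read.table(text = lines[end + seq_len(nv)],
                            col.names = pnames)
  fdat <- utils::read.table(text = lines[end + nv + seq_len(nf)])
  out <- list(vertices = as.matrix(vdat[, c("x", "y", "z")]),
              faces = as.matrix(fdat[, 2:4]) + 1L)
  if (all(c("nx", "ny", "nz") %in% pnames))
    out$normals <- as.matrix(vdat[, c("nx", "ny", "nz")])
  extra <- setdiff(pnames, c("x", "y", "z", "nx", "ny", "nz"))
  for (p in extra) out[[p]] <- vdat[[p]]
  out
}

#' Serialize landmarks or a coordinate frame to JSON
#'
#' Landmarks are written as named coordinate arrays; a frame is written as a
#' 4 x 4 homogeneous matrix (rotation columns = axes, translation = origin).
#'
#' @param landmarks named list of 3D points (patches are skipped).
#' @param cs a [tibial_cs].
#' @param path output path.
#' @return the written path (write) or the parsed object (read), invisibly
#'   for writers.
#' @export
write_landmarks_json <- function(landmarks, path) {
  pts <- Filter(function(x) is.numeric(x) && length(x) == 3, landmarks)
  jsonlite::write_json(pts, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
}

#' @rdname write_landmarks_json
#' @export
write_frame_json <- function(cs, path) {
  m <- rbind(cbind(cs$x_axis, cs$y_axis, cs$z_axis, cs$origin), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m), path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_frame_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix
  tibial_cs(origin = m[1:3, 4], x_axis = m[1:3, 1], y_axis = m[1:3, 2],
            z_axis = m[1:3, 3])
}

#' Write regional CBT results as CSV
#'
#' Two files mirroring the regional-table and ratio-table layouts: the
#' 24-region table (band, sector, point count, actual mm, standardized
#' x 10^-3) and the per-band M/L and A/P ratios.
#'
#' @param regional a `regional_cbt` object.
#' @param path_regions,path_ratios output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_regional_csv <- function(regional, path_regions, path_ratios) {
  utils::write.csv(regional$regional, path_regions, row.names = FALSE)
  utils::write.csv(regional$ratios, path_ratios, row.names = FALSE)
  invisible(c(path_regions, path_ratios))
}
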