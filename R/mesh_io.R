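# Triangle-mesh readers/writers for the three interchange formats used by
# the surrounding tooling: OFF, ASCII PLY, and legacy VTK POLYDATA.
# Vertex indices are 0-based on disk (the formats' convention) and 1-based
# in memory.

#' Write a triangle mesh to disk
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param format `"off"`, `"ply"` (ASCII) or `"vtk"` (legacy POLYDATA);
#'   inferred from the file extension when omitted.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- resolve_mesh_format(path, format)
  v <- mesh$vertices; f <- mesh$faces - 1L
  nv <- nrow(v); nf <- nrow(f)
  vtxt <- sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L])
  ftxt <- sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L])
  lines <- switch(format,
    off = c("OFF", sprintf("%d %d %d", nv, nf, nrow(mesh$edges)),
            vtxt, ftxt),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nv),
            "property double x", "property double y", "property double z",
            sprintf("element face %d", nf),
            "property list uchar int vertex_indices", "end_header",
            vtxt, ftxt),
    vtk = c("# vtk DataFile Version 3.0", "tri_mesh", "ASCII",
            "DATASET POLYDATA",
            sprintf("POINTS %d double", nv), vtxt,
            sprintf("POLYGONS %d %d", nf, 4L * nf), ftxt))
  writeLines(lines, path)
  invisible(path)
}

#' Read a triangle mesh from disk
#'
#' Accepts the formats written by [write_mesh()]; malformed input is
#' reported with the offending line number.  Only triangular faces are
#' supported.
#'
#' @param path input file path.
#' @param format `"off"`, `"ply"` or `"vtk"`; inferred from the extension
#'   when omitted.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  format <- resolve_mesh_format(path, format)
  lines <- readLines(path, warn = FALSE)
  parse_fail <- function(lineno, msg)
    stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
  if (length(lines) == 0) parse_fail(1L, "empty file")
  nums <- function(i) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                              "[ \t]+")[[1]]))
    if (anyNA(x)) parse_fail(i, "expected numeric fields")
    x
  }
  read_faces <- function(rows) {
    f <- t(vapply(rows, function(i) {
      x <- nums(i)
      if (x[1L] != 3 || length(x) < 4)
        parse_fail(i, "only triangular faces are supported")
      x[2:4]
    }, numeric(3)))
    storage.mode(f) <- "integer"
    f + 1L
  }
  if (format == "off") {
    if (toupper(trimws(lines[1L])) != "OFF") parse_fail(1L, "missing OFF header")
    cnt <- nums(2L)
    nv <- cnt[1L]; nf <- cnt[2L]
    if (length(lines) < 2 + nv + nf) parse_fail(length(lines), "truncated file")
    v <- t(vapply(2L + seq_len(nv), function(i) nums(i)[1:3], numeric(3)))
    f <- read_faces(2L + nv + seq_len(nf))
  } else if (format == "ply") {
    if (trimws(lines[1L]) != "ply") parse_fail(1L, "missing ply header")
    hdr_end <- which(trimws(lines) == "end_header")[1L]
    if (is.na(hdr_end)) parse_fail(length(lines), "missing end_header")
    get_count <- function(what) {
      ln <- grep(paste0("^element ", what, " "), trimws(lines[1:hdr_end]))
      if (!length(ln)) parse_fail(hdr_end, paste("missing element", what))
      as.integer(strsplit(trimws(lines[ln[1L]]), " ")[[1L]][3L])
    }
    nv <- get_count("vertex"); nf <- get_count("face")
    if (length(lines) < hdr_end + nv + nf)
      parse_fail(length(lines), "truncated file")
    v <- t(vapply(hdr_end + seq_len(nv), function(i) nums(i)[1:3],
                  numeric(3)))
    f <- read_faces(hdr_end + nv + seq_len(nf))
  } else {
    pts <- grep("^POINTS", lines)[1L]
    if (is.na(pts)) parse_fail(length(lines), "missing POINTS section")
    nv <- as.integer(strsplit(trimws(lines[pts]), "[ \t]+")[[1L]][2L])
    coords <- numeric(0)
    i <- pts
    while (length(coords) < 3L * nv) {
      i <- i + 1L
      if (i > length(lines)) parse_fail(length(lines), "truncated POINTS")
      coords <- c(coords, nums(i))
    }
    v <- matrix(coords[seq_len(3L * nv)], ncol = 3L, byrow = TRUE)
    pol <- grep("^POLYGONS", lines)[1L]
    if (is.na(pol)) parse_fail(length(lines), "missing POLYGONS section")
    nf <- as.integer(strsplit(trimws(lines[pol]), "[ \t]+")[[1L]][2L])
    f <- read_faces(pol + seq_len(nf))
  }
  if (any(f < 1L) || any(f > nrow(v)))
    parse_fail(length(lines), "face index out of range")
  tri_mesh(v, f)
}

resolve_mesh_format <- function(path, format) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("off", "ply", "vtk"))
  format
}
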